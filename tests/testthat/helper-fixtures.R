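# Shared helpers: tiny sample tables written on the fly.

write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_samples <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    x = c(0, 1000, 2000),
    y = c(0, 500, 1500),
    unit = c("A", "A", "B"),
    As = c(10, 14, 30),
    Cd = c(0.10, 0.12, 0.25),
    stringsAsFactors = FALSE
  )
}
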