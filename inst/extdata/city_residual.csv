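area,city,As,Pb,Zn,Cr,Hg,Cu,Ni,Cd
Pearl River Basin,Dongguan,69.76,457.48,291.55,232.88,67.24,53.38,59.41,0.38
Pearl River Basin,Foshan,41.66,334.62,17.65,189.77,66.51,-3.79,35.84,0.56
Pearl River Basin,Guangzhou,43.79,413.21,214.85,196.04,66.96,39.32,43.51,0.13
Pearl River Basin,Huizhou,28.80,440.33,264.08,252.68,67.17,69.68,65.63,0.38
Pearl River Basin,Jiangmen,57.79,449.63,282.49,205.46,67.05,46.58,53.44,0.00
Pearl River Basin,Shenzhen,37.70,452.31,280.75,239.91,67.37,58.39,65.76,0.41
Pearl River Basin,Zhaoqing,65.14,468.46,212.40,224.11,67.14,44.33,50.29,0.05
Pearl River Basin,Zhongshan,65.48,439.05,194.03,216.15,67.19,13.34,42.75,0.03
Pearl River Basin,Zhuhai,76.84,400.84,288.12,277.99,67.24,67.39,60.98,0.34
Yangtze River Basin,Nanjing,42.55,493.58,317.24,400.57,0.51,52.97,31.08,0.46
Yangtze River Basin,Huzhou,21.80,151.00,486.00,85.70,1.92,173.00,61.20,1.70
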