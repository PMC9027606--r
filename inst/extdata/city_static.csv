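city,As,Pb,Zn,Cr,Hg,Cu,Ni,Cd
Dongguan,70.42,474.75,328.50,238.50,67.32,69.98,62.78,0.46
Foshan,58.05,470.25,261.00,207.00,67.21,49.05,47.92,0.21
Guangzhou,69.75,468.00,319.50,258.75,67.26,84.60,69.30,0.49
Huizhou,72.90,483.75,348.75,267.75,67.32,88.65,71.32,0.55
Jiangmen,73.80,486.00,362.25,256.50,67.33,87.98,72.45,0.52
Shenzhen,81.22,474.75,319.50,265.50,67.38,81.00,69.75,0.49
Zhaoqing,66.82,499.50,353.25,227.25,67.29,79.88,64.58,0.49
Zhongshan,58.50,465.75,195.75,189.00,67.25,4.95,17.78,-0.12
Zhuhai,61.62,463.50,229.50,207.00,67.27,27.90,33.30,0.21
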