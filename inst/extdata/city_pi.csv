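area,city,Pi,capacity_label,risk_label
Pearl River Basin,Dongguan,0.76,Medium capacity,Mild risk
Pearl River Basin,Foshan,0.44,Low capacity,Moderate risk
Pearl River Basin,Guangzhou,0.60,Medium capacity,Mild risk
Pearl River Basin,Huizhou,0.71,Medium capacity,Mild risk
Pearl River Basin,Jiangmen,0.63,Medium capacity,Mild risk
Pearl River Basin,Shenzhen,0.74,Medium capacity,Mild risk
Pearl River Basin,Zhaoqing,0.70,Medium capacity,Mild risk
Pearl River Basin,Zhongshan,0.67,Medium capacity,Mild risk
Pearl River Basin,Zhuhai,0.87,Medium capacity,Mild risk
Yangtze River Basin,Nanjing,0.91,High capacity,No risk
Yangtze River Basin,Huzhou,0.88,High capacity,No risk
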