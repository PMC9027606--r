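element,background,reference
As,25.00,40.00
Pb,60.00,250.00
Zn,97.00,200.00
Cr,77.00,150.00
Hg,0.13,30.00
Cu,32.00,50.00
Ni,28.00,40.00
Cd,0.11,0.30
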