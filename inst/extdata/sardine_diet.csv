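item,code,fraction,prey_tl
zooplankton,ZOO,0.703,2.05
phytoplankton,FIT,0.297,1.00
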