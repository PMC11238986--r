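interaction,parameter,value,units
double_inhibition,e_x,28,ng/mL
double_inhibition,h_x,4.2,dimensionless
self_limiting,e_k,25.57,ng/mL
self_limiting,h_k,6.6,dimensionless
self_limiting,alpha,0.48,dimensionless
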