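x,y,e,h,n,p,species
corticosterone,progesterone,1,4.2,6,<0.001,chicken
corticosterone,testosterone,5,3.9,4,<0.001,chicken
cortisol,testosterone,28,5.2,6,<0.001,rabbit
cortisol,LH,28,2.4,13,<0.001,swine
cortisol,progesterone,23,8,8,<0.001,humans
cortisol,testosterone,22,6,10,<0.001,men
cortisol,testosterone,48,2.4,71,<0.001,men
progesterone,corticosterone,32,3.5,11,<0.001,chicken
testosterone,cortisol,17,7.3,6,<0.001,rabbit
testosterone,cortisol,58,7.5,12,<0.001,rabbit
LH,cortisol,50,7.5,6,<0.001,rabbit
LH,cortisol,51,4.1,12,<0.001,rabbit
testosterone,cortisol,23,1.5,71,<0.001,male humans
progesterone,cortisol,64,3.8,23,<0.001,female humans
progesterone,cortisol,65,8,6,<0.001,female humans
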