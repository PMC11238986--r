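phase,steroid,tissue,concentration,provenance
follicular,progesterone,plasma,1.5,measured
follicular,progesterone,brain,NA,not-reported
follicular,allopregnanolone,plasma,0.15,measured
follicular,allopregnanolone,brain,2.4,ratio-estimated
luteal,progesterone,plasma,10,measured
luteal,progesterone,brain,41,measured
luteal,allopregnanolone,plasma,1.2,measured
luteal,allopregnanolone,brain,20,measured
late_pregnancy,progesterone,plasma,204,measured
late_pregnancy,progesterone,brain,NA,not-reported
late_pregnancy,allopregnanolone,plasma,16,measured
late_pregnancy,allopregnanolone,brain,260,ratio-estimated
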