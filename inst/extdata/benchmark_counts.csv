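cohort,strategy,class,tp,fn,fp,tn
internal,one_step,EAP,80,9,4,195
internal,one_step,LAP,3,4,9,272
internal,one_step,PVP,88,8,3,189
internal,one_step,DP,93,3,8,184
internal,two_step,EAP,86,3,0,199
internal,two_step,LAP,7,0,3,278
internal,two_step,PVP,95,1,1,191
internal,two_step,DP,95,1,1,191
external,two_step,EAP,58,3,1,583
external,two_step,LAP,153,1,3,488
external,two_step,PVP,214,1,1,429
external,two_step,DP,214,1,1,429
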