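group,label,mean_ci,sem,n
IF:ERK1/2,Baseline,0.267,0.016,18
IF:ERK1/2,1h-serum,0.357,0.013,21
IF:ERK1/2,1h-FGF4,0.343,0.009,27
IF:ERK1/2,2h-serum,0.529,0.029,19
IF:ERK1/2,2h-FGF4,0.449,0.035,14
rERK2-LOC,Baseline,0.093,0.018,13
rERK2-LOC,1h-serum,0.189,0.025,11
rERK2-LOC,1h-FGF4,0.367,0.066,15
rERK2-LOC,2h-serum,0.532,0.053,16
rERK2-LOC,2h-FGF4,0.486,0.026,12
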