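group,label,mean_ci,sem,n
eGFP-rERK2,Baseline,0.586,0.024,10
eGFP-rERK2,Serum,0.692,0.083,5
eGFP-rERK2,FGF4,0.643,0.050,6
eGFP-rERK2,U0126,0.659,0.054,8
eGFP-rERK2,U0126+serum,0.767,0.043,6
eGFP-rERK2,U0126+FGF4,0.598,0.019,11
eGFP-rERK2,DMSO+serum,0.759,0.068,7
eGFP-rERK2,DMSO+FGF4,0.701,0.036,10
IF:ERK1/2,Baseline,0.200,0.009,16
IF:ERK1/2,Serum,0.273,0.007,9
IF:ERK1/2,FGF4,0.291,0.008,27
IF:ERK1/2,U0126,0.204,0.011,13
IF:ERK1/2,U0126+serum,0.230,0.012,12
IF:ERK1/2,U0126+FGF4,0.214,0.019,7
IF:ERK1/2,DMSO+serum,0.271,0.010,18
IF:ERK1/2,DMSO+FGF4,0.287,0.025,6
rERK2-LOC,Baseline,0.064,0.009,12
rERK2-LOC,serum,0.480,0.007,7
rERK2-LOC,FGF4,0.508,0.008,16
rERK2-LOC,U0126,0.083,0.011,15
rERK2-LOC,U0126+serum,0.082,0.012,6
rERK2-LOC,U0126+FGF4,0.112,0.019,11
rERK2-LOC,DMSO+serum,0.353,0.010,7
rERK2-LOC,DMSO+FGF4,0.358,0.025,18
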