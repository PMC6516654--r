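name,mean,sd,mode
CLm,0.473,0.271,bayesian
fr,0.1,0,fixed
V1,0.278,0.092,bayesian
CL12,9.96,0,fixed
V2,0.686,0.335,bayesian
Eec,0.212,0.069,bayesian
assay_c0,1.3842,0,assay
assay_c1,0.0626,0,assay
assay_c2,0.0018,0,assay
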