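method,dataset,frr
svm_rfe,dataset1,0.82
rfecv,dataset1,0.85
rfs,dataset1,0.78
rfe,dataset1,0.76
skr_dmkcf,dataset1,0.89
svm_rfe,dataset2,0.84
rfecv,dataset2,0.87
rfs,dataset2,0.79
rfe,dataset2,0.76
skr_dmkcf,dataset2,0.91
svm_rfe,dataset3,0.81
rfecv,dataset3,0.84
rfs,dataset3,0.77
rfe,dataset3,0.73
skr_dmkcf,dataset3,0.87
svm_rfe,dataset4,0.83
rfecv,dataset4,0.86
rfs,dataset4,0.79
rfe,dataset4,0.76
skr_dmkcf,dataset4,0.90
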