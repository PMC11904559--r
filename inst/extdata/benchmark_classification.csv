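method,dataset,accuracy,precision,specificity,recall
svm_rfe,dataset1,78,75,82,76
rfecv,dataset1,83,79,86,80
rfs,dataset1,73,69,77,70
rfe,dataset1,69,65,73,66
skr_dmkcf,dataset1,87,83,90,86
svm_rfe,dataset2,74,69,78,72
rfecv,dataset2,79,73,82,77
rfs,dataset2,67,64,72,66
rfe,dataset2,64,60,68,63
skr_dmkcf,dataset2,82,79,88,81
svm_rfe,dataset3,71,70,79,73
rfecv,dataset3,72,73,82,78
rfs,dataset3,64,65,74,67
rfe,dataset3,60,61,70,63
skr_dmkcf,dataset3,83,80,89,85
svm_rfe,dataset4,82,78,84,77
rfecv,dataset4,87,83,89,82
rfs,dataset4,76,73,78,71
rfe,dataset4,71,70,74,68
skr_dmkcf,dataset4,89,84,91,88
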