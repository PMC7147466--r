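patient_id,classifier,sn,sp,accuracy,gmean
P12,mlp,64.08,63.19,63.39,63.28
P18,mlp,65.45,79.10,76.64,71.73
P23,mlp,66.47,78.86,76.47,72.11
P29,mlp,65.71,72.98,69.81,69.00
P34,mlp,63.08,86.57,82.38,73.70
P40,mlp,74.43,88.22,85.38,80.69
P45,mlp,77.81,78.62,78.12,77.95
P51,mlp,100.00,99.73,99.79,99.86
P56,mlp,79.90,91.37,87.20,85.44
P62,mlp,72.57,70.15,71.51,71.19
P12,svm,67.63,61.30,62.76,64.31
P18,svm,76.91,71.98,72.87,74.34
P23,svm,74.93,81.75,80.44,78.18
P29,svm,78.35,82.20,80.53,80.20
P34,svm,69.00,84.50,81.74,76.14
P40,svm,80.57,88.74,87.06,84.37
P45,svm,81.43,86.54,83.38,83.86
P51,svm,100.00,100.00,100.00,100.00
P56,svm,79.15,82.09,81.02,80.54
P62,svm,79.53,75.97,77.97,77.70
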