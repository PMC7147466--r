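patient_id,mean_cgm,std_cgm,cv_pct,pct_70_180,pct_below_70,pct_below_54,pct_above_180,pct_above_250
P12,187.13,87.19,46.59,45.34,6.15,2.13,48.51,23.45
P18,147.01,58.58,39.84,62.16,9.90,4.62,27.95,5.38
P23,158.43,69.62,43.94,56.30,8.82,3.28,34.88,11.31
P29,171.59,78.15,45.54,49.19,8.20,3.71,42.61,16.92
P34,163.16,65.60,40.21,55.22,5.74,1.35,39.03,10.20
P40,183.93,80.63,43.84,42.06,7.91,4.51,50.03,21.11
P45,154.55,75.83,49.06,50.06,14.45,7.12,35.49,11.33
P51,155.25,73.00,47.02,56.37,10.81,3.92,32.82,12.22
P56,175.17,79.76,45.53,46.45,8.68,3.71,44.87,17.98
P62,160.44,90.53,56.42,47.21,16.30,9.92,36.49,16.61
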