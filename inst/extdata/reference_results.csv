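magnification,split,phase,class,accuracy,sensitivity,specificity,f_score,mcc
100x,80:20,training,benign,94.59,93.76,94.96,91.44,87.55
100x,80:20,training,malignant,94.59,94.96,93.76,96.05,87.55
100x,80:20,training,Average,94.59,94.36,94.36,93.75,87.55
100x,80:20,testing,benign,96.40,94.66,97.20,94.30,91.67
100x,80:20,testing,malignant,96.40,97.20,94.66,97.37,91.67
100x,80:20,testing,Average,96.40,95.93,95.93,95.83,91.67
100x,70:30,training,benign,95.60,87.07,99.31,92.31,89.56
100x,70:30,training,malignant,95.60,99.31,87.07,96.92,89.56
100x,70:30,training,Average,95.60,93.19,93.19,94.62,89.56
100x,70:30,testing,benign,96.16,90.64,98.82,93.88,91.21
100x,70:30,testing,malignant,96.16,98.82,90.64,97.20,91.21
100x,70:30,testing,Average,96.16,94.73,94.73,95.54,91.21
200x,80:20,training,benign,96.40,95.58,96.79,94.49,91.83
200x,80:20,training,malignant,96.40,96.79,95.58,97.32,91.83
200x,80:20,training,Average,96.40,96.18,96.18,95.91,91.83
200x,80:20,testing,benign,96.77,97.09,96.67,93.90,91.80
200x,80:20,testing,malignant,96.77,96.67,97.09,97.81,91.80
200x,80:20,testing,Average,96.77,96.88,96.88,95.85,91.80
200x,70:30,training,benign,93.04,82.22,97.85,87.90,83.45
200x,70:30,training,malignant,93.04,97.85,82.22,95.12,83.45
200x,70:30,training,Average,93.04,90.03,90.03,91.51,83.45
200x,70:30,testing,benign,95.03,89.47,97.58,91.89,88.38
200x,70:30,testing,malignant,95.03,97.58,89.47,96.42,88.38
200x,70:30,testing,Average,95.03,93.53,93.53,94.16,88.38
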