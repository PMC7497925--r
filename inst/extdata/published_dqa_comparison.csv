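case,gamma_m1s0,gamma_m1s1,med_diff_m1s0,med_diff_m1s1
Lung 1,63.4,99.6,-4.6,-0.5
Lung 2,98.8,100.0,-1.9,-1.0
Lung 3,94.2,100.0,-7.9,-1.6
Lung 4,88.9,100.0,-8.3,-1.7
Lung 5,86.6,100.0,-1.1,-0.5
Liver 1,97.8,100.0,-1.3,0.1
Liver 2,41.7,99.2,-6.0,-0.7
Liver 3,87.2,100.0,-2.0,0.2
Liver 4,82.8,100.0,-0.7,-0.5
Pancreas 1,88.9,100.0,-5.0,-0.4
Pancreas 2,68.6,94.0,-5.9,-0.5
Pancreas 3,76.1,97.9,-1.3,-0.1
Pancreas 4,99.6,99.4,-0.2,0.0
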