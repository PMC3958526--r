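# Calibrated LIF/serum reference parameter set (time in minutes, a.u.)
# Produced by calibrate() against the phenotype constraints; see the
# package vignette for the calibration targets and search procedure.
s12 = 3.125
s3 = 0.42
s4 = 35
s5 = 0.16
s6 = 16
s7 = 1.4616
k = 31.25
n = 2
p = 15
d_OS = 0.04
d_N = 0.04
d_R = 0.04
d_E = 0.04
i_OS = 1
i_N = 1
i_R = 1
sigma_OS = 0.028
sigma_N = 0.1185
sigma_R = 0.085
Y = 0
k_Y = 4
h = 2
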