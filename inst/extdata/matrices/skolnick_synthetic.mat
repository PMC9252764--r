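# SYNTHETIC surrogate for a sequence-neighbour pairwise contact potential
# (Skolnick-style quasi-chemical reference; the published table is not
# redistributed here). Constructed deterministically as a symmetric,
# energy-like 20x20 table: -0.45 * outer(h, h) for h = Kyte-Doolittle/4.5,
# plus symmetrized N(0, 0.08) perturbation, seed 71, rounded to 3 decimals.
# Units: dimensionless statistical energy; negative = favourable contact.
# All value-independent score properties (symmetry, anti-symmetry of the
# derived variant scores) are unaffected by the surrogate values.
        A      R      N      D      C      Q      E      G      H      I      L      K      M      F      P      S      T      W      Y      V
A  -0.107  0.150  0.100  0.240 -0.145  0.073  0.084  0.036  0.080 -0.144 -0.116  0.165 -0.024 -0.094  0.011 -0.057  0.150  0.082  0.004 -0.160
R   0.150 -0.593 -0.325 -0.339  0.227 -0.476 -0.309  0.070 -0.339  0.472  0.347 -0.480  0.251  0.278 -0.145 -0.085 -0.011 -0.050 -0.052  0.373
N   0.100 -0.325 -0.449 -0.262  0.187 -0.282 -0.252 -0.102 -0.269  0.310  0.265 -0.169  0.253  0.243 -0.140  0.040  0.005  0.037 -0.069  0.292
D   0.240 -0.339 -0.262 -0.022  0.313 -0.261 -0.309 -0.034 -0.201  0.354  0.379 -0.281  0.214  0.150 -0.070 -0.034  0.012 -0.034 -0.146  0.274
C  -0.145  0.227  0.187  0.313 -0.165  0.268  0.189  0.089  0.159 -0.236 -0.199  0.161 -0.213 -0.194  0.108 -0.020  0.010 -0.045 -0.014 -0.187
Q   0.073 -0.476 -0.282 -0.261  0.268 -0.189 -0.236 -0.047 -0.153  0.521  0.189 -0.319  0.152  0.213 -0.153 -0.080 -0.065 -0.056 -0.135  0.395
E   0.084 -0.309 -0.252 -0.309  0.189 -0.236 -0.147  0.018 -0.163  0.301  0.260 -0.349  0.133  0.263 -0.003 -0.024 -0.145 -0.103 -0.011  0.351
G   0.036  0.070 -0.102 -0.034  0.089 -0.047  0.018 -0.157 -0.031  0.092 -0.029  0.020  0.070  0.057  0.079 -0.093  0.029 -0.054 -0.011  0.055
H   0.080 -0.339 -0.269 -0.201  0.159 -0.153 -0.163 -0.031 -0.257  0.295  0.333 -0.279  0.133  0.277 -0.140 -0.071 -0.130 -0.096 -0.083  0.308
I  -0.144  0.472  0.310  0.354 -0.236  0.521  0.301  0.092  0.295 -0.432 -0.438  0.431 -0.303 -0.185  0.238  0.006  0.082  0.089  0.090 -0.374
L  -0.116  0.347  0.265  0.379 -0.199  0.189  0.260 -0.029  0.333 -0.438 -0.439  0.418 -0.118 -0.281  0.093  0.105  0.066  0.111  0.112 -0.317
K   0.165 -0.480 -0.169 -0.281  0.161 -0.319 -0.349  0.020 -0.279  0.431  0.418 -0.305  0.138  0.307 -0.170 -0.073 -0.015  0.022 -0.070  0.348
M  -0.024  0.251  0.253  0.214 -0.213  0.152  0.133  0.070  0.133 -0.303 -0.118  0.138 -0.114 -0.082  0.101  0.050  0.030  0.035  0.074 -0.181
F  -0.094  0.278  0.243  0.150 -0.194  0.213  0.263  0.057  0.277 -0.185 -0.281  0.307 -0.082 -0.144  0.091  0.030  0.061  0.024  0.099 -0.309
P   0.011 -0.145 -0.140 -0.070  0.108 -0.153 -0.003  0.079 -0.140  0.238  0.093 -0.170  0.101  0.091 -0.063 -0.149 -0.005 -0.060 -0.029  0.149
S  -0.057 -0.085  0.040 -0.034 -0.020 -0.080 -0.024 -0.093 -0.071  0.006  0.105 -0.073  0.050  0.030 -0.149  0.073 -0.027 -0.124 -0.021  0.204
T   0.150 -0.011  0.005  0.012  0.010 -0.065 -0.145  0.029 -0.130  0.082  0.066 -0.015  0.030  0.061 -0.005 -0.027  0.088 -0.062 -0.056  0.067
W   0.082 -0.050  0.037 -0.034 -0.045 -0.056 -0.103 -0.054 -0.096  0.089  0.111  0.022  0.035  0.024 -0.060 -0.124 -0.062 -0.021 -0.003 -0.035
Y   0.004 -0.052 -0.069 -0.146 -0.014 -0.135 -0.011 -0.011 -0.083  0.090  0.112 -0.070  0.074  0.099 -0.029 -0.021 -0.056 -0.003  0.117  0.213
V  -0.160  0.373  0.292  0.274 -0.187  0.395  0.351  0.055  0.308 -0.374 -0.317  0.348 -0.181 -0.309  0.149  0.204  0.067 -0.035  0.213 -0.410
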