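# SYNTHETIC surrogate for a spatial-contact pairwise statistical potential
# (Bastolla-Vendruscolo-style; the published table is not redistributed
# here). Constructed deterministically as a symmetric, energy-like 20x20
# table: -0.60 * outer(h, h) for h = Kyte-Doolittle/4.5, plus symmetrized
# N(0, 0.08) perturbation, seed 137, rounded to 3 decimals.
# Units: dimensionless statistical energy; negative = favourable contact.
        A      R      N      D      C      Q      E      G      H      I      L      K      M      F      P      S      T      W      Y      V
A  -0.065  0.219  0.197  0.236 -0.050  0.201  0.245 -0.020  0.262 -0.295 -0.195  0.294 -0.140 -0.092  0.105  0.084  0.017  0.076  0.092 -0.202
R   0.219 -0.633 -0.435 -0.580  0.245 -0.472 -0.529 -0.042 -0.442  0.657  0.490 -0.516  0.291  0.371 -0.200 -0.064 -0.185 -0.079 -0.179  0.437
N   0.197 -0.435 -0.461 -0.375  0.264 -0.320 -0.304 -0.037 -0.339  0.460  0.427 -0.324  0.275  0.377 -0.203 -0.081 -0.126 -0.133 -0.103  0.486
D   0.236 -0.580 -0.375 -0.390  0.226 -0.424 -0.325 -0.010 -0.364  0.517  0.418 -0.332  0.260  0.164 -0.171 -0.170 -0.012 -0.224 -0.133  0.450
C  -0.050  0.245  0.264  0.226 -0.233  0.273  0.219  0.167  0.288 -0.255 -0.231  0.243 -0.217 -0.254  0.125  0.192  0.161  0.136  0.080 -0.365
Q   0.201 -0.472 -0.320 -0.424  0.273 -0.360 -0.389 -0.188 -0.277  0.458  0.396 -0.404  0.228  0.282 -0.257 -0.153 -0.070 -0.070 -0.069  0.435
E   0.245 -0.529 -0.304 -0.325  0.219 -0.389 -0.213 -0.014 -0.389  0.390  0.313 -0.420  0.294  0.349 -0.132 -0.089 -0.011 -0.124 -0.084  0.389
G  -0.020 -0.042 -0.037 -0.010  0.167 -0.188 -0.014 -0.034 -0.049  0.059  0.003 -0.085  0.036 -0.000 -0.030  0.031  0.068 -0.009  0.034  0.081
H   0.262 -0.442 -0.339 -0.364  0.288 -0.277 -0.389 -0.049 -0.416  0.504  0.365 -0.386  0.251  0.210 -0.023  0.007 -0.031 -0.153 -0.182  0.417
I  -0.295  0.657  0.460  0.517 -0.255  0.458  0.390  0.059  0.504 -0.609 -0.523  0.572 -0.386 -0.359  0.248  0.072  0.006  0.172  0.150 -0.625
L  -0.195  0.490  0.427  0.418 -0.231  0.396  0.313  0.003  0.365 -0.523 -0.473  0.493 -0.240 -0.277  0.254  0.022  0.085  0.053  0.178 -0.443
K   0.294 -0.516 -0.324 -0.332  0.243 -0.404 -0.420 -0.085 -0.386  0.572  0.493 -0.534  0.352  0.340 -0.040 -0.057 -0.042 -0.114 -0.263  0.482
M  -0.140  0.291  0.275  0.260 -0.217  0.228  0.294  0.036  0.251 -0.386 -0.240  0.352 -0.203 -0.190  0.100  0.114  0.042 -0.018  0.085 -0.196
F  -0.092  0.371  0.377  0.164 -0.254  0.282  0.349 -0.000  0.210 -0.359 -0.277  0.340 -0.190 -0.182  0.053  0.109  0.118  0.047  0.086 -0.255
P   0.105 -0.200 -0.203 -0.171  0.125 -0.257 -0.132 -0.030 -0.023  0.248  0.254 -0.040  0.100  0.053  0.024  0.076 -0.037  0.006 -0.088  0.234
S   0.084 -0.064 -0.081 -0.170  0.192 -0.153 -0.089  0.031  0.007  0.072  0.022 -0.057  0.114  0.109  0.076 -0.027  0.025  0.042 -0.133  0.139
T   0.017 -0.185 -0.126 -0.012  0.161 -0.070 -0.011  0.068 -0.031  0.006  0.085 -0.042  0.042  0.118 -0.037  0.025  0.000 -0.032  0.019  0.159
W   0.076 -0.079 -0.133 -0.224  0.136 -0.070 -0.124 -0.009 -0.153  0.172  0.053 -0.114 -0.018  0.047  0.006  0.042 -0.032 -0.048 -0.128  0.125
Y   0.092 -0.179 -0.103 -0.133  0.080 -0.069 -0.084  0.034 -0.182  0.150  0.178 -0.263  0.085  0.086 -0.088 -0.133  0.019 -0.128  0.080  0.154
V  -0.202  0.437  0.486  0.450 -0.365  0.435  0.389  0.081  0.417 -0.625 -0.443  0.482 -0.196 -0.255  0.234  0.139  0.159  0.125  0.154 -0.584
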