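# HPS one-bead-per-residue parameters.
# code: one-letter residue code ("s" = phosphoserine, SEP)
# mass: average residue mass, Da
# charge: integer bead charge at neutral pH, elementary charges
# sigma_A: bead diameter, Angstrom (from amino-acid van der Waals volumes)
# lambda: hydrophobicity scale, dimensionless (Kapcha-Rossky-derived,
#         per the HPS model of Dignon et al. 2018, PLoS Comput Biol 14:e1005941)
# SEP: package parameterization of phosphoserine (no table is printed in the
#      sources above): charge -2; mass = Ser + HPO3; sigma from the serine
#      bead enlarged by the phosphate group volume (~53 A^3); lambda set to
#      0.15, below serine, reflecting the strong hydrophilicity of the
#      dianionic phosphate (serine 0.595 minus about twice the carboxylate
#      decrement of the S->D step, keeping SEP below aspartate's 0.378).
code,mass,charge,sigma_A,lambda
A,71.08,0,5.04,0.730
R,156.19,1,6.56,0.000
N,114.10,0,5.68,0.432
D,115.09,-1,5.58,0.378
C,103.14,0,5.48,0.595
Q,128.13,0,6.02,0.514
E,129.11,-1,5.92,0.459
G,57.05,0,4.50,0.649
H,137.14,0,6.08,0.514
I,113.16,0,6.18,0.973
L,113.16,0,6.18,0.973
K,128.17,1,6.36,0.514
M,131.20,0,6.18,0.838
F,147.18,0,6.36,1.000
P,97.12,0,5.56,1.000
S,87.08,0,5.18,0.595
T,101.10,0,5.62,0.676
W,186.21,0,6.78,0.946
Y,163.18,0,6.46,0.865
V,99.07,0,5.86,0.892
s,167.06,-2,5.97,0.150
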