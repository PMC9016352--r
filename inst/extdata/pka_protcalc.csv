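# Side-chain and terminal pKa values (Scripps Protein Calculator v3.4 set).
# This set, with termini included, reproduces the reference net charges of
# full-length TDP-43 at pH 7.4: Wt -4.1, 12D -16.1, 12pS -28.1.
group,pka,kind
D,4.4,acid
E,4.4,acid
C,8.5,acid
Y,10.0,acid
H,6.5,base
K,10.0,base
R,12.0,base
Nterm,8.0,base
Cterm,3.1,acid
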