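# pcpascreen default branch-site frequency matrix (synthetic table built from
# the yUnAy-type human branch consensus with the near-invariant branch-point
# adenosine at position 6). Replace with a compilation-derived matrix for
# production scans.
# name: branch_7mer
# bases: A C G T
0.22	0.33	0.17	0.28
0.25	0.25	0.25	0.25
0.21	0.30	0.18	0.31
0.06	0.08	0.05	0.81
0.57	0.09	0.28	0.06
0.93	0.02	0.02	0.03
0.09	0.56	0.11	0.24
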