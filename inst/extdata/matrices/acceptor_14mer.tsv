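# pcpascreen default 3' splice-site frequency matrix (synthetic table built
# from the consensus description of the human acceptor: pyrimidine tract,
# C-biased -3, invariant AG, G-biased first exonic base). Replace with a
# compilation-derived matrix for production scans.
# name: acceptor_14mer
# bases: A C G T
# required: 12=A 13=G
# exonic_from: 14
0.10	0.31	0.12	0.47
0.09	0.32	0.10	0.49
0.07	0.31	0.08	0.54
0.07	0.33	0.07	0.53
0.09	0.36	0.08	0.47
0.09	0.37	0.09	0.45
0.08	0.38	0.08	0.46
0.09	0.40	0.07	0.44
0.06	0.43	0.06	0.45
0.23	0.30	0.21	0.26
0.04	0.75	0.01	0.20
1.00	0.00	0.00	0.00
0.00	0.00	1.00	0.00
0.28	0.14	0.48	0.10
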