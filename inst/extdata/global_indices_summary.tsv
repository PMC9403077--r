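polarity	band	metric	n1	m1	s1	n2	m2	s2	p_printed	t_printed	df_printed	d_printed
positive	theta	strength	53	15.98	7.57	39	20.30	8.33	0.009	-2.56	77.35	0.55
positive	theta	clustering	53	0.21	0.09	39	0.26	0.11	0.008	-2.55	76.23	0.55
positive	theta	path_length	53	2.75	0.81	39	2.27	0.65	0.003	3.15	89.30	0.64
positive	alpha	strength	53	11.85	6.62	39	14.51	6.13	0.051	-1.98	85.27	0.41
positive	alpha	clustering	53	0.17	0.08	39	0.20	0.07	0.088	-1.72	87.24	0.36
positive	alpha	path_length	53	3.29	1.10	39	2.86	0.87	0.038	2.11	89.44	0.42
positive	low_beta	strength	53	6.93	2.89	39	7.11	2.61	0.753	-0.32	86.33	0.07
positive	low_beta	clustering	53	0.09	0.04	39	0.09	0.03	0.891	-0.14	86.84	0.02
positive	low_beta	path_length	53	5.49	1.49	39	5.28	1.39	0.490	0.69	85.10	0.15
positive	high_beta	strength	53	6.67	2.40	39	6.23	1.91	0.327	0.99	89.37	0.20
positive	high_beta	clustering	53	0.09	0.03	39	0.08	0.02	0.214	1.25	89.99	0.25
positive	high_beta	path_length	53	5.57	1.49	39	5.75	1.08	0.517	-0.65	89.98	0.13
negative	theta	strength	53	9.04	4.42	39	7.19	2.93	0.019	2.41	89.14	0.48
negative	theta	clustering	53	0.13	0.06	39	0.11	0.04	0.065	1.89	89.97	0.38
negative	theta	path_length	53	4.06	1.28	39	4.61	1.39	0.055	-1.95	78.24	0.42
negative	alpha	strength	53	16.38	8.93	39	12.74	3.02	0.075	1.81	76.64	0.39
negative	alpha	clustering	53	0.22	0.11	39	0.17	0.12	0.083	1.76	76.75	0.38
negative	alpha	path_length	53	2.83	1.23	39	3.40	1.17	0.028	-2.24	84.14	0.47
negative	low_beta	strength	53	7.40	2.98	39	7.35	3.02	0.937	0.08	81.53	0.02
negative	low_beta	clustering	53	0.10	0.04	39	0.10	0.04	0.770	0.29	80.98	0.06
negative	low_beta	path_length	53	5.22	1.31	39	5.18	1.14	0.889	0.14	87.41	0.03
negative	high_beta	strength	53	7.37	2.46	39	6.83	2.32	0.284	1.08	84.52	0.23
negative	high_beta	clustering	53	0.10	0.03	39	0.09	0.03	0.133	1.52	85.31	0.32
negative	high_beta	path_length	53	5.15	1.27	39	5.42	1.34	0.335	-0.97	79.48	0.21
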