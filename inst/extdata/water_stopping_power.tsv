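energy_keV	S_keV_per_um
10	2.256
15	1.647
20	1.317
30	0.9653
40	0.7777
50	0.6603
60	0.5797
70	0.5207
80	0.4757
90	0.4402
100	0.4115
125	0.3591
150	0.3238
175	0.2984
200	0.2793
250	0.2528
300	0.2355
350	0.2233
400	0.2148
450	0.2083
500	0.2034
550	0.1995
600	0.1963
700	0.1917
800	0.1886
900	0.1864
1000	0.1849
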