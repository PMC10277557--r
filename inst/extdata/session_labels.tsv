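subject	afternoon_ecp_lt_lcp	afternoon_ecp_gt_lcp	evening_ecp_lt_lcp	evening_ecp_gt_lcp	morning_ecp_lt_lcp	morning_ecp_gt_lcp
1	UNC	UNC	UNC	ECP	UNC	UNC
2	UNC	UNC	UNC	ECP	LCP	UNC
3	UNC	UNC	UNC	ECP	UNC	UNC
4	UNC	UNC	UNC	ECP	UNC	UNC
5	LCP	UNC	UNC	ECP	UNC	UNC
6	LCP	UNC	UNC	ECP	UNC	UNC
7	LCP	UNC	UNC	ECP	UNC	UNC
8	UNC	UNC	UNC	ECP	UNC	UNC
9	UNC	UNC	UNC	ECP	UNC	UNC
10	LCP	UNC	UNC	ECP	LCP	UNC
11	NA	NA	UNC	ECP	UNC	UNC
12	UNC	UNC	UNC	ECP	UNC	UNC
13	UNC	UNC	UNC	ECP	LCP	UNC
14	UNC	UNC	UNC	ECP	UNC	UNC
15	UNC	UNC	UNC	ECP	UNC	UNC
16	LCP	UNC	UNC	ECP	UNC	UNC
17	UNC	UNC	UNC	LCP	UNC	UNC
18	UNC	UNC	UNC	LCP	UNC	UNC
19	UNC	UNC	UNC	LCP	ECP	UNC
20	UNC	UNC	UNC	LCP	ECP	UNC
21	UNC	UNC	UNC	LCP	UNC	UNC
22	UNC	ECP	UNC	LCP	UNC	UNC
23	ECP	UNC	UNC	LCP	UNC	UNC
24	UNC	UNC	UNC	LCP	UNC	UNC
25	UNC	UNC	UNC	LCP	UNC	UNC
26	ECP	UNC	UNC	LCP	ECP	UNC
27	UNC	UNC	UNC	LCP	ECP	UNC
28	UNC	UNC	UNC	LCP	UNC	UNC
29	UNC	UNC	UNC	LCP	UNC	UNC
30	UNC	UNC	UNC	LCP	UNC	UNC
31	ECP	UNC	UNC	LCP	UNC	UNC
32	UNC	UNC	UNC	LCP	UNC	UNC
33	UNC	UNC	UNC	LCP	UNC	UNC
34	UNC	UNC	UNC	LCP	UNC	UNC
35	UNC	UNC	UNC	LCP	UNC	UNC
36	ECP	UNC	UNC	ECP	ECP	UNC
37	ECP	UNC	UNC	LCP	ECP	UNC
38	ECP	UNC	UNC	LCP	UNC	UNC
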