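ga_weeks	ofd_mm	bpd_mm	od_mm
14	34	28	6
15	38.7	31.8	6.6
16	43.3	35.4	7.1
17	47.8	39	7.6
18	52.1	42.4	8.2
19	56.3	45.8	8.7
20	60.3	49.1	9.2
21	64.3	52.3	9.7
22	68	55.4	10.1
23	71.7	58.4	10.6
24	75.2	61.3	11.1
25	78.6	64.1	11.5
26	81.8	66.8	12
27	84.9	69.4	12.4
28	87.9	72	12.8
29	90.7	74.4	13.2
30	93.4	76.8	13.6
31	96	79	14
32	98.4	81.2	14.4
33	100.7	83.2	14.7
34	102.9	85.2	15.1
35	104.9	87.1	15.4
36	106.8	88.8	15.8
37	108.6	90.5	16.1
38	110.2	92.1	16.4
39	111.7	93.6	16.7
40	113	95	17
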