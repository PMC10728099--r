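probe_id	offset	context	role
P1	25	CpG	target
P1	28	CpG	target
P1	41	CpG	target
P1	57	CpG	target
P1	76	CpG	target
P1	23	CpT	naive
P1	31	CpC	naive
P1	32	CpC	naive
P1	37	CpT	naive
P1	40	CpC	naive
P1	51	CpT	naive
P1	56	CpC	naive
P1	81	CpC	naive
P1	82	CpC	naive
P2	25	CpG	target
P2	38	CpG	target
P2	44	CpG	target
P2	52	CpG	target
P2	66	CpG	target
P2	69	CpG	target
P2	24	CpC	naive
P2	29	CpT	naive
P2	34	CpT	naive
P2	36	CpT	naive
P2	62	CpC	naive
P2	80	CpC	naive
P2	81	CpT	naive
P2	95	CpC	naive
P2	96	CpC	naive
P3	26	CpG	target
P3	34	CpG	target
P3	41	CpG	target
P3	44	CpG	target
P3	25	CpC	naive
P3	28	CpT	naive
P3	37	CpT	naive
P3	51	CpC	naive
P3	57	CpC	naive
P3	58	CpT	naive
P3	65	CpC	naive
P3	70	CpC	naive
P3	71	CpT	naive
P4	30	CpG	target
P4	33	CpG	target
P4	47	CpG	target
P4	59	CpG	target
P4	63	CpG	target
P4	28	CpT	naive
P4	35	CpC	naive
P4	36	CpT	naive
P4	39	CpT	naive
P4	41	CpT	naive
P4	46	CpC	naive
P4	55	CpT	naive
P4	66	CpT	naive
P4	74	CpC	naive
P5	27	CpG	target
P5	36	CpG	target
P5	40	CpG	target
P5	43	CpG	target
P5	58	CpG	target
P5	20	CpC	naive
P5	29	CpT	naive
P5	38	CpT	naive
P5	63	CpC	naive
P5	64	CpC	naive
P5	67	CpT	naive
P5	75	CpC	naive
P5	76	CpC	naive
P5	88	CpT	naive
P6	25	CpG	target
P6	29	CpG	target
P6	45	CpG	target
P6	62	CpG	target
P6	81	CpG	target
P6	24	CpC	naive
P6	27	CpC	naive
P6	28	CpC	naive
P6	32	CpT	naive
P6	39	CpT	naive
P6	44	CpC	naive
P6	60	CpC	naive
P6	61	CpC	naive
P6	80	CpC	naive
P7	26	CpG	target
P7	43	CpG	target
P7	60	CpG	target
P7	64	CpG	target
P7	23	CpT	naive
P7	29	CpC	naive
P7	30	CpT	naive
P7	37	CpC	naive
P7	41	CpC	naive
P7	42	CpC	naive
P7	62	CpT	naive
P7	70	CpC	naive
P7	71	CpC	naive
P8	21	CpG	target
P8	30	CpG	target
P8	45	CpG	target
P8	40	CpA	target
P8	63	CpA	target
P8	65	CpA	target
P8	23	CpC	naive
P8	24	CpT	naive
P8	48	CpC	naive
P8	49	CpT	naive
P8	51	CpC	naive
P8	62	CpC	naive
P8	67	CpC	naive
P8	68	CpT	naive
P8	70	CpT	naive
P8	73	CpC	naive
P9	23	CpG	target
P9	28	CpG	target
P9	42	CpG	target
P9	26	CpA	target
P9	32	CpA	target
P9	38	CpA	target
P9	31	CpC	naive
P9	37	CpC	naive
P9	41	CpC	naive
P9	66	CpT	naive
P9	68	CpT	naive
P9	70	CpC	naive
P9	80	CpT	naive
P9	87	CpC	naive
P9	88	CpC	naive
P9	89	CpT	naive
P10	27	CpG	target
P10	30	CpG	target
P10	48	CpG	target
P10	37	CpA	target
P10	42	CpA	target
P10	44	CpA	target
P10	21	CpC	naive
P10	22	CpC	naive
P10	23	CpT	naive
P10	46	CpT	naive
P10	50	CpC	naive
P10	61	CpC	naive
P10	62	CpC	naive
P10	71	CpC	naive
P10	88	CpT	naive
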