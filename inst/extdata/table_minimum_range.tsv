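energy	region	group	n	at	all_closed
0.250	I	OS	0	0	FALSE
0.250	I	g1	0	0	FALSE
0.250	I	g2	1	1	FALSE
0.250	I	g3	4	1	FALSE
0.250	I	g4	31	20	FALSE
0.250	II	OS	30	17	FALSE
0.250	II	g1	21	9	FALSE
0.250	II	g2	39	22	FALSE
0.250	II	g3	9	2	FALSE
0.250	II	g4	300	179	FALSE
0.250	III	OS	54	39	FALSE
0.250	III	g1	60	41	FALSE
0.250	III	g2	41	31	FALSE
0.250	III	g3	2	2	FALSE
0.250	III	g4	183	130	FALSE
0.300	I	OS	0	0	FALSE
0.300	I	g1	0	0	FALSE
0.300	I	g2	0	0	FALSE
0.300	I	g3	0	0	FALSE
0.300	I	g4	2	1	FALSE
0.300	II	OS	8	5	FALSE
0.300	II	g1	9	5	FALSE
0.300	II	g2	2	0	FALSE
0.300	II	g3	5	1	FALSE
0.300	II	g4	18	9	FALSE
0.300	III	OS	0	0	FALSE
0.300	III	g1	0	0	FALSE
0.300	III	g2	0	0	FALSE
0.300	III	g3	0	0	FALSE
0.300	III	g4	8	5	FALSE
0.350	I	OS	0	0	FALSE
0.350	I	g1	0	0	FALSE
0.350	I	g2	0	0	FALSE
0.350	I	g3	0	0	FALSE
0.350	I	g4	NA	NA	TRUE
0.350	II	OS	24	8	FALSE
0.350	II	g1	10	9	FALSE
0.350	II	g2	79	54	FALSE
0.350	II	g3	2	0	FALSE
0.350	II	g4	NA	NA	TRUE
0.350	III	OS	0	0	FALSE
0.350	III	g1	5	2	FALSE
0.350	III	g2	120	97	FALSE
0.350	III	g3	0	0	FALSE
0.350	III	g4	NA	NA	TRUE
0.400	I	OS	1	0	FALSE
0.400	I	g1	0	0	FALSE
0.400	I	g2	0	0	FALSE
0.400	I	g3	0	0	FALSE
0.400	I	g4	NA	NA	TRUE
0.400	II	OS	33	8	FALSE
0.400	II	g1	3	1	FALSE
0.400	II	g2	33	10	FALSE
0.400	II	g3	62	10	FALSE
0.400	II	g4	NA	NA	TRUE
0.400	III	OS	0	0	FALSE
0.400	III	g1	0	0	FALSE
0.400	III	g2	33	9	FALSE
0.400	III	g3	10	3	FALSE
0.400	III	g4	NA	NA	TRUE
0.450	I	OS	2	0	FALSE
0.450	I	g1	0	0	FALSE
0.450	I	g2	0	0	FALSE
0.450	I	g3	NA	NA	TRUE
0.450	I	g4	NA	NA	TRUE
0.450	II	OS	34	5	FALSE
0.450	II	g1	0	0	FALSE
0.450	II	g2	7	3	FALSE
0.450	II	g3	NA	NA	TRUE
0.450	II	g4	NA	NA	TRUE
0.450	III	OS	2	0	FALSE
0.450	III	g1	3	0	FALSE
0.450	III	g2	0	0	FALSE
0.450	III	g3	NA	NA	TRUE
0.450	III	g4	NA	NA	TRUE
0.500	I	OS	0	0	FALSE
0.500	I	g1	0	0	FALSE
0.500	I	g2	NA	NA	TRUE
0.500	I	g3	NA	NA	TRUE
0.500	I	g4	NA	NA	TRUE
0.500	II	OS	100	25	FALSE
0.500	II	g1	62	15	FALSE
0.500	II	g2	NA	NA	TRUE
0.500	II	g3	NA	NA	TRUE
0.500	II	g4	NA	NA	TRUE
0.500	III	OS	109	69	FALSE
0.500	III	g1	67	43	FALSE
0.500	III	g2	NA	NA	TRUE
0.500	III	g3	NA	NA	TRUE
0.500	III	g4	NA	NA	TRUE
0.550	I	OS	0	0	FALSE
0.550	I	g1	NA	NA	TRUE
0.550	I	g2	NA	NA	TRUE
0.550	I	g3	NA	NA	TRUE
0.550	I	g4	NA	NA	TRUE
0.550	II	OS	3	0	FALSE
0.550	II	g1	NA	NA	TRUE
0.550	II	g2	NA	NA	TRUE
0.550	II	g3	NA	NA	TRUE
0.550	II	g4	NA	NA	TRUE
0.550	III	OS	0	0	FALSE
0.550	III	g1	NA	NA	TRUE
0.550	III	g2	NA	NA	TRUE
0.550	III	g3	NA	NA	TRUE
0.550	III	g4	NA	NA	TRUE
0.600	I	OS	NA	NA	TRUE
0.600	I	g1	NA	NA	TRUE
0.600	I	g2	NA	NA	TRUE
0.600	I	g3	NA	NA	TRUE
0.600	I	g4	NA	NA	TRUE
0.600	II	OS	NA	NA	TRUE
0.600	II	g1	NA	NA	TRUE
0.600	II	g2	NA	NA	TRUE
0.600	II	g3	NA	NA	TRUE
0.600	II	g4	NA	NA	TRUE
0.600	III	OS	NA	NA	TRUE
0.600	III	g1	NA	NA	TRUE
0.600	III	g2	NA	NA	TRUE
0.600	III	g3	NA	NA	TRUE
0.600	III	g4	NA	NA	TRUE
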