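energy	region	group	n	at	all_closed
0.250	I	OS	0	0	FALSE
0.250	I	g1	0	0	FALSE
0.250	I	g2	0	0	FALSE
0.250	I	g3	0	0	FALSE
0.250	I	g4	1	0	FALSE
0.250	II	OS	5	1	FALSE
0.250	II	g1	62	26	FALSE
0.250	II	g2	3	2	FALSE
0.250	II	g3	3	0	FALSE
0.250	II	g4	13	6	FALSE
0.250	III	OS	3	1	FALSE
0.250	III	g1	9	5	FALSE
0.250	III	g2	0	0	FALSE
0.250	III	g3	0	0	FALSE
0.250	III	g4	2	2	FALSE
0.300	I	OS	0	0	FALSE
0.300	I	g1	0	0	FALSE
0.300	I	g2	0	0	FALSE
0.300	I	g3	0	0	FALSE
0.300	I	g4	0	0	FALSE
0.300	II	OS	11	1	FALSE
0.300	II	g1	8	1	FALSE
0.300	II	g2	2	0	FALSE
0.300	II	g3	1	1	FALSE
0.300	II	g4	0	0	FALSE
0.300	III	OS	2	2	FALSE
0.300	III	g1	0	0	FALSE
0.300	III	g2	0	0	FALSE
0.300	III	g3	0	0	FALSE
0.300	III	g4	34	31	FALSE
0.350	I	OS	0	0	FALSE
0.350	I	g1	0	0	FALSE
0.350	I	g2	0	0	FALSE
0.350	I	g3	0	0	FALSE
0.350	I	g4	NA	NA	TRUE
0.350	II	OS	0	0	FALSE
0.350	II	g1	1	0	FALSE
0.350	II	g2	4	2	FALSE
0.350	II	g3	9	3	FALSE
0.350	II	g4	NA	NA	TRUE
0.350	III	OS	2	1	FALSE
0.350	III	g1	0	0	FALSE
0.350	III	g2	34	29	FALSE
0.350	III	g3	0	0	FALSE
0.350	III	g4	NA	NA	TRUE
0.400	I	OS	0	0	FALSE
0.400	I	g1	0	0	FALSE
0.400	I	g2	0	0	FALSE
0.400	I	g3	0	0	FALSE
0.400	I	g4	NA	NA	TRUE
0.400	II	OS	1	0	FALSE
0.400	II	g1	1	0	FALSE
0.400	II	g2	1	0	FALSE
0.400	II	g3	1	0	FALSE
0.400	II	g4	NA	NA	TRUE
0.400	III	OS	0	0	FALSE
0.400	III	g1	0	0	FALSE
0.400	III	g2	0	0	FALSE
0.400	III	g3	0	0	FALSE
0.400	III	g4	NA	NA	TRUE
0.450	I	OS	0	0	FALSE
0.450	I	g1	0	0	FALSE
0.450	I	g2	0	0	FALSE
0.450	I	g3	NA	NA	TRUE
0.450	I	g4	NA	NA	TRUE
0.450	II	OS	38	13	FALSE
0.450	II	g1	5	0	FALSE
0.450	II	g2	0	0	FALSE
0.450	II	g3	NA	NA	TRUE
0.450	II	g4	NA	NA	TRUE
0.450	III	OS	1	0	FALSE
0.450	III	g1	0	0	FALSE
0.450	III	g2	3	0	FALSE
0.450	III	g3	NA	NA	TRUE
0.450	III	g4	NA	NA	TRUE
0.500	I	OS	0	0	FALSE
0.500	I	g1	0	0	FALSE
0.500	I	g2	NA	NA	TRUE
0.500	I	g3	NA	NA	TRUE
0.500	I	g4	NA	NA	TRUE
0.500	II	OS	20	5	FALSE
0.500	II	g1	20	5	FALSE
0.500	II	g2	NA	NA	TRUE
0.500	II	g3	NA	NA	TRUE
0.500	II	g4	NA	NA	TRUE
0.500	III	OS	0	0	FALSE
0.500	III	g1	0	0	FALSE
0.500	III	g2	NA	NA	TRUE
0.500	III	g3	NA	NA	TRUE
0.500	III	g4	NA	NA	TRUE
0.550	I	OS	27	12	FALSE
0.550	I	g1	NA	NA	TRUE
0.550	I	g2	NA	NA	TRUE
0.550	I	g3	NA	NA	TRUE
0.550	I	g4	NA	NA	TRUE
0.550	II	OS	259	121	FALSE
0.550	II	g1	NA	NA	TRUE
0.550	II	g2	NA	NA	TRUE
0.550	II	g3	NA	NA	TRUE
0.550	II	g4	NA	NA	TRUE
0.550	III	OS	10	4	FALSE
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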