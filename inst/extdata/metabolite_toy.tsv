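feature_id	S01	S02	S03	S04	S05	S06	S07	S08	S09	S10
M01	10	12	11	13	10	9	11	12	10	11
M02	NA	NA	NA	5	6	7	8	5	6	7
M03	NA	NA	4	5	6	7	8	4	5	6
M04	-3	0	6	7	8	9	6	7	8	9
M01	14	16	15	17	14	13	15	16	14	15
M06	3	4	3	5	4	3	4	5	3	4
M07	20	22	21	23	20	19	21	22	20	21
M08	2	3	2	4	3	2	3	4	2	3
M09	6	7	6	8	7	6	7	8	6	7
M10	9	10	9	11	10	9	10	11	9	10
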