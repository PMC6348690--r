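otu_id	1	2	3	4	5	6	7	8	9	10	11	12	13	14	15	16	17	18	19	20	21	22	23	24	25	26	27	28	29	30	31	32	33	34	35	36	37	38	39	40	41	42	43	44	45	46	47	48	49	50
OTU_01	7	3	6	9	14	42	16	12	5	15	17	23	8	22	13	16	18	6	5	2	10	2	15	12	32	16	24	9	1	3	6	10	6	2	4	48	13	7	4	11	10	10	20	NA	13	20	14	7	9	12
OTU_02	6	4	12	8	3	6	17	6	3	4	4	6	19	19	25	23	11	4	5	8	7	6	9	8	7	7	9	12	24	16	5	20	12	6	6	NA	NA	10	14	12	4	13	9	11	15	19	9	15	19	28
OTU_03	6	6	6	3	3	5	6	8	9	9	11	24	23	21	5	6	19	6	25	8	8	15	5	3	12	5	6	27	9	7	21	18	10	6	2	1	7	15	25	34	13	7	9	7	5	9	6	5	14	21
OTU_04	57	19	6	8	50	NA	3	8	8	13	7	12	5	26	5	7	9	10	19	19	7	3	3	2	6	3	2	1	2	3	5	25	NA	17	9	23	10	8	1	3	8	8	12	19	11	17	4	11	10	3
OTU_05	37	13	49	16	16	7	6	9	14	8	24	31	21	29	38	12	39	7	11	11	7	23	85	25	30	44	16	10	11	9	6	6	3	69	102	12	11	8	2	4	8	6	23	25	6	3	3	1	1	5
OTU_06	6	22	16	65	12	3	10	10	9	18	4	15	22	10	7	4	5	6	2	2	14	39	32	79	187	47	27	10	8	12	6	7	14	31	9	13	39	37	74	NA	NA	64	27	6	9	8	6	2	10	5
OTU_07	6	8	4	1	3	6	27	61	208	96	9	10	4	6	6	14	9	10	8	4	4	30	8	8	13	66	27	72	118	NA	74	58	40	24	24	16	13	8	66	9	3	11	6	10	37	30	20	14	15	7
OTU_08	6	7	4	4	13	6	30	21	8	4	3	5	4	39	50	10	NA	9	10	25	11	8	8	4	1	2	3	6	12	11	27	15	11	10	13	6	7	4	2	NA	11	15	8	6	50	14	19	8	17	29
OTU_09	11	6	17	38	8	1	2	3	4	17	30	16	7	3	6	2	4	7	3	4	7	5	3	5	4	9	33	17	20	15	11	6	5	6	2	2	4	21	12	7	3	3	6	9	15	108	26	19	16	NA
OTU_10	56	28	20	24	15	NA	10	8	11	11	16	3	2	3	12	9	6	5	31	14	5	4	3	6	37	19	7	18	16	28	16	10	10	16	19	4	9	11	7	6	6	17	8	49	26	12	92	17	13	17
OTU_11	2	21	22	7	6	27	5	1	1	3	7	3	5	16	11	29	22	22	8	36	15	12	3	NA	23	10	NA	7	23	17	22	20	38	41	19	16	10	8	13	11	17	10	31	34	40	4	4	5	6	8
OTU_12	15	15	18	5	18	6	4	1	8	2	3	5	16	4	4	13	14	13	1	4	11	9	10	16	7	6	4	6	45	27	13	23	5	14	NA	7	4	8	13	27	13	3	1	5	6	14	10	8	4	2
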