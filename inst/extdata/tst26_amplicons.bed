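chr14	999980	1000140	AKT1_ex2_amp01
chr2	1999980	2000140	ALK_ex23_amp01
chr5	2999980	3000140	APC_ex15.1_amp01
chr5	2999990	3000160	APC_ex15.1_amp02
chr5	3009980	3010140	APC_ex15.2_amp01
chr5	3009990	3010160	APC_ex15.2_amp02
chr5	3019980	3020140	APC_ex15.3_amp01
chr5	3019990	3020160	APC_ex15.3_amp02
chr5	3020000	3020180	APC_ex15.3_amp03
chr5	3020010	3020200	APC_ex15.3_amp04
chr5	3020020	3020220	APC_ex15.3_amp05
chr5	3020030	3020240	APC_ex15.3_amp06
chr5	3020040	3020260	APC_ex15.3_amp07
chr5	3020050	3020280	APC_ex15.3_amp08
chr5	3020060	3020300	APC_ex15.3_amp09
chr5	3020070	3020320	APC_ex15.3_amp10
chr7	3999980	4000140	BRAF_ex11_amp01
chr7	4009980	4010140	BRAF_ex15_amp01
chr7	4009990	4010160	BRAF_ex15_amp02
chr16	4999980	5000140	CDH1_ex8_amp01
chr16	4999990	5000160	CDH1_ex8_amp02
chr16	5009980	5010140	CDH1_ex9_amp01
chr16	5009990	5010160	CDH1_ex9_amp02
chr16	5019980	5020140	CDH1_ex12_amp01
chr16	5019990	5020160	CDH1_ex12_amp02
chr3	5999980	6000140	CTNNB1_ex2_amp01
chr3	5999990	6000160	CTNNB1_ex2_amp02
chr7	6999980	7000140	EGFR_ex18_amp01
chr7	6999990	7000160	EGFR_ex18_amp02
chr7	7009980	7010140	EGFR_ex19_amp01
chr7	7009990	7010160	EGFR_ex19_amp02
chr7	7019980	7020140	EGFR_ex20_amp01
chr7	7029980	7030140	EGFR_ex21_amp01
chr7	7029990	7030160	EGFR_ex21_amp02
chr17	7999980	8000140	ERBB2_ex20_amp01
chr17	7999990	8000160	ERBB2_ex20_amp02
chr4	8999980	9000140	FBXW7_ex7_amp01
chr4	8999990	9000160	FBXW7_ex7_amp02
chr4	9000000	9000180	FBXW7_ex7_amp03
chr4	9009980	9010140	FBXW7_ex8_amp01
chr4	9009990	9010160	FBXW7_ex8_amp02
chr4	9010000	9010180	FBXW7_ex8_amp03
chr4	9019980	9020140	FBXW7_ex9_amp01
chr4	9019990	9020160	FBXW7_ex9_amp02
chr4	9020000	9020180	FBXW7_ex9_amp03
chr4	9029980	9030140	FBXW7_ex10_amp01
chr4	9029990	9030160	FBXW7_ex10_amp02
chr4	9039980	9040140	FBXW7_ex11_amp01
chr4	9039990	9040160	FBXW7_ex11_amp02
chr10	9999980	10000140	FGFR2_ex6_amp01
chr10	9999990	10000160	FGFR2_ex6_amp02
chr3	10999980	11000140	FOXL2_ex1_amp01
chr9	11999980	12000140	GNAQ_ex4_amp01
chr9	11999990	12000160	GNAQ_ex4_amp02
chr9	12009980	12010140	GNAQ_ex5_amp01
chr9	12009990	12010160	GNAQ_ex5_amp02
chr9	12019980	12020140	GNAQ_ex6_amp01
chr9	12019990	12020160	GNAQ_ex6_amp02
chr20	12999980	13000140	GNAS_ex6_amp01
chr20	13009980	13010140	GNAS_ex8_amp01
chr4	13999980	14000140	KIT_ex9_amp01
chr4	13999990	14000160	KIT_ex9_amp02
chr4	14009980	14010140	KIT_ex11_amp01
chr4	14009990	14010160	KIT_ex11_amp02
chr4	14019980	14020140	KIT_ex13_amp01
chr4	14019990	14020160	KIT_ex13_amp02
chr4	14029980	14030140	KIT_ex17_amp01
chr4	14029990	14030160	KIT_ex17_amp02
chr4	14039980	14040140	KIT_ex18_amp01
chr12	14999980	15000140	KRAS_ex1_amp01
chr12	14999990	15000160	KRAS_ex1_amp02
chr12	15009980	15010140	KRAS_ex2_amp01
chr12	15009990	15010160	KRAS_ex2_amp02
chr12	15019980	15020140	KRAS_ex3_amp01
chr12	15019990	15020160	KRAS_ex3_amp02
chr12	15029980	15030140	KRAS_ex4_amp01
chr12	15029990	15030160	KRAS_ex4_amp02
chr15	15999980	16000140	MAP2K1_ex2_amp01
chr7	16999980	17000140	MET_ex1_amp01
chr7	16999990	17000160	MET_ex1_amp02
chr7	17000000	17000180	MET_ex1_amp03
chr7	17009980	17010140	MET_ex4_amp01
chr7	17009990	17010160	MET_ex4_amp02
chr7	17010000	17010180	MET_ex4_amp03
chr7	17019980	17020140	MET_ex13_amp01
chr7	17019990	17020160	MET_ex13_amp02
chr7	17020000	17020180	MET_ex13_amp03
chr7	17029980	17030140	MET_ex15_amp01
chr7	17029990	17030160	MET_ex15_amp02
chr7	17030000	17030180	MET_ex15_amp03
chr7	17039980	17040140	MET_ex16_amp01
chr7	17039990	17040160	MET_ex16_amp02
chr7	17040000	17040180	MET_ex16_amp03
chr7	17049980	17050140	MET_ex17_amp01
chr7	17049990	17050160	MET_ex17_amp02
chr7	17050000	17050180	MET_ex17_amp03
chr7	17059980	17060140	MET_ex18_amp01
chr7	17059990	17060160	MET_ex18_amp02
chr7	17069980	17070140	MET_ex20_amp01
chr7	17069990	17070160	MET_ex20_amp02
chr2	17999980	18000140	MSH6_ex5_amp01
chr2	17999990	18000160	MSH6_ex5_amp02
chr2	18000000	18000180	MSH6_ex5_amp03
chr1	18999980	19000140	NRAS_ex1_amp01
chr1	18999990	19000160	NRAS_ex1_amp02
chr1	19009980	19010140	NRAS_ex2_amp01
chr1	19009990	19010160	NRAS_ex2_amp02
chr1	19019980	19020140	NRAS_ex3_amp01
chr1	19019990	19020160	NRAS_ex3_amp02
chr1	19029980	19030140	NRAS_ex4_amp01
chr1	19029990	19030160	NRAS_ex4_amp02
chr4	19999980	20000140	PDGFRA_ex11_amp01
chr4	19999990	20000160	PDGFRA_ex11_amp02
chr4	20009980	20010140	PDGFRA_ex13_amp01
chr4	20009990	20010160	PDGFRA_ex13_amp02
chr4	20019980	20020140	PDGFRA_ex17_amp01
chr3	20999980	21000140	PIK3CA_ex1_amp01
chr3	20999990	21000160	PIK3CA_ex1_amp02
chr3	21000000	21000180	PIK3CA_ex1_amp03
chr3	21009980	21010140	PIK3CA_ex2_amp01
chr3	21009990	21010160	PIK3CA_ex2_amp02
chr3	21010000	21010180	PIK3CA_ex2_amp03
chr3	21019980	21020140	PIK3CA_ex7_amp01
chr3	21019990	21020160	PIK3CA_ex7_amp02
chr3	21020000	21020180	PIK3CA_ex7_amp03
chr3	21029980	21030140	PIK3CA_ex9_amp01
chr3	21029990	21030160	PIK3CA_ex9_amp02
chr3	21030000	21030180	PIK3CA_ex9_amp03
chr3	21039980	21040140	PIK3CA_ex20_amp01
chr3	21039990	21040160	PIK3CA_ex20_amp02
chr3	21040000	21040180	PIK3CA_ex20_amp03
chr10	21999980	22000140	PTEN_ex1.1_amp01
chr10	22009980	22010140	PTEN_ex1.2_amp01
chr10	22019980	22020140	PTEN_ex2_amp01
chr10	22019990	22020160	PTEN_ex2_amp02
chr10	22029980	22030140	PTEN_ex3_amp01
chr10	22029990	22030160	PTEN_ex3_amp02
chr10	22039980	22040140	PTEN_ex4_amp01
chr10	22039990	22040160	PTEN_ex4_amp02
chr10	22049980	22050140	PTEN_ex5.1_amp01
chr10	22059980	22060140	PTEN_ex5.2_amp01
chr10	22069980	22070140	PTEN_ex6.1_amp01
chr10	22079980	22080140	PTEN_ex6.2_amp01
chr10	22089980	22090140	PTEN_ex7_amp01
chr10	22089990	22090160	PTEN_ex7_amp02
chr10	22090000	22090180	PTEN_ex7_amp03
chr10	22099980	22100140	PTEN_ex9_amp01
chr10	22099990	22100160	PTEN_ex9_amp02
chr18	22999980	23000140	SMAD4_ex8_amp01
chr18	22999990	23000160	SMAD4_ex8_amp02
chr18	23000000	23000180	SMAD4_ex8_amp03
chr18	23009980	23010140	SMAD4_ex11_amp01
chr18	23009990	23010160	SMAD4_ex11_amp02
chr20	23999980	24000140	SRC_ex10_amp01
chr20	23999990	24000160	SRC_ex10_amp02
chr19	24999980	25000140	STK11_ex1_amp01
chr19	24999990	25000160	STK11_ex1_amp02
chr19	25009980	25010140	STK11_ex4_amp01
chr19	25009990	25010160	STK11_ex4_amp02
chr19	25019980	25020140	STK11_ex6_amp01
chr19	25029980	25030140	STK11_ex8_amp01
chr19	25029990	25030160	STK11_ex8_amp02
chr17	25999980	26000140	TP53_ex2_3_4_amp01
chr17	25999990	26000160	TP53_ex2_3_4_amp02
chr17	26000000	26000180	TP53_ex2_3_4_amp03
chr17	26000010	26000200	TP53_ex2_3_4_amp04
chr17	26000020	26000220	TP53_ex2_3_4_amp05
chr17	26000030	26000240	TP53_ex2_3_4_amp06
chr17	26009980	26010140	TP53_ex5_6_amp01
chr17	26009990	26010160	TP53_ex5_6_amp02
chr17	26010000	26010180	TP53_ex5_6_amp03
chr17	26010010	26010200	TP53_ex5_6_amp04
chr17	26019980	26020140	TP53_ex7_amp01
chr17	26029980	26030140	TP53_ex8_9_amp01
chr17	26029990	26030160	TP53_ex8_9_amp02
chr17	26030000	26030180	TP53_ex8_9_amp03
chr17	26039980	26040140	TP53_ex10_amp01
chr17	26049980	26050140	TP53_ex11_amp01
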