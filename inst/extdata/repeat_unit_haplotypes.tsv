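species	haplotype	role	row
Eremophila_alpestris	A_CS	reference	AACAAAAGAAATCAATCCCATTTCTTTCTTTATTATACATATAATAAAGAG
Eremophila_alpestris	A_1	mask	...................................................
Eremophila_alpestris	A_2	mask	..................T................................
Eremophila_alpestris	A_3	mask	.....----------------------------------------------
Alaudala_cheleensis	B_CS	reference	ACACACGTATAAATAAAGACAGGACACCTT-ACGTCTTCTTATACTATTCTTATACTATTATACACGT
Alaudala_cheleensis	B_1	mask	......A.....G.................-.....................................
Alaudala_cheleensis	B_2	mask	..............................T.....................................
Alaudala_cheleensis	B_3	mask	..............................-.....................................
Alaudala_cheleensis	B_4	mask	......A.....G.................-..........................G..........
Alaudala_cheleensis	B_5	mask	..............................-..........................G..........
Alaudala_cheleensis	B_6	mask	.........---------------------------................................
Alaudala_cheleensis	B_7	mask	..............................-...........--------------------------
Alaudala_heinei	C_CS	reference	CACGTATAAGTAAAGAGAGGACACCTCACGTCTCCTTACTATTATACGTGTA
Alaudala_heinei	C_1	mask	....................................................
Alaudala_heinei	C_2	mask	............................................--------
Alauda_arvensis	D_CS	reference	AAAGAAATCAATCCCATTGATTTCATTATATTAGTAT
Alauda_arvensis	D_1	mask	.......C..G..ATA....C....C.G.....A..C
Alauda_arvensis	D_2	mask	.....................................
Alauda_arvensis	D_3	mask	.................--------------------
Alauda_gulgula	E_CS	reference	AAAGAAATCAATCCCATTGATTTCATTATATTAGTAT
Alauda_gulgula	E_1	mask	.....................................
Alauda_gulgula	E_2	mask	....G.........-----------------------
Alauda_razae	F_CS	reference	AAAGAAATCAACCCTATTGACTTCATTATATTAGTAT
Alauda_razae	F_1	mask	..CA..CCA.T...-......................
Alauda_razae	F_2	mask	.....................................
Alauda_razae	F_3	mask	................---------------------
Calandrella_cinerea	G_CS	reference	AAAGAATAAGAGACCACTCTTACTCTTTATCATACACATAACTGTATATATATATATGTAT
Calandrella_cinerea	G_1	mask	.......---------.A..CTTA..C.T.ATC.T...C.TAAC.G..........TA...
Calandrella_cinerea	G_2	mask	.............................................................
Calandrella_cinerea	G_3	mask	............................................----.............
Calandrella_cinerea	G_4	mask	..........................
Melanocorypha_mongolica	H_1	reference	TCTTTACTTATTACATGTATATAAAGTAGAGA
Melanocorypha_mongolica	H_2	mask	......TC.....T..ACG..C...AC.....
Melanocorypha_mongolica	H_3	mask	......................----------
Melanocorypha_mongolica	H_1+H_2	sequence	TCTTTACTTATTACATGTATATAAAGTAGAGATCTTTATCTATTATATACGTACAAAACAGAGA
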