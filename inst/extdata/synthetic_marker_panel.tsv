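marker_id	chrom	start	end	strand	target_celltype	cpg_offsets
LIV-001	chr1	1002000	1002119	+	liver	23,41,45,83,103,105
LIV-002	chr1	1004000	1004107	+	liver	21,23,43,49,51,67,87,89
LIV-003	chr1	1006000	1006104	+	liver	35,39,49,51,55
LIV-004	chr1	1008000	1008114	+	liver	15,37,41,45
LIV-005	chr1	1010000	1010096	+	liver	21,33,37,55,57,63
SKN-001	chr2	2002000	2002129	-	skin	7,11,33,45,55,73,119
SKN-002	chr2	2004000	2004127	+	skin	9,13,23,51,61,87,119
SKN-003	chr2	2006000	2006124	+	skin	11,29,35,53,105,113
SKN-004	chr2	2008000	2008135	+	skin	23,39,45,53,73,75,77,85
SKN-005	chr2	2010000	2010102	+	skin	21,25,31,51,63,79
LNG-001	chr3	3002000	3002093	+	lung	7,29,37,39,41,57,73,75
LNG-002	chr3	3004000	3004107	+	lung	11,25,33,37,49
LNG-003	chr3	3006000	3006140	+	lung	27,55,61,65,71,111,125
LNG-004	chr3	3008000	3008096	-	lung	5,13,19,27,31
LNG-005	chr3	3010000	3010125	+	lung	11,17,43,53,103
LNG-006	chr3	3012000	3012102	-	lung	7,9,21,25,35,43,77
LNG-007	chr3	3014000	3014128	+	lung	13,37,39,59,75
LNG-008	chr3	3016000	3016100	-	lung	49,63,87,91
LNG-009	chr3	3018000	3018094	-	lung	29,31,35,51
LNG-010	chr3	3020000	3020114	+	lung	17,25,35,37,45,73,75
GIT-001	chr4	4002000	4002133	-	gi	21,29,45,101
GIT-002	chr4	4004000	4004106	+	gi	19,39,41,67,75,79
GIT-003	chr4	4006000	4006099	-	gi	5,15,39,51,71,79
GIT-004	chr4	4008000	4008119	+	gi	21,47,55,75,85
GIT-005	chr4	4010000	4010133	-	gi	15,61,85,101,109,111,119
GIT-006	chr4	4012000	4012127	+	gi	13,19,37,55
GIT-007	chr4	4014000	4014119	+	gi	9,53,61,101
GIT-008	chr4	4016000	4016113	+	gi	15,17,19,23,71
NEU-001	chr5	5002000	5002091	-	neutrophil	7,25,29,59,71,73,81
NEU-002	chr5	5004000	5004138	-	neutrophil	15,43,71,95,123
NEU-003	chr5	5006000	5006110	+	neutrophil	5,13,19,43,79,83
NEU-004	chr5	5008000	5008115	-	neutrophil	13,19,25,37,43,53,61,73
MON-001	chr6	6002000	6002091	+	monocyte	13,45,51,73
MON-002	chr6	6004000	6004124	-	monocyte	15,17,29,59,69,95,107,109
MON-003	chr6	6006000	6006093	-	monocyte	23,45,75,87
MON-004	chr6	6008000	6008110	-	monocyte	7,11,13,29,35,71,79,83
EOS-001	chr7	7002000	7002108	+	eosinophil	11,29,45,61,65,83,87,91
EOS-002	chr7	7004000	7004107	-	eosinophil	5,7,9,35,65,91
EOS-003	chr7	7006000	7006124	+	eosinophil	13,45,49,75,79,83,87,117
EOS-004	chr7	7008000	7008134	-	eosinophil	7,111,117,123
BCL-001	chr8	8002000	8002098	+	b_cell	9,27,45,47,57,69,87
BCL-002	chr8	8004000	8004100	-	b_cell	7,43,51,55,61,69,81
BCL-003	chr8	8006000	8006131	+	b_cell	7,11,29,35,53,69,103,121
BCL-004	chr8	8008000	8008101	+	b_cell	11,15,31,41,81
TCL-001	chr9	9002000	9002118	+	t_cell	19,39,67,79,81,87,111
TCL-002	chr9	9004000	9004118	-	t_cell	25,67,73,107
TCL-003	chr9	9006000	9006113	-	t_cell	23,27,47,51,53,59,61
TCL-004	chr9	9008000	9008116	-	t_cell	27,47,53,71,89,95
CD8-001	chr10	10002000	10002106	-	cd8_t	21,37,47,53,61,67
CD8-002	chr10	10004000	10004105	+	cd8_t	21,35,39,65,69,79,93,99
CD8-003	chr10	10006000	10006120	-	cd8_t	7,11,85,87,91,95,109
CD8-004	chr10	10008000	10008107	+	cd8_t	9,25,69,95
TRG-001	chr11	11002000	11002101	+	treg	13,29,67,73,87
TRG-002	chr11	11004000	11004137	+	treg	27,43,63,85,119
TRG-003	chr11	11006000	11006094	+	treg	23,45,47,49,53,59,67,85
TRG-004	chr11	11008000	11008101	-	treg	5,37,55,59,71
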