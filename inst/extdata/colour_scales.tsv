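scale_id	name	low	high	colour
1	deciles blue-red	0	9	#0000FF
1	deciles blue-red	10	19	#1C00E2
1	deciles blue-red	20	29	#3800C6
1	deciles blue-red	30	39	#5500AA
1	deciles blue-red	40	49	#71008D
1	deciles blue-red	50	59	#8D0071
1	deciles blue-red	60	69	#AA0055
1	deciles blue-red	70	79	#C60038
1	deciles blue-red	80	89	#E2001C
1	deciles blue-red	90	100	#FF0000
2	deciles greyscale	0	9	#F0F0F0
2	deciles greyscale	10	19	#D5D5D5
2	deciles greyscale	20	29	#BABABA
2	deciles greyscale	30	39	#A0A0A0
2	deciles greyscale	40	49	#858585
2	deciles greyscale	50	59	#6A6A6A
2	deciles greyscale	60	69	#505050
2	deciles greyscale	70	79	#353535
2	deciles greyscale	80	89	#1A1A1A
2	deciles greyscale	90	100	#000000
3	deciles white-blue	0	9	#FFFFFF
3	deciles white-blue	10	19	#E2E2F2
3	deciles white-blue	20	29	#C6C6E5
3	deciles white-blue	30	39	#AAAAD8
3	deciles white-blue	40	49	#8D8DCB
3	deciles white-blue	50	59	#7171BE
3	deciles white-blue	60	69	#5555B1
3	deciles white-blue	70	79	#3838A4
3	deciles white-blue	80	89	#1C1C97
3	deciles white-blue	90	100	#00008B
4	deciles green-red	0	9	#008000
4	deciles green-red	10	19	#1C7100
4	deciles green-red	20	29	#386300
4	deciles green-red	30	39	#555500
4	deciles green-red	40	49	#714700
4	deciles green-red	50	59	#8D3800
4	deciles green-red	60	69	#AA2A00
4	deciles green-red	70	79	#C61C00
4	deciles green-red	80	89	#E20E00
4	deciles green-red	90	100	#FF0000
5	deciles yellow-red	0	9	#FFFF00
5	deciles yellow-red	10	19	#FFE200
5	deciles yellow-red	20	29	#FFC600
5	deciles yellow-red	30	39	#FFAA00
5	deciles yellow-red	40	49	#FF8D00
5	deciles yellow-red	50	59	#FF7100
5	deciles yellow-red	60	69	#FF5500
5	deciles yellow-red	70	79	#FF3800
5	deciles yellow-red	80	89	#FF1C00
5	deciles yellow-red	90	100	#FF0000
6	deciles white-red	0	9	#FFFFFF
6	deciles white-red	10	19	#F2E2E2
6	deciles white-red	20	29	#E5C6C6
6	deciles white-red	30	39	#D8AAAA
6	deciles white-red	40	49	#CB8D8D
6	deciles white-red	50	59	#BE7171
6	deciles white-red	60	69	#B15555
6	deciles white-red	70	79	#A43838
6	deciles white-red	80	89	#971C1C
6	deciles white-red	90	100	#8B0000
7	deciles blue-yellow-red	0	9	#0000FF
7	deciles blue-yellow-red	10	19	#3838C6
7	deciles blue-yellow-red	20	29	#71718D
7	deciles blue-yellow-red	30	39	#AAAA55
7	deciles blue-yellow-red	40	49	#E2E21C
7	deciles blue-yellow-red	50	59	#FFE200
7	deciles blue-yellow-red	60	69	#FFAA00
7	deciles blue-yellow-red	70	79	#FF7100
7	deciles blue-yellow-red	80	89	#FF3800
7	deciles blue-yellow-red	90	100	#FF0000
8	quintiles blue-red	0	19	#0000FF
8	quintiles blue-red	20	39	#3F00BF
8	quintiles blue-red	40	59	#7F007F
8	quintiles blue-red	60	79	#BF003F
8	quintiles blue-red	80	100	#FF0000
9	ventiles blue-red	0	4	#0000FF
9	ventiles blue-red	5	9	#0D00F1
9	ventiles blue-red	10	14	#1A00E4
9	ventiles blue-red	15	19	#2800D6
9	ventiles blue-red	20	24	#3500C9
9	ventiles blue-red	25	29	#4300BB
9	ventiles blue-red	30	34	#5000AE
9	ventiles blue-red	35	39	#5D00A1
9	ventiles blue-red	40	44	#6B0093
9	ventiles blue-red	45	49	#780086
9	ventiles blue-red	50	54	#860078
9	ventiles blue-red	55	59	#93006B
9	ventiles blue-red	60	64	#A1005D
9	ventiles blue-red	65	69	#AE0050
9	ventiles blue-red	70	74	#BB0043
9	ventiles blue-red	75	79	#C90035
9	ventiles blue-red	80	84	#D60028
9	ventiles blue-red	85	89	#E4001A
9	ventiles blue-red	90	94	#F1000D
9	ventiles blue-red	95	100	#FF0000
10	low-density blue-red	0	0	#BEBEBE
10	low-density blue-red	1	1	#0000FF
10	low-density blue-red	2	2	#1F00DF
10	low-density blue-red	3	3	#3F00BF
10	low-density blue-red	4	4	#5F009F
10	low-density blue-red	5	5	#7F007F
10	low-density blue-red	6	6	#9F005F
10	low-density blue-red	7	7	#BF003F
10	low-density blue-red	8	8	#DF001F
10	low-density blue-red	9	9	#FF0000
10	low-density blue-red	10	100	#8B0000
11	low-density green-red	0	0	#BEBEBE
11	low-density green-red	1	1	#008000
11	low-density green-red	2	2	#1F7000
11	low-density green-red	3	3	#3F6000
11	low-density green-red	4	4	#5F5000
11	low-density green-red	5	5	#7F4000
11	low-density green-red	6	6	#9F3000
11	low-density green-red	7	7	#BF2000
11	low-density green-red	8	8	#DF1000
11	low-density green-red	9	9	#FF0000
11	low-density green-red	10	100	#8B0000
12	GC content	0	29	#BEBEBE
12	GC content	30	30	#008000
12	GC content	31	31	#0D7900
12	GC content	32	32	#1A7200
12	GC content	33	33	#286B00
12	GC content	34	34	#356500
12	GC content	35	35	#435E00
12	GC content	36	36	#505700
12	GC content	37	37	#5D5000
12	GC content	38	38	#6B4A00
12	GC content	39	39	#784300
12	GC content	40	40	#863C00
12	GC content	41	41	#933500
12	GC content	42	42	#A12F00
12	GC content	43	43	#AE2800
12	GC content	44	44	#BB2100
12	GC content	45	45	#C91A00
12	GC content	46	46	#D61400
12	GC content	47	47	#E40D00
12	GC content	48	48	#F10600
12	GC content	49	49	#FF0000
12	GC content	50	100	#8B0000
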