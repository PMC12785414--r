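protein	water_id	run	residency_ns	censored	exit_region
mCherry	W1	1	0.93	FALSE	Reg 2
mCherry	W1	2	0.28	FALSE	Reg 1
mCherry	W1	3	0.5	FALSE	Reg 1
mCherry	W2	1	93.33	FALSE	Reg 2
mCherry	W2	2	122.05	FALSE	Reg 1
mCherry	W2	3	164.2	FALSE	Reg 2
mCherry	W3	1	112.26	FALSE	Reg 2
mCherry	W3	2	146.32	FALSE	Reg 1
mCherry	W3	3	168.45	FALSE	Reg 1
mCherry	W4	1	114.84	FALSE	Reg 1
mCherry	W4	2	128.37	FALSE	Reg 1
mCherry	W4	3	495.34	FALSE	Reg 1
mCherry	W5	1	11.71	FALSE	Reg 1
mCherry	W5	2	121.82	FALSE	Reg 1
mCherry	W5	3	1000	TRUE	NA
mCherry	W6	1	163.99	FALSE	Reg 2
mCherry	W6	2	41.97	FALSE	Reg 1
mCherry	W6	3	828.01	FALSE	Reg 1
mCoral	W_M66C	1	3.52	FALSE	Reg 4
mCoral	W_M66C	2	1.3	FALSE	Reg 4
mCoral	W_M66C	3	0.19	FALSE	Reg 4
mCoral	W1	1	7.1	FALSE	Reg 1
mCoral	W1	2	4.07	FALSE	Reg 1
mCoral	W1	3	7.6	FALSE	Reg 3
mCoral	W2	1	6.96	FALSE	Reg 4
mCoral	W2	2	4.46	FALSE	Reg 4
mCoral	W2	3	2.7	FALSE	Reg 4
mCoral	W3	1	2.52	FALSE	Reg 4
mCoral	W3	2	130.24	FALSE	Reg 2
mCoral	W3	3	9.06	FALSE	Reg 4
mCoral	W4	1	6.05	FALSE	Reg 4
mCoral	W4	2	9.17	FALSE	Reg 4
mCoral	W4	3	0.63	FALSE	Reg 4
mCoral	W5	1	6.04	FALSE	Reg 4
mCoral	W5	2	8.01	FALSE	Reg 4
mCoral	W5	3	4.58	FALSE	Reg 4
mCoral	W6	1	17.16	FALSE	Reg 1
mCoral	W6	2	55.22	FALSE	Reg 3
mCoral	W6	3	11.7	FALSE	Reg 1
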