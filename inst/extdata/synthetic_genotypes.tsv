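subject_id	A_1	A_2	B_1	B_2	C_1	C_2	DRB1_1	DRB1_2	DQB1_1	DQB1_2	DPB1_1	DPB1_2
S00001	A*02:01	A*06:01	B*01:01	B*02:01	C*01:01	C*08:01	DRB1*02:01	DRB1*01:01	DQB1*01:01	DQB1*03:01	DPB1*01:01	DPB1*02:01
S00002	A*02:01	A*02:01	B*04:01	B*02:01	C*05:01	C*04:01	DRB1*01:01	DRB1*07:01	DQB1*01:01	DQB1*02:01	DPB1*01:01	DPB1*01:01
S00003	A*01:01	A*05:01	B*01:01	B*03:01	C*04:01	C*01:01	DRB1*07:01	DRB1*03:01	DQB1*01:01	DQB1*08:01	DPB1*06:01	DPB1*03:01
S00004	A*02:01	A*02:01	B*01:01	B*06:01	C*01:01	C*06:01	DRB1*02:01	DRB1*02:01	DQB1*02:01	DQB1*02:01	DPB1*01:01	DPB1*03:01
S00005	A*01:01	A*02:01	B*01:01	B*02:01	C*06:01	C*03:01	DRB1*04:01	DRB1*01:01	DQB1*01:01	DQB1*08:01	DPB1*02:01	DPB1*01:01
S00006	A*03:01	A*04:01	B*02:01	B*04:01	C*02:01	C*01:01	DRB1*01:01	DRB1*06:01	DQB1*01:01	DQB1*01:01	DPB1*01:01	DPB1*05:01
S00007	A*02:01	A*03:01	B*02:01	B*01:01	C*06:01	C*06:01	DRB1*03:01	DRB1*02:01	DQB1*03:01	DQB1*01:01	DPB1*03:01	DPB1*06:01
S00008	A*01:01	A*01:01	B*02:01	B*04:01	C*08:01	C*01:01	DRB1*07:01	DRB1*08:01	DQB1*02:01	DQB1*01:01	DPB1*02:01	DPB1*01:01
S00009	A*02:01	A*01:01	B*02:01	B*02:01	C*01:01	C*01:01	DRB1*06:01	DRB1*02:01	DQB1*01:01	DQB1*03:01	DPB1*04:01	DPB1*03:01
S00010	A*06:01	A*01:01	B*08:01	B*01:01	C*03:01	C*01:01	DRB1*01:01	DRB1*01:01	DQB1*01:01	DQB1*03:01	DPB1*03:01	DPB1*03:01
S00011	A*07:01	A*01:01	B*06:01	B*03:01	C*03:01	C*03:01	DRB1*04:01	DRB1*01:01	DQB1*02:01	DQB1*03:01	DPB1*02:01	DPB1*02:01
S00012	A*02:01	A*01:01	B*05:01	B*02:01	C*01:01	C*06:01	DRB1*07:01	DRB1*04:01	DQB1*04:01	DQB1*02:01	DPB1*01:01	DPB1*02:01
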