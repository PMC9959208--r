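pattern	motif	pairs
C1-C2-C3C4-C5-C6	ICK6	1-4,2-5,3-6
C1-C2-C3C4-C5-C6-C7-C8	ICK8	1-4,2-5,3-8,6-7
C1-C2-C3C4-C5-C6-C7-C8-C9-C10	FamA10	1-4,2-5,3-7,6-9,8-10
C1-C2-C3-C4C5-C6-C7-C8-C9-C10-C11-C12-C13-C14	FamI14	1-5,2-6,3-10,4-9,7-8,11-12,13-14
C1-C2-C3-C4-C5-C6-C7-C8	FamJ8	1-4,2-8,3-7,5-6
C1-C2-C3-C4-C5-C6	DDH	1-3,2-5,4-6
C1-C2-C3-C4-C5-C6	Kunitz	1-6,2-4,3-5
C1-C2	SS1	1-2
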