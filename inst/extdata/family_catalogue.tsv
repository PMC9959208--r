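family	template_id	framework	propeptide	amidation	mature_core	signal_template	pro_template
A	A1	C1-C2-C3C4-C5-C6-C7-C8-C9-C10	none	none	IWCHWWCKTHNCCWVCGSDHPNCPAFCLGCYSFFHVCISPCQEW	MTDSTFFFFVFFVDNGQA	
B	B1	C1-C2-C3C4-C5-C6C7-C8-C9-C10	none	none	IVCYNCVTSYLKCCTSLSCKDNRTCCFLLVICNQCWIHCMAN	MQNNTSTDDSLVFFFIFIDQGNS	
C	C1	C1-C2-C3-C4-C5-C6C7-C8-C9-C10-C11-C12	none	none	KMSCWQHPMWCGTCDQHACWIEGCEICCQWSQICVLCKDSECGHEWCYICIQR	MQNSDDSIFLLLFIVQNGNA	
D	D1	C1-C2-C3C4-C5-C6	always	none	GCFGYTDCAVHVQNWVCCASMPFNTNCMLAKYGKCDVS	MSNDDDVLIIIILFNDGQA	NPNSNKKSAER
D	D2	C1-C2-C3C4-C5-C6-C7-C8	always	none	VKLCPTGPCDINVCCHQRMYMCYGYKNQCDHKSQQCDECLIW	MNSTSDDNTNILIFVLIIQDSQA	NNTAQTKTADGER
E	E1	C1-C2-C3C4-C5-C6-C7-C8	most	G	PCHMNQHCNRMACCEMENYGCKDMRCKGNDMKCFVGVNCMNS	MDSTSQLLIILILLNQANS	PSSQDSKSKDER
F	F1	C1-C2-C3C4-C5-C6-C7-C8	always	most	NHCKTHTCEDRCCKPQTCHFHDCWWTQKCEYYCHYV	MDTDTTTNNQVVIVLFFINDANS	GKQGHATESHR
G	G1	C1-C2-C3C4-C5-C6-C7-C8	some	none	DCIETCEQHEVFCCMRSVFCMGCGDPSCKSVHCKRM	MDTSDSNTQSNLLFIFVFVQNGNS	TKHHEEGR
H	H1	C1-C2-C3C4-C5-C6-C7-C8-C9	none	none	YHCGGCEGYAHLCCWSLCGDTGCRSHCNIWQCNKKQCEND	MSTSVLFFIIFFQQSQS	
H	H2	C1-C2-C3-C4C5-C6-C7-C8-C9-C10	none	none	PCMECRIRHCMNMCCMHDCHAFPHYCIYCGMMCMAQEWPCFPA	MDDQLLLVIVVLQNSQA	
H	H3	C1-C2-C3-C4C5-C6-C7-C8-C9-C10-C11-C12	none	G	PCYTFLCLNDVCWRACCSFFVPCYTDPCNMALCSLHLAVCPMCIKQQRACWAWCQRR	MSSNTLFVFFFFFNNGNS	
I	I1	C1-C2-C3-C4C5-C6-C7-C8-C9-C10-C11-C12-C13-C14	always	G	FFYCNFWCQRIKNKCEICCFTRCQNNKDDCNIKDTYCAMCFLAKRVCALSMMCMEELQCEQDVLTCHWMWRMCTRP	MSNDLVILFVLVNQSNS	STSKEEHR
J	J1	C1-C2-C3-C4-C5-C6-C7-C8	always	mixed	MAPCYTHCLDYGSKCGFCAWCMQWCMEFRKPCHRSNYHCQHN	MDQDDNQNVLLIFIIINNANS	HQNPSEETR
J	J2	C1-C2-C3C4-C5-C6-C7-C8	always	mixed	WMCLFQERQCHDAEICCHMECFNPACYTVCYTHICPDI	MNDDSDNTSLFILLVFVDQANA	NAHQPATQHEEDR
K	K1	C1-C2	none	none	SIVCAPQPSMSETSNLTREDNQYAAYFNLPQEWYNFQLCAQE	MQSQDTTNTTLLVILIIIQDGQA	
K	K2	C1-C2-C3-C4	none	none	LPICRTPNVISYMENCVTQHWQIMPGCVAKMPFAYDKCGTP	MNSDSTDNSVILFVVLVNNGNA	
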