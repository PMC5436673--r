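label	level
V1	0
V2	1
V3	2
VP	2
PIP	3
V3A	3
MDP	4
MIP	4
PO	4
MT	4
V4t	4
V4	4
DP	5
VOT	5
VIP	6
LIP	6
MSTd	6
MSTI	6
FST	6
PITd	6
PITv	6
7a	7
FEF	7
STPp	7
CITd	7
CITv	7
STPa	8
AITd	8
AITv	8
46	9
TF	9
TH	9
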