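# Default cortical neighbor relations between the 16 seed areas.
# One unordered pair per row; edit and pass via default_area_adjacency(path=).
area_a	area_b
V1	V2
V2	V3
V3	V4
V3	V3A/DP
V4	V4A
V4	V4t
V4A	OTd
V4A	V4t
OTd	PITd
OTd	PITv
PITd	PITv
PITv	OTS
MT	MST
MT	FST
MT	V4t
MST	FST
FST	V4t
V3A/DP	CIP
CIP	LIP
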