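# Published enriched-MCS query set (COVID-19 case): 18 SMARTS patterns in
# five chemotype clusters, with reported hit counts and targets.
# Columns: cluster<TAB>smarts<TAB>hits<TAB>targets
1	[#6](:[#7]:[#6]:[#7]-,:[#6]-,:[#6]-[#6]-[#6]):[#6]	53	PPIA_HUMAN
1	[#6](-,:[#6]-,:[#6]-[#6]-[#6]=[#6]-[#6])-,:[#6]-,:[#6]	5	PPIA_HUMAN
1	[#6]:,-[#6]-,:[#7]-,:[#6]:,-[#6]:,-[#6]:,-[#6]:[#6]:[#6]	1	PPIA_HUMAN
2	[#6]1:[#7]:[#6]:[#7]:[#6]2:[#6]:1:[#7]:[#6]:[#7]:2-[#6]1-[#8]-[#6]-[#6]-[#6]-1	36	R1AB_SARS2
2	[#7]1:[#6]:[#7]:[#6]2:[#6]:1:[#7]:[#6]:[#7]:[#6]:2	11	PPIA_HUMAN
2	[#6]1:[#7]:[#6]:[#7](-[#6]2-[#8]-[#6]-[#6]-[#6]-2):[#7]:1	3	PPIA_HUMAN
2	[#6]1:[#7]:[#6]:[#7]:[#6](:[#6]:1):[#7](:[#6])-[#6]1-[#8]-[#6]-[#6]-[#6]-1	2	PPIA_HUMAN
2	[#6]1(-[#6]2:[#6]:[#6]:[#6]3:[#6]:[#7]:[#6]:[#7]:[#7]:2:3)-[#8]-[#6]-[#6]-[#6]-1	1	R1AB_SARS2
3	[#7]1-[#6]-[#6]-[#7]-[#6]-[#6]-1	8	R1AB_SARS2
3	[#6]-:[#6]-:[#6](-[#6](=[#8])-[#7]-[#6](:-[#6]:-[#6]):-[#6]:-[#6])-:[#6]-:[#6]	4	R1AB_SARS2
3	[#6]1:[#6]:[#6]:[#6]2:[#6](:[#6]:1)-[#8]-[#6]-[#8]-2	3	R1AB_SARS2
3	[#6]1:[#7]:[#6]:[#6]:[#6]:[#6]:1	3	PPIA_HUMAN
3	[#6](-[#6]-[#6]1-[#6]-[#6]-[#7]-[#6]-1=[#8])-[#7]-[#6](=[#8])-[#6]	2	R1A_SARS, R1AB_SARS
3	[#6](-[#6]-[#6]1-[#6]-[#6]-[#7]-[#6]-1=[#8])-[#7]-[#6](=[#8])-[#6]-[#6]-[#6]1:[#6]:[#6]:[#6]:[#6]:[#6]:1	2	R1A_SARS, R1AB_SARS
4	[#6](-[#7]-[#6](=[#8])-[#6]1-[#6](-[#6]-[#6]-[#7]-1-[#6](=[#8])-[#6]-[#7]-[#6]=[#8])-[#6])-[#6]-[#6](=[#8])-[#7]-[#6]1-[#6]-[#6]-1	1	R1AB_SARS2
4	[#6](-[#7]-[#6](=[#8])-[#6]1-[#6]2-[#6]-[#6]-[#6]-[#6]-2-[#6]-[#7]-1)-[#6]-[#6](=[#8])-[#7]-[#6]1-[#6]-[#6]-1	1	R1AB_SARS2
4	[#7]1-[#6]-[#6]2-[#6](-[#6]-1-[#6](=[#8])-[#7]-[#6]-[#6]-[#6]1-[#6]-[#6]-[#6]-1)-[#6]-2	1	R1AB_SARS2
5	[#6]12-[#6]-[#6]3-[#6]-[#6](-[#6]-1)-[#6]-[#6](-[#6]-2)-[#6]-3	3	PPIA_HUMAN
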