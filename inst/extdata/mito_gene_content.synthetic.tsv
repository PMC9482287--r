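gene	class	Christisonia_kwangtungensis	Aeginetia_indica
atp1	core	retained	retained
atp4	core	retained	retained
atp6	core	retained	retained
atp8	core	retained	retained
atp9	core	retained	retained
ccmB	core	retained	retained
ccmC	core	retained	retained
ccmFc	core	retained	retained
ccmFn	core	retained	retained
cob	core	retained	retained
cox1	core	retained	retained
cox2	core	retained	retained
cox3	core	retained	retained
nad1	core	retained	retained
nad2	core	retained	retained
nad3	core	retained	retained
nad4	core	retained	retained
nad4L	core	retained	retained
nad5	core	retained	retained
nad6	core	retained	retained
nad7	core	retained	retained
nad9	core	retained	retained
matR	core	retained	retained
mttB	core	retained	retained
rps1	variable	retained	lost
rps2	variable	lost	lost
rps3	variable	retained	retained
rps4	variable	retained	retained
rps7	variable	retained	lost
rps10	variable	retained	retained
rps11	variable	lost	lost
rps12	variable	retained	retained
rps13	variable	retained	retained
rps14	variable	retained	retained
rps19	variable	lost	lost
rpl2	variable	retained	retained
rpl5	variable	retained	retained
rpl6	variable	retained	retained
rpl10	variable	retained	retained
rpl16	variable	retained	retained
sdh3	variable	retained	lost
sdh4	variable	retained	lost
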