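gene	detected
psbA	1
psbB	1
psbC	1
psaA	1
psaB	1
petB	1
petD	1
alpha	1
beta	1
C	1
B	1
HemA	1
HemL	1
HemB	1
HemC	1
HemD	1
HemE	1
HemF	1
HemN	1
HemY	1
chlH	1
chlM	1
chlE	1
DVR	0
por	0
chlG	0
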