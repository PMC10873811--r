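# visual similarity matrix configuration
l1I|	c1
O0	c2
S5	c3
Z2	c4
B8	c5
mn	c6
G6	c7
oc	c8
c1	c1	1
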