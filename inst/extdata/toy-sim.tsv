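x1	y1	1.0
x2	y3	0.6
x3	y2	0.6
x2	y2	0.5
x3	y3	0.5
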