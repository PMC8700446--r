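20
15
61
38
98
42
86
76
146
121
157
149
175
180
176
180
220
198
224
264
251
282
325
321
653
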