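0.11
0.30
0.40
0.45
0.59
0.63
0.70
0.71
0.74
0.77
0.94
1.06
1.17
1.23
1.23
1.24
1.43
1.46
1.49
1.74
1.82
1.86
1.97
2.23
2.37
2.46
2.63
3.46
4.36
4.73
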