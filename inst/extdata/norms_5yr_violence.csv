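bin,label,rate
1,<= -25,8.0
2,-24 to -19,9.0
3,-18 to -14,18.0
4,-13 to -8,19.0
5,-7 to 5,25.0
6,6 to 12,37.0
7,13 to 18,45.0
8,19 to 27,58.0
9,28+,80.0
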