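bin,female,male
1,37,72
2,9,67
3,12,43
4,8,48
5,3,40
6,7,39
7,1,24
8,3,31
9,0,34
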