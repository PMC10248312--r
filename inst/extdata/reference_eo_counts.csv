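bin,n_overall,E_overall,O_overall,n_male,E_male,O_male
1,87,7.0,1,62,5.0,1
2,64,5.8,2,58,5.2,2
3,53,9.5,3,42,7.6,3
4,48,6.7,3,42,5.9,3
5,32,8.0,2,30,7.5,2
6,43,15.9,1,37,13.7,1
7,21,9.5,2,20,9.0,2
8,30,17.4,3,28,16.2,3
9,27,21.6,5,27,21.6,5
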