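group,mean,sd,n
male,-4.81,19.1,398
female,-16.61,14.9,80
overall,-6.79,19.0,478
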