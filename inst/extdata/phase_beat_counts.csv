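phase,n_before,n_after
rest,14290,10878
exercise,21174,6566
recovery,17193,14419
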