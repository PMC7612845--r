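dose	n_tested	n_positive
500	6	1
1500	6	2
5000	5	4
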