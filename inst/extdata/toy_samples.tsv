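sample	population	phenotype	mean_depth
s1	popA	none	10
s2	popA	none	10
s3	popA	none	10
s4	popB	none	10
s5	popB	none	10
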