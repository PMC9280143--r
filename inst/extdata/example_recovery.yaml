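# example configuration for `phasefit simulate`
paradigm: gambling
p_ref_given_pos: 0.69
p_ref_given_neg: 0.57
n_subjects: 200
n_replicates: 100
seed: 1
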