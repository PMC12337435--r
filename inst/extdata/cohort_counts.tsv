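item	count
n_total	166774
n_male	70151
n_first_degree_relative	106282
n_second_degree_relative	33691
n_masld_cases	13167
n_masld_assessed	58466
n_focal_disorders	5
n_diseases	7
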