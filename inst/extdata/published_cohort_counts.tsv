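metric	count
n_snps	28913164
n_indels	3905781
n_total	32818945
n_burden_snps	18975
n_burden_indels	6969
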