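contrast	mean_fst_all_snps	mean_fst_outlier_snps
wild-wild	0.0314	0.1865
wild-selected	0.0936	0.3272
selected-selected	0.1490	0.3815
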