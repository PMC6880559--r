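# Printed marginal counts of the PCR validation of computational predictions
# (96 intergenerically ascertained loci genotyped across a 10-individual ingroup
# DNA panel), plus the post-filter re-validation counts.
key	value
n_loci	96
n_panel	10
n_predicted_filled	206
n_no_amplification	3
n_confirmed	145
n_false_prediction	58
n_false_loci_all_absent	22
n_false_calls_all_absent	43
n_false_negative_loci	7
n_false_prediction_postfilter	22
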