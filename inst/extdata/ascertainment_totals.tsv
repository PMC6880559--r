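# Genome-scale ascertainment totals: candidate loci present in the intergeneric
# individual and in 2..12 of the 12 ingroup individuals (absent from the outgroup),
# before and after the 30 bp 5'-flank read filter.
run	n_ascertained	n_fixed	n_polymorphic
prefilter	27700	14744	12956
postfilter	22875	10422	12453
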