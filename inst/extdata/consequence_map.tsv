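term	class
missense_variant	missense
stop_gained	lof
stop_lost	lof
splice_donor_variant	lof
splice_acceptor_variant	lof
frameshift_variant	lof
start_lost	lof
synonymous_variant	synonymous
stop_retained_variant	synonymous
intergenic_variant	intergenic
upstream_gene_variant	other
downstream_gene_variant	other
intron_variant	other
5_prime_UTR_variant	other
3_prime_UTR_variant	other
non_coding_transcript_exon_variant	other
regulatory_region_variant	other
missense	missense
lof	lof
synonymous	synonymous
intergenic	intergenic
other	other
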