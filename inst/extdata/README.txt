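# Synthetic example catalog: ids and ORs are invented for testing;
# format mirrors a GWAS index-locus catalog (SNP/CHR/BP/RISK_ALLELE/REPORTED_OR/PANEL/GENE).
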