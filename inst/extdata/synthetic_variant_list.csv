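protein,position,wt_aa,mut_aa,allele_count,allele_frequency,source
toy,2,A,T,1,4e-06,synthetic-example
toy,4,D,N,2,8e-06,synthetic-example
toy,5,E,K,1,4e-06,synthetic-example
toy,7,G,R,3,1.2e-05,synthetic-example
toy,9,I,V,5,2e-05,synthetic-example
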