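name	length	purine_notation	pyrimidine_notation	site_start	site_end
c-MYC_DS45	45	5'-agcagagggcgtgggggaaaagaaaaaagatccaccggtcgccac-3'	3'-tcgtctcccgcacccccttttcttttttctaggtggccagcggtg-5'	16	30
c-MYC_DS29-Hetero	29	5'-gcagagggcgtgggggaaaagaaaaaaga-3'	3'-cGtcTccCgcAccCcCtTtTcTtTtTtCt-Cy5-5'	15	29
c-MYC_DS19	19	5'-ggggaaaagaaaaaagatc-3'	3'-ccccttttcttttttctag-5'	3	17
FXN_DS19	19	5'-gggaagaagaagaagaatc-3'	3'-cccttcttcttcttcttag-5'	3	17
c-MYC_DS19-Hetero	19	5'-ggggaaaagaaaaaagatc-3'	3'-cCcCtTtTcTtTtTtCtAg-5'	3	17
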