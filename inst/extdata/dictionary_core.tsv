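# Offline concept-expansion dictionary, version 1.
# Format: phrase<TAB>expansion1|expansion2|...
# Phrase lookup is case-insensitive and hyphen/space-insensitive.
tgf beta	TGFbeta|transforming growth factor beta
signaling pathway	signal transduction|signaling pathway
osteosarcoma	osteosarcoma|osteogenic sarcoma
alp gene	ALP gene|alkaline phosphatase gene
breast cancer	breast cancer|breast neoplasms|breast carcinoma
gene expression	gene expression|transcriptional profiling
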