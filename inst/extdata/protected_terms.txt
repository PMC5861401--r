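# Terms protected against the light stemmer (MeSH headings and entry terms),
# version 1. Case-insensitive; multi-word phrases allowed.
neoplasms
breast neoplasms
diabetes mellitus
transforming growth factor beta
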