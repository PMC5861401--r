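# Self-defined question stopwords removed during query generation, version 1.
# These are dataset-search boilerplate words that carry no topical content.
database
databases
datasets
dataset
data
related
relate
relation
type
types
studies
study
search
find
across
mention
mentions
mentioning
i
a
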