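# Example S61 specific peptides (aminoacyl-tRNA synthetase markers).
# peptide<TAB>EC
FYALPQAPQ	6.1.1.12
ISRQLWWGH	6.1.1.9
FFWVARMIM	6.1.1.9
DTWFSSALWP	6.1.1.9
DDNGLPTER	6.1.1.9
TRFPPEPNGYLH	6.1.1.18
GEAAFYGPK	6.1.1.3
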