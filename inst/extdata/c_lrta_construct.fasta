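>C-LrtA construct | His-tagged C-terminal domain (residues 102-191) of LrtA, Synechocystis sp. PCC 6803
MGSSHHHHHHSSGPQQGLRQHGNVKTSEIVEDKPVEENLIGDRAPELPSEVLRMKYFAMP
PMAIEDALEQLQLVDHDFYMFRNKDTDEINVIYIRNHGGYGVIQPHQAS
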