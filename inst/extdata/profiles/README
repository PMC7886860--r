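Synthetic marker-protein alignments (one aligned FASTA per marker, gapless,
8 members at 15% divergence from a random ancestor; generated in-repo with a
fixed seed by scratch/make_profiles.R). They emulate the conservation
structure of the crAss-like marker roster (TerL, MCP, portal, gene75,
gene74, IHF_53, Ttub, Tstab, PDDEXK_a, primase, DnaB) plus the two
insert-domain profiles (Hint, endonuclease) and are NOT biological
sequences. manifest.tsv columns: name, file, marker_class, group_tags.
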