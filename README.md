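# crasskit

Discovery and annotation of crAss-like phage genomes from metagenomic
assemblies, at desk scale.

crAss-like phages — the most abundant viruses of the human gut, infecting
Bacteroidetes — assemble into circular contigs and show genomic features
that break standard annotation: stop-codon reassignment (TAG→Gln or
TGA→Trp, mostly in late genes), suppressor tRNAs, and genes shattered by
group I self-splicing introns and inteins. crasskit implements the full
analysis chain for such genomes:

* **Circularity** — detection of exact terminal direct repeats (50–200 bp,
  longest wins) and trimming to circular genomes (cMAGs).
* **Marker search** — position-specific scoring profiles over six-frame
  translations, as gapless local segments with empirically calibrated
  e-values (Gumbel tail fitted to shuffled-translation nulls); a
  readthrough mode translates stops as `X` so recoded genes still score.
* **Genetic-code inference** — in-frame TAA/TAG/TGA counts inside TerL,
  MCP and portal hits decide between the standard code, TAG→Gln and
  TGA→Trp (≥2 markers with ≥2 reassigned stops, none of the competing
  stop); code-aware ORF calling follows.
* **Split genes** — consecutive marker fragments merged and separators
  classified as intein (in-frame Hint-domain hit), intron (endonuclease
  hit or frame change) or unclassified.
* **Suppressor tRNAs** — anticodon classification (exactly TTA, CTA, TCA
  suppress TAA, TAG, TGA).
* **Species clustering** — k-mer-seeded, rotation-aware pairwise identity
  and 90%-identity / 90%-coverage single-linkage clusters; a tree-depth
  statistic (mean MRCA-to-leaf over mean root-to-leaf distance) quantifies
  within-group diversity.
* **Host assignment** — CRISPR spacer matching (one hit ≥90% of spacer
  positions, or two hits ≥80%; complete genomes preferred on ties), 75%
  taxonomy verification, and protein-match evidence (identity ≥50% over
  ≥66% of length) with per-phylum fold enrichment.
* **Abundance** — canonical 31-mer LCA classification of reads with
  Bracken-style redistribution of internal-node counts to genome leaves
  (largest-remainder rounding; exact conservation).
* **Pangenome** — gene families by profile class, else 0.4-similarity
  greedy cluster, else singleton; rarefaction over 1001 random orderings
  with 5/95 percentile bands.
* **Synthetic communities** — a first-class generator that plants every
  one of these signals (repeats, diverged markers, recoded regions,
  introns/inteins, suppressor tRNAs, CRISPR spacers with mutations, reads
  from an abundance vector) with serialized ground truth.

## Worked example

```r
library(crasskit)

# a recoded phage genome with planted truth
g <- generate_phage(phage_spec("demo", code = "TAG_to_Q"), seed = 42)
circ <- circularize(g$contig, "demo")
circ
#> <circular_genome> demo | 10000 bp circle, 100 bp terminal repeat

profs <- load_profiles()
dm <- detect_markers(circ$sequence, profs[c("TerL", "MCP", "portal")],
                     seed = 7)
infer_genetic_code(circ$sequence, dm$hits)
#> <code_assignment> genome -> TAG_to_Q (3 markers supporting)
#>   marker n_TAA n_TAG n_TGA
#> 1    MCP     0    10     0
#> 2 portal     0     6     0
#> 3   TerL     0     7     0
```

The three marker genes each carry multiple in-frame TAG codons and no
TGA/TAA, so the genome is called TAG→Gln with all three markers
supporting — after which `call_orfs(circ$sequence,
genetic_code_table("TAG_to_Q"))` recovers the full-length marker ORFs
that the standard code would shatter.

The end-to-end driver `run_pipeline(contigs, reads, spacers, out_dir)`
writes a workspace of TSV/GFF3 reports (cMAGs, code assignments, clusters,
groups, hosts, abundance, rarefaction) stamped with a config hash; a thin
CLI wrapper lives at `inst/exec/crasskit`.

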