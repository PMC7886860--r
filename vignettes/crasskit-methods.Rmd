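---
title: "crasskit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crasskit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crasskit is a desk-scale pipeline for the discovery and annotation of
crAss-like bacteriophage genomes in metagenomic assemblies. This vignette
explains the models behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic community generator
does and does not emulate, and the numerical choices and known limitations
a careful user should be aware of.

## The scientific problem

crAss-like phages are the most abundant viruses of the human gut. They
infect Bacteroidetes, assemble into circular (terminally redundant)
genomes, and show several unusual genomic features: stop-codon
reassignment (TAG read as glutamine, or TGA as tryptophan, mostly in
late genes), suppressor tRNAs, and — in some groups — a very high density
of group I self-splicing introns and inteins that fragment even core genes
such as the major capsid protein (MCP) or the large terminase subunit
(TerL). Recovering these genomes from assemblies and annotating them
correctly therefore requires a pipeline in which circularity detection,
marker search, genetic-code inference and split-gene reconstruction
cooperate.

Because no desk-scale rerun can reproduce an analysis of thousands of
public metagenomes, crasskit pairs every analytical stage with a synthetic
community generator that plants exactly the signals the stage detects,
with serialized ground truth. Validation is therefore recovery of planted
truth, plus small arithmetic identities that hold independently of data
scale.

## Circularity

A contig is treated as a complete circular genome (cMAG) when its first
and last L bases are exactly identical for some L in [50, 200] bp — the
signature of terminally redundant assembly. `find_terminal_repeat()`
checks every candidate length from 200 down and returns the longest hit;
`circularize()` trims the trailing copy. Two choices deserve note:

* **Exactness.** The overlap must be exact; no mismatches are tolerated.
  Approximate terminal overlaps are a non-goal.
* **Longest-wins.** When nested qualifying overlaps exist, the longest is
  trimmed, removing maximal redundancy. The alternative (shortest) would
  leave residual duplication that downstream k-mer stages would double
  count.

No rotation canonicalization is applied by default: downstream comparison
is rotation-aware. An optional flag rotates to the lexicographically
minimal rotation when byte-stable output across rotated inputs matters.

## Marker search with scoring profiles

Conserved marker proteins (TerL, MCP, portal, and companions) are detected
with position-specific scoring matrices built from bundled protein
alignments: per-column half-bit log-odds of observed residue frequencies
against Robinson–Robinson background frequencies, with a pseudocount of
0.5 × background added to each column and columns more than 50% gapped
dropped.

The scan is a **gapless local segment search**: for every diagonal of the
profile × six-frame-translation matrix, maximal positive-sum segments are
collected (Kadane scan). We deliberately use local segments rather than
fixed full-profile windows: fragments of split genes are much shorter than
the profile, and a full-length window could never report them. Local
segments retain score additivity (a segment's score is exactly the sum of
its per-column scores) while making fragment detection well-posed. Gapped
alignment is a non-goal; at the divergences the pipeline targets, gapless
scoring suffices, and the tests bound the error against a full
dynamic-programming oracle where relevant.

In **readthrough mode**, stop codons translate as `X`, which scores 0
(background) in every column: a stop-interrupted marker accrues score
across its stops. In normal mode stops are impassable. Readthrough can
therefore never lower the best score of a stop-broken marker — a property
the tests check.

**Significance** is calibrated empirically per genome: the maximum segment
score is measured on `n_null = 200` shuffles of the genome's own six-frame
translation, a Gumbel location/scale is fitted by moments, and e-values
follow the fitted tail. To keep 200 nulls affordable, each null replicate
subsamples at most `null_m = 3000` residues and the fitted location is
shifted by β·log(N/m), the standard extreme-value rescaling to the full
search space of N residues. The default cutoff is e < 0.05 — deliberately
relaxed, as marker discovery favours sensitivity; the calibration test
verifies that false positives on profile-free random sequence stay within
Poisson bounds of the nominal rate.

**The bundled profile library is synthetic.** Real marker alignments are
not shipped; `inst/extdata/profiles` holds alignments generated in-repo
with a fixed seed (files named `*.synthetic.afa`). Each emulates the
conservation structure of one marker class at 15% member divergence. The
TerL alignment additionally contains the five group reference sequences at
25% divergence from its ancestor — mirroring how real clade-wide
alignments span group-level diversity — and those references are bundled
alongside (`group_refs.synthetic.afa`). This width matters: with the
0.5 × background pseudocount, residues unobserved in a column score about
−8 half-bits, so a profile built only from near-identical sequences cannot
detect group-diverged members locally; including the group references in
the alignment restores local detection of short fragments without
inflating the false-positive rate.

## Genetic-code inference and ORF calling

Three code tables are supported: standard, TAG→Gln, TGA→Trp. TAA is never
a reassignment candidate (only TAG and TGA reassignments are observed in
this clade), though TAA-suppressor tRNAs are still flagged.

`infer_genetic_code()` counts in-frame TAA/TAG/TGA inside the readthrough
hits of the evidence markers (TerL, MCP, portal). The decision rule: at
least 2 markers each containing at least 2 in-frame TAG, with zero
in-frame TGA overall, calls TAG→Gln; symmetrically for TGA→Trp; anything
else is standard. The evidence type (standard stops inside nearly
ubiquitous marker genes) is the published heuristic; the counts (2 and 2)
are this package's quantification, chosen so that a single mutational
artifact can never flip a genome's code while two independent markers with
repeated in-frame stops always can. Inference is per-genome; per-marker
counts are reported so regional (late-gene) recoding remains visible, but
regional segmentation is not performed.

`call_orfs()` is a deliberately simple caller: maximal stop-free codon
spans per frame under the active code table, gene start at the first ATG
(fallback GTG, then TTG), spans shorter than 60 codons dropped, and the
terminating stop codon included in the reported interval. There is no
coding-statistics model — unnecessary for synthetic genomes and fully
specified, which lets an exhaustive enumeration oracle check every call.
Inference runs before split-gene detection, so a gene that combines
recoding with intron insertion is searched under its correct code.

## Split genes

`detect_split_genes()` merges consecutive same-marker hits within 15 kb
into one candidate split gene and classifies each separator:

* Hint-domain hit with preserved frame → **intein** (protein-level
  splicing requires an in-frame insert);
* endonuclease-domain hit, or a frame change between flanking fragments →
  **intron** (group I introns typically carry homing endonucleases and
  freely shift the downstream reading frame);
* otherwise → **unclassified**.

Fragment hits are gated at e < 1e-3 — tighter than the 0.05 discovery
gate — because genuine fragments of a present marker score far above this
while the tighter gate suppresses the occasional random hit that would
otherwise inflate the fragment count of an architecture call.

## Suppressor tRNAs

tRNA loci are consumed as annotations (interval + anticodon); covariance
model scanning is out of scope. A tRNA is a suppressor exactly when the
reverse complement of its anticodon is a standard stop codon; enumeration
of all 64 anticodons yields TTA (suppresses TAA), CTA (TAG) and TCA
(TGA). The pipeline flags suppressor-bearing genomes that show no codon
reassignment — the "pre-emergence" configuration from which a code switch
can later evolve.

## Species clustering and group assignment

`pairwise_similarity()` seeds with exact 21-mers, groups seeds by
diagonal, merges runs, extends ungapped with an X-drop, and reports
per-block identity. The subject is doubled (circular rotation) and both
strands are scanned. A minimum block length of 100 bp replaces a search
e-value as the spam filter — an e-value is tool-specific, while a length
floor plays the same role and is exactly testable. Indels are handled only
via block boundaries; the DP oracle in the tests bounds the resulting
identity error (within one point on mutation-only pairs).

Genomes are linked when best-hit identity ≥ 90% and query coverage ≥ 90%
in at least one direction (the published criterion's query/subject
asymmetry is unresolved; a both-directions mode is available by flag).
Species-level clusters are the connected components of the linkage graph —
so linkage is transitive by construction, which the A~B~C chain test
exercises.

`assign_group()` replaces phylogenetic placement (tree inference is out of
scope) with nearest-reference assignment: shared amino-acid 5-mer fraction
between the genome's TerL and the labeled group references, with the
margin to the runner-up exposed so unreliable calls are visible.

`group_depth_fraction()` computes, per group, the mean patristic distance
from the group's MRCA to its leaves divided by the mean root-to-leaf
depth — the within-group diversity statistic — from any rooted newick tree
with branch lengths.

## Host assignment

Spacer matching uses exact 12-mer seeds on both strands anchoring
full-spacer ungapped placements; identity is computed over the full spacer
length, so unmatched overhangs count as mismatches (stricter and
unambiguous). A source assembly qualifies with one hit at ≥ 90% of spacer
positions or two hits at ≥ 80% identity; among qualifying sources the
highest-scoring match wins (score = matches − mismatches), with ties
preferring completely sequenced genomes, then the lexicographically
smaller assembly id. The two-hit rule requires the hits to share an
assembly, not an array (the finer condition is unstated in the source
analysis). CRISPR evidence outranks protein evidence.

`verify_taxonomy()` walks ranks leaf-to-root and returns the lowest rank
containing at least 75% of translating-search hits. Protein-match
evidence counts reference pairs at identity ≥ 50% over ≥ 66% of the query
length (both inclusive) and reports per-phylum fold enrichment against the
reference composition.

## Abundance

`build_index()` maps canonical (strand-minimal) 31-mers to the LCA of all
genomes containing them; k = 31 is the standard discriminative length at
genome scale, and canonicalization makes classification strand-symmetric.
`classify_reads()` scores every root-to-leaf path by the read's k-mer
votes; the read goes to the leaf of the unique maximum-weight path, or to
the LCA of tied paths — the conservative (shallower) choice.

`redistribute()` moves internal-node counts down to genome leaves
proportionally to the leaves' unique (leaf-assigned) counts, splitting
equally when no descendant has unique counts, with largest-remainder
rounding so read totals are conserved exactly. Redistribution uses
within-run unique counts; a pooled multi-sample mode would simply sum
count tables first.

## Pangenome

Gene families are labeled with precedence profile class → cluster id →
unique singleton. Greedy clustering sorts proteins by length and joins
each to the first centroid whose similarity reaches 0.4. Similarity is the
fraction of the shorter sequence's positions covered by amino-acid 4-mers
shared with the centroid. A set-containment variant of the same 4-mer
statistic was rejected during design: at 20% member divergence its
expectation is 0.8⁴ ≈ 0.41, i.e. exactly at the threshold, so genuine
members fall below it about half the time; the coverage form sits near
0.65 for such members and near 0.01 for unrelated sequences, giving the
0.4 threshold a real margin on both sides.

`rarefaction()` draws 1001 random genome orderings (the published
protocol's count) and reports per-k median and 5/95 percentiles of
cumulative distinct-family counts, with nearest-rank percentiles (ranks 51
and 951 at n = 1001 — unambiguous and exact). Distinct families are
counted as a set union per genome prefix; the k = N value therefore equals
the true pangenome size in every ordering.

## The synthetic community generator

`generate_phage()` assembles: an i.i.d. uniform-nucleotide backbone at
configurable GC (the simplest null); marker CDSs obtained by
back-translating the profile consensus (TerL: the group reference) with
uniform synonymous codon choice after applying the requested amino-acid
divergence (one parameter controls detectability); an exact terminal
repeat; optional recoding; inserts; and tRNA loci. Defaults: 10 kb
genomes, 45% GC, 100 bp repeat, 15% marker divergence, markers TerL + MCP
+ portal. Real crAss-like genomes are 97–192 kb; 10 kb keeps every
synthetic cohort tractable while leaving all detection problems
structurally identical (the backbone-to-marker ratio, not absolute length,
drives difficulty).

Recoding rewrites a fraction (`recode_density`, default 5%) of the codons
in each recoded marker to the reassigned stop codon, preferring codons
that already encode the reassigned amino acid, with a floor of two per
marker — the floor matches the inference rule's minimum evidence, and the
density is a free parameter, not an inference target (no published density
exists). The truth record stores the realized protein.

Intron inserts are 450–900 bp with an optional frame shift and an
endonuclease-domain cassette (a 10%-diverged copy of the bundled
endonuclease consensus); intein inserts are in-frame Hint-domain
cassettes. Fragments between inserts are at least 40 codons — chosen so
that every fragment sits comfortably above the profile-search detection
limit at default divergence; shorter fragments would make architecture
recovery a coin flip rather than a test.

`generate_host()` embeds spacers (25–45 bp substrings of source phages,
mutated at exactly the requested number of positions) in a fixed-30-bp
repeat-spacer-…-repeat array. Mutations avoid one random 14 bp window so
each planted protospacer retains an exact seed-length stretch; without
this, spacers with 4–5 mutations in 30 bp often retain no exact 12-mer and
would be invisible to any seeded matcher — including the one this package
implements — by construction rather than by biology.

`generate_reads()` draws read origins multinomially from the abundance
vector, positions uniformly across the circular join, applies i.i.d.
substitution errors, and reverse-complements about half the reads. The
default community mix across groups (Alpha-Gamma 53.7%, Delta 18%,
Epsilon 15%, Zeta 11.7%, Beta 1.6%) reproduces the relative group
abundances reported for the human gut virome.

**What the generator does not emulate:** indel sequencing errors,
paired-end structure, realistic codon-usage bias, assembly artifacts,
strain-level mosaicism, and real protein families. Passing tests therefore
demonstrate that the algorithms implement their stated rules correctly and
recover planted signals at realistic signal-to-noise — not that the
pipeline's thresholds are optimal for any particular real dataset.

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; conversion to 1-based
  inclusive happens only at the GFF3 boundary.
* Every stochastic step takes an explicit seed; compiled kernels use a
  private RNG seeded from R's stream, so identical seeds give
  byte-identical outputs and the caller's RNG state is never disturbed.
* Contigs shorter than twice the minimum repeat length, genomes shorter
  than 3 × profile length, reads shorter than k, empty match tables and
  single-leaf groups all return defined absent/zero results rather than
  errors; truly contradictory inputs (an insert naming an absent marker, a
  spacer longer than its source, abundances not summing to 1) are rejected
  with messages.
* Largest-remainder apportionment breaks remainder ties toward the lower
  node index; cluster ids number components by first member in input
  order; both make reports byte-stable.

## Problem sizes used in validation

The shipped validation uses cohorts of 150 genomes (code inference), 52
(split genes), 200 contigs (circularity), 15 genomes (clustering), 50
phage–host links, and 100,000 reads over 15 genomes in 5 groups
(abundance) — sizes at which every stage's guarantee is measurable with
comfortable statistical margins on a single CPU.

## Known limitations

* Gapless extension under-calls identity on genuinely indel-rich pairs;
  at the 90% species threshold this is immaterial for substitutions-only
  divergence but untested against real indel spectra.
* Regional (late-gene-only) code inference is reported but not segmented.
* The Gumbel moment fit is slightly anti-conservative in the extreme
  tail; the discovery cutoff (0.05) and the architecture gate (1e-3) were
  chosen with that bias in mind.
* Group assignment margins are alignment-free heuristics, not posterior
  probabilities; treat low-margin calls as unassigned.
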