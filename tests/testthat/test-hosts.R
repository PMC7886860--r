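# Spacer matching, host assignment rules, taxonomy verification, protein
# evidence.

mk_match <- function(phage = "ph1", src = "asm", ident, complete = FALSE,
                     spacer_len = 30L) {
  mp <- as.integer(round(ident / 100 * spacer_len))
  data.frame(spacer_id = paste0(src, "_", seq_along(ident)),
             spacer_len = spacer_len, source_assembly = src,
             taxon_path = "Bacteria;Bacteroidetes;Bacteroides",
             completeness = ifelse(complete, "complete", "draft"),
             phage_id = phage, matched_positions = mp,
             identity = 100 * mp / spacer_len,
             score = mp - (spacer_len - mp), start = 0L, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("spacer matches report forced identities", {
  set.seed(61)
  genome <- crasskit:::random_dna(5000, 0.5)
  exact <- substr(genome, 1001, 1030)
  mut <- crasskit:::mutate_dna(exact, n_mut = 3)
  sp <- data.frame(spacer_id = c("s_exact", "s_mut3"),
                   sequence = c(exact, mut), source_assembly = "asm",
                   taxon_path = "Bacteria;Bacteroidetes",
                   completeness = "draft", stringsAsFactors = FALSE)
  m <- match_spacers(sp, c(ph = genome))
  expect_equal(m$identity[m$spacer_id == "s_exact"], 100)
  expect_equal(m$matched_positions[m$spacer_id == "s_mut3"], 27L)
  expect_equal(m$identity[m$spacer_id == "s_mut3"], 90)
  expect_error(match_spacers(data.frame(spacer_id = "x", sequence = "ACGT",
                                        source_assembly = "a",
                                        taxon_path = "B",
                                        completeness = "draft"),
                             c(ph = genome)), "\\[20, 60\\]")
})

test_that("generator-planted spacers are all recovered at truth identity", {
  g <- generate_phage(phage_spec("src"), seed = 62)
  phages <- setNames(substr(g$contig, 1, g$truth$circle_len), "src")
  hs <- host_spec("asmC", c("Bacteria", "Bacteroidetes"), "draft",
                  spacers = data.frame(source_phage = "src",
                                       mutations = c(0L, 2L, 4L),
                                       length = c(30L, 32L, 36L)))
  h <- generate_host(hs, phages, seed = 63)
  sp <- h$truth$spacers
  tab <- data.frame(spacer_id = sp$spacer_id, sequence = sp$sequence,
                    source_assembly = "asmC", taxon_path = "Bacteria;Bacteroidetes",
                    completeness = "draft", stringsAsFactors = FALSE)
  m <- match_spacers(tab, phages)
  expect_identical(nrow(m), 3L)
  # matched positions equal the exhaustive-alignment oracle
  for (i in seq_len(nrow(sp))) {
    want <- oracle_spacer_match(sp$sequence[i], phages[[1]])
    expect_identical(m$matched_positions[m$spacer_id == sp$spacer_id[i]],
                     want)
    expect_identical(want, sp$length[i] - sp$mutations[i])
  }
})

test_that("assignment rules (a) and (b) fire as specified", {
  # one 93% hit (28/30) from a draft genome: rule (a)
  a <- assign_host(mk_match(ident = 28 / 30 * 100))
  expect_identical(a$evidence, "crispr_one_hit_90")
  # two hits at 85% and 82% from one assembly: rule (b)
  b <- assign_host(mk_match(ident = c(85, 82)))
  expect_identical(b$evidence, "crispr_two_hits_80")
  expect_identical(b$n_support, 2L)
  # a single 80% hit qualifies under neither rule
  expect_null(assign_host(mk_match(ident = 80)))
  # adding an extra >=80% hit never disqualifies a rule-(a) source
  a2 <- assign_host(rbind(mk_match(ident = c(93, 81))))
  expect_identical(a2$evidence, "crispr_one_hit_90")
})

test_that("ties prefer completely sequenced genomes", {
  m <- rbind(mk_match(src = "zz_complete", ident = 93, complete = TRUE),
             mk_match(src = "aa_draft", ident = 93, complete = FALSE))
  w <- assign_host(m)
  expect_identical(w$source_assembly, "zz_complete")
  # equal score, both drafts: lexicographic assembly id breaks the tie
  m2 <- rbind(mk_match(src = "bb", ident = 93), mk_match(src = "aa", ident = 93))
  expect_identical(assign_host(m2)$source_assembly, "aa")
})

test_that("taxonomy verification walks up to the first safe rank", {
  # 9/10 hits in one order overrides the deposited label
  hits <- c(rep("Bacteria;Proteobacteria;Enterobacteriales", 9),
            "Bacteria;Proteobacteria;Pseudomonadales")
  v <- verify_taxonomy(hits)
  expect_identical(v$taxon, "Enterobacteriales")
  expect_false(v$at_root_warning)
  # all hits one species
  one <- verify_taxonomy(rep("Bacteria;Bacteroidetes;Bacteroides;B. fragilis", 5))
  expect_identical(one$taxon, "B. fragilis")
  # 60/40 split between two genera of one family resolves at the family
  mix <- c(rep("Bacteria;F1;GenusA", 6), rep("Bacteria;F1;GenusB", 4))
  expect_identical(verify_taxonomy(mix)$taxon, "F1")
  # monotone: a higher threshold never returns a more specific rank
  expect_gte(verify_taxonomy(mix, threshold = 60)$rank_depth,
             verify_taxonomy(mix, threshold = 90)$rank_depth)
  # nothing reaches the threshold at any rank: root with warning
  split2 <- c("A1;x", "A2;y", "A3;z", "A4;w")
  expect_true(verify_taxonomy(split2)$at_root_warning)
})

test_that("protein evidence counts inclusive thresholds and enrichment", {
  set.seed(64)
  aa <- function(n) paste(sample(names(crasskit:::AA_BACKGROUND), n, TRUE),
                          collapse = "")
  p1 <- aa(150)
  ref <- data.frame(protein_id = c("self", "far"),
                    sequence = c(p1, aa(150)),
                    phylum = c("Bacteroidetes", "Firmicutes"),
                    stringsAsFactors = FALSE)
  ev <- protein_host_evidence(c(q1 = p1), ref)
  expect_identical(ev$matches$subject_id, "self")
  expect_equal(ev$matches$identity, 100)
  expect_equal(ev$matches$coverage, 100)
  # exactly-at-threshold pair is counted (inclusive >=50% over >=66%)
  half <- paste0(substr(p1, 1, 100), aa(50))  # 100/150 identical
  ev2 <- protein_host_evidence(c(q2 = half), ref[1, , drop = FALSE],
                               identity_min = 50, coverage_min = 66)
  expect_identical(nrow(ev2$matches), 1L)
  expect_error(protein_host_evidence(c(q = p1), ref[0, ]), "empty")
})

test_that("fold enrichment mirrors the 11-fold Bacteroidetes scenario", {
  # a reference where one phylum holds 5.7% of proteins but receives 63% of
  # matches: enrichment = 0.63 / 0.057 ~ 11
  set.seed(65)
  aa <- function(n) paste(sample(names(crasskit:::AA_BACKGROUND), n, TRUE),
                          collapse = "")
  n_ref <- 35L
  n_bact <- 2L       # 2/35 = 5.7% of the database
  phyla <- c(rep("Bacteroidetes", n_bact), rep("other", n_ref - n_bact))
  seqs <- vapply(seq_len(n_ref), function(i) aa(80), character(1))
  ref <- data.frame(protein_id = sprintf("r%02d", seq_len(n_ref)),
                    sequence = seqs, phylum = phyla, stringsAsFactors = FALSE)
  # 19 queries: 12 near-identical to Bacteroidetes proteins, 7 to others
  queries <- c(vapply(1:12, function(i)
                 crasskit:::mutate_protein(seqs[(i %% n_bact) + 1L], 0.05),
                 character(1)),
               vapply(1:7, function(i)
                 crasskit:::mutate_protein(seqs[n_bact + i], 0.05),
                 character(1)))
  names(queries) <- sprintf("q%02d", seq_along(queries))
  ev <- protein_host_evidence(queries, ref)
  bp <- ev$by_phylum[ev$by_phylum$phylum == "Bacteroidetes", ]
  expect_equal(bp$match_fraction, 12 / 19, tolerance = 1e-9)
  expect_equal(bp$fold_enrichment, (12 / 19) / (2 / 35), tolerance = 1e-9)
  expect_gt(bp$fold_enrichment, 10)
  expect_lt(bp$fold_enrichment, 12.5)
})
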