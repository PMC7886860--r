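# Profile construction and six-frame search.

test_that("profile of identical sequences scores its consensus maximally", {
  aln <- setNames(rep("MKKLVAYTRE", 4), paste0("s", 1:4))
  p <- build_profile(aln, "toy")
  expect_identical(p$length, 10L)
  expect_identical(p$consensus, "MKKLVAYTRE")
  # consensus attains the sum of per-column maxima
  expect_equal(score_sequence(p, p$consensus),
               sum(apply(p$scores, 2, max)))
})

test_that("scores are half-bit log-odds vs background and gappy columns drop", {
  aa20 <- names(crasskit:::AA_BACKGROUND)
  aln <- setNames(paste0(aa20, "A"), paste0("s", seq_along(aa20)))
  p <- build_profile(aln, "uniform")
  # log-odds identity: column 1 sees each residue once with 0.5*bg pseudocount
  bg <- crasskit:::AA_BACKGROUND
  want <- 2 * log2(((1 + 0.5 * bg) / 20.5) / bg)
  expect_equal(p$scores[aa20, 1], want, tolerance = 1e-12)
  # a column whose frequencies equal the background scores exactly zero
  expect_equal(max(abs(2 * log2(((20 * bg + 0.5 * bg) / 20.5) / bg))), 0,
               tolerance = 1e-12)
  gappy <- setNames(c("M-K", "M-K", "MAK", "M-K"), paste0("g", 1:4))
  expect_identical(build_profile(gappy, "gap")$length, 2L)
  expect_error(build_profile(character(0), "x"), "at least 2")
})

test_that("window scores are additive over per-column scores", {
  p <- test_profiles("TerL")$TerL
  set.seed(31)
  prot <- paste(sample(names(crasskit:::AA_BACKGROUND), p$length, TRUE),
                collapse = "")
  rows <- crasskit:::aa_to_rows(prot) + 1L
  naive <- sum(vapply(seq_len(p$length),
                      function(j) p$scores[rows[j], j], numeric(1)))
  expect_equal(score_sequence(p, prot), naive)
})

test_that("a planted consensus CDS is found at its interval", {
  p <- test_profiles("portal")$portal
  set.seed(32)
  cds <- paste(crasskit:::back_translate(p$consensus), collapse = "")
  genome <- paste0(crasskit:::random_dna(3000, 0.5), cds,
                   crasskit:::random_dna(3000, 0.5))
  hits <- search_genome(genome, p, seed = 5)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$aa_score), ]
  expect_lt(best$evalue, 0.05)
  expect_lt(abs(best$start - 3000), 30)
  expect_lt(abs(best$end - (3000 + nchar(cds))), 30)
  expect_identical(best$frame, 1L)
})

test_that("detection survives 20% divergence but not 80%", {
  p <- test_profiles("TerL")$TerL
  set.seed(33)
  for (div in c(0.2, 0.8)) {
    prot <- crasskit:::mutate_protein(p$consensus, div)
    cds <- paste(crasskit:::back_translate(prot), collapse = "")
    genome <- paste0(crasskit:::random_dna(2500, 0.5), cds,
                     crasskit:::random_dna(2500, 0.5))
    hits <- search_genome(genome, p, seed = 6)
    if (div == 0.2) expect_gte(nrow(hits), 1L)
    else expect_identical(nrow(hits), 0L)
  }
})

test_that("a minus-strand marker is found in a negative frame with equal score", {
  p <- test_profiles("MCP")$MCP
  set.seed(34)
  prot <- crasskit:::mutate_protein(p$consensus, 0.1)
  cds <- paste(crasskit:::back_translate(prot), collapse = "")
  left <- crasskit:::random_dna(2000, 0.5)
  right <- crasskit:::random_dna(2000, 0.5)
  fwd <- paste0(left, cds, right)
  rev <- paste0(left, revcomp(cds), right)
  h_f <- search_genome(fwd, p, seed = 7)
  h_r <- search_genome(rev, p, seed = 7)
  expect_gt(nrow(h_f), 0L); expect_gt(nrow(h_r), 0L)
  bf <- h_f[which.max(h_f$aa_score), ]; br <- h_r[which.max(h_r$aa_score), ]
  expect_gt(bf$frame, 0L)
  expect_lt(br$frame, 0L)
  expect_equal(bf$aa_score, br$aa_score, tolerance = 1e-9)
})

test_that("readthrough never lowers the best score of a stop-broken marker", {
  p <- test_profiles("TerL")$TerL
  set.seed(35)
  cods <- crasskit:::back_translate(p$consensus)
  cods[c(40, 80, 120)] <- "TAG"   # stop-interrupted marker
  genome <- paste0(crasskit:::random_dna(2000, 0.5),
                   paste(cods, collapse = ""),
                   crasskit:::random_dna(2000, 0.5))
  h_rt <- search_genome(genome, p, readthrough = TRUE, seed = 8)
  h_plain <- search_genome(genome, p, readthrough = FALSE, seed = 8)
  best <- function(h) if (nrow(h)) max(h$aa_score) else 0
  expect_gte(best(h_rt), best(h_plain))
})

test_that("empirical e-values are calibrated on profile-free random DNA", {
  profs <- test_profiles(c("TerL", "IHF_53"))
  set.seed(36)
  fp <- 0L
  runs <- 40L
  for (i in seq_len(runs)) {
    g <- crasskit:::random_dna(5000, 0.45)
    for (p in profs) fp <- fp + nrow(search_genome(g, p, readthrough = TRUE,
                                                   seed = i))
  }
  # expectation 0.05 per profile per genome; Poisson 99.5% upper bound
  lambda <- 0.05 * runs * length(profs)
  expect_lte(fp, qpois(0.995, lambda))
})

test_that("detect_markers reports exactly the planted marker panel", {
  profs <- test_profiles(c("TerL", "MCP", "portal", "gene75", "IHF_53"))
  g <- generate_phage(phage_spec("pm", markers = c("TerL", "MCP", "portal")),
                      seed = 61)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  dm <- detect_markers(seqc, profs, seed = 9, genome_id = "pm")
  present <- dm$table$profile_name[dm$table$present]
  expect_setequal(present, c("TerL", "MCP", "portal"))
  expect_error(detect_markers("", profs), "empty")
})

test_that("conservation matrix equals the planted incidence matrix", {
  profs <- test_profiles(c("TerL", "MCP", "portal", "gene75"))
  panel <- list(a = c("TerL", "MCP", "portal"),
                b = c("TerL", "portal"),
                c = c("TerL", "MCP", "gene75"))
  genomes <- vapply(names(panel), function(id) {
    g <- generate_phage(phage_spec(id, markers = panel[[id]]),
                        seed = 70 + match(id, names(panel)))
    substr(g$contig, 1, g$truth$circle_len)
  }, character(1))
  cm <- conservation_matrix(genomes, profs, seed = 10)
  want <- t(vapply(panel, function(m) names(profs) %in% m,
                   logical(length(profs))))
  colnames(want) <- names(profs)
  expect_identical(cm, want)
})
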