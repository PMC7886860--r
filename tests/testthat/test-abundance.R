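# k-mer LCA index, read classification, redistribution, group summaries.

toy_tree <- function() {
  # root(1) -> g1(2), g2(3); g1 -> A(4), B(5); g2 -> C(6)
  taxonomy_tree(data.frame(
    node_id = 1:6, parent_id = c(0L, 1L, 1L, 2L, 2L, 3L),
    rank = c("root", "group", "group", "genome", "genome", "genome"),
    name = c("root", "g1", "g2", "A", "B", "C"),
    genome_id = c(NA, NA, NA, "A", "B", "C"),
    group = c(NA, "g1", "g2", NA, NA, NA), stringsAsFactors = FALSE))
}

test_that("index contents equal an exhaustive dictionary on small genomes", {
  set.seed(71)
  k <- 15L
  shared <- crasskit:::random_dna(60, 0.5)
  genomes <- c(A = paste0(crasskit:::random_dna(150, 0.5), shared),
               B = paste0(shared, crasskit:::random_dna(150, 0.5)),
               C = crasskit:::random_dna(200, 0.5))
  tree <- toy_tree()
  idx <- build_index(genomes, tree, k = k)
  dict <- oracle_kmer_index(genomes, tree, k)
  kms <- ls(dict)
  expect_identical(idx$n_kmers, length(kms))
  got <- crasskit:::cpp_index_lookup(idx$ptr, kms)
  want <- vapply(kms, function(x) dict[[x]], integer(1))
  expect_identical(got, unname(want))
  # k-mer unique to one genome maps to its leaf; shared by siblings to parent
  expect_true(any(want == 2L))  # the shared block hits LCA(A,B) = node 2
  expect_true(all(want %in% c(2L, 4L, 5L, 6L)))
  expect_error(build_index(genomes, tree, k = 16L), "odd")
  expect_error(build_index(c(A = "ACGT", A = "ACGT"), tree), "duplicate")
})

test_that("read classification follows unique, chimeric and alien cases", {
  set.seed(72)
  k <- 15L
  genomes <- c(A = crasskit:::random_dna(400, 0.5),
               B = crasskit:::random_dna(400, 0.5),
               C = crasskit:::random_dna(400, 0.5))
  tree <- toy_tree()
  idx <- build_index(genomes, tree, k = k)
  leafA <- tree$nodes$node_id[match("A", tree$nodes$genome_id)]
  # unique read -> leaf A; its reverse complement -> same node
  rd <- substr(genomes[["A"]], 51, 150)
  expect_identical(unname(classify_reads(rd, idx)), leafA)
  expect_identical(unname(classify_reads(revcomp(rd), idx)), leafA)
  # chimeric read half A / half sibling B -> their parent; pick a junction
  # whose spanning k-mers are database-absent so the A/B votes tie exactly
  chim <- NULL
  for (off in seq(1, 300, by = 7)) {
    cand <- paste0(substr(genomes[["A"]], off, off + 59),
                   substr(genomes[["B"]], off, off + 59))
    jx <- substring(cand, (60 - k + 2):60, (60 + 1):(60 + k - 1))
    if (all(crasskit:::cpp_index_lookup(idx$ptr, jx) == 0L)) {
      chim <- cand
      break
    }
  }
  expect_false(is.null(chim))
  expect_identical(unname(classify_reads(chim, idx)), 2L)
  # random read and too-short read -> unclassified
  expect_identical(unname(classify_reads(crasskit:::random_dna(100, 0.5), idx)),
                   0L)
  expect_identical(unname(classify_reads("ACGTACGT", idx)), 0L)
})

test_that("redistribution is proportional, conservative and hand-checkable", {
  tree <- toy_tree()
  # parent 100 reads; leaf unique counts 30 and 10 -> +75 / +25
  out <- redistribute(c(`2` = 100L, `4` = 30L, `5` = 10L), tree)
  expect_identical(out, c(A = 105L, B = 35L, C = 0L))
  # all internal counts zero: identity on leaf counts
  out2 <- redistribute(c(`4` = 7L, `5` = 3L, `6` = 2L), tree)
  expect_identical(out2, c(A = 7L, B = 3L, C = 2L))
  # two-level cascade with root counts, zero-unique subtree splits equally
  out3 <- redistribute(c(`1` = 12L, `2` = 100L, `4` = 30L, `5` = 10L), tree)
  # root's 12: weights (30, 10, 0) -> 9, 3, 0; node2's 100 -> 75/25
  expect_identical(out3, c(A = 30L + 75L + 9L, B = 10L + 25L + 3L, C = 0L))
  expect_identical(sum(out3), 152L)
  # all-zero uniques below an internal node: equal split, exact conservation
  out4 <- redistribute(c(`2` = 7L), tree)
  expect_identical(sum(out4), 7L)
  expect_identical(unname(out4[c("A", "B")]), c(4L, 3L))
})

test_that("group summaries partition classified reads", {
  tree <- toy_tree()
  gs <- summarize_groups(c(A = 50L, B = 30L, C = 20L), tree)
  expect_equal(gs$fraction[gs$group == "g1"], 80)
  expect_equal(gs$fraction[gs$group == "g2"], 20)
  expect_equal(sum(gs$fraction), 100)
  one <- summarize_groups(c(A = 10L, B = 5L), setNames(c("g", "g"), c("A", "B")))
  expect_equal(one$fraction, 100)
})

test_that("abundance recovery: planted fractions within 1 point error-free", {
  set.seed(73)
  genomes <- setNames(vapply(1:4, function(i) crasskit:::random_dna(9000, 0.48),
                             character(1)), c("w", "x", "y", "z"))
  groups <- setNames(c("G1", "G1", "G2", "G3"), names(genomes))
  tree <- group_taxonomy(groups)
  idx <- build_index(genomes, tree)
  truth <- c(w = 0.45, x = 0.25, y = 0.2, z = 0.1)
  com <- community_spec(truth, n_reads = 30000, error_rate = 0, seed = 74)
  rr <- generate_reads(com, genomes)
  at <- abundance_table(rr$reads, idx)
  expect_identical(sum(at$leaf_counts) + at$n_unclassified, 30000L)
  got <- at$leaf_fractions[names(truth)]
  expect_true(all(abs(got - 100 * truth) < 1))
  grp <- setNames(at$group_fractions$fraction, at$group_fractions$group)
  expect_true(abs(grp[["G1"]] - 70) < 1)
})

test_that("abundance recovery degrades gracefully at 1% read error", {
  set.seed(75)
  genomes <- setNames(vapply(1:3, function(i) crasskit:::random_dna(9000, 0.48),
                             character(1)), c("x", "y", "z"))
  tree <- group_taxonomy(setNames(c("G1", "G2", "G3"), names(genomes)))
  idx <- build_index(genomes, tree)
  truth <- c(x = 0.6, y = 0.3, z = 0.1)
  com <- community_spec(truth, n_reads = 30000, error_rate = 0.01, seed = 76)
  rr <- generate_reads(com, genomes)
  at <- abundance_table(rr$reads, idx)
  got <- at$leaf_fractions[names(truth)]
  expect_true(all(abs(got - 100 * truth) < 2))
})

test_that("recovered fractions track random abundance vectors", {
  set.seed(77)
  genomes <- setNames(vapply(1:5, function(i) crasskit:::random_dna(8000, 0.5),
                             character(1)), paste0("g", 1:5))
  tree <- group_taxonomy(setNames(rep("G", 5), names(genomes)))
  idx <- build_index(genomes, tree)
  maes <- vapply(1:6, function(r) {
    ab <- rgamma(5, 1); ab <- ab / sum(ab)
    names(ab) <- names(genomes)
    com <- community_spec(ab, n_reads = 20000, seed = 500 + r)
    rr <- generate_reads(com, genomes)
    at <- abundance_table(rr$reads, idx)
    mean(abs(at$leaf_fractions[names(ab)] - 100 * ab))
  }, numeric(1))
  expect_lt(mean(maes), 1.5)
})
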