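# Code-aware ORF calling, code inference, split genes, orchestration.

test_that("stop-codon semantics follow the code table on a constructed gene", {
  set.seed(41)
  # 70 sense codons, a TAG, then 70 more sense codons and a TAA
  sense <- function(n) paste(crasskit:::back_translate(
    paste(sample(setdiff(names(crasskit:::AA_BACKGROUND), "M"), n, TRUE),
          collapse = "")), collapse = "")
  gene <- paste0("ATG", sense(70), "TAG", sense(70), "TAA")
  pad <- crasskit:::random_dna(200, 0.5)
  genome <- paste0(pad, gene, pad)
  covers <- function(calls) calls[calls$start == 200L & calls$strand == "+", ]
  std <- call_orfs(genome, genetic_code_table("standard"), min_len = 100L)
  expect_identical(nrow(covers(std)), 0L)  # TAG truncates both halves below 100
  alt <- covers(call_orfs(genome, genetic_code_table("TAG_to_Q"),
                          min_len = 100L))
  expect_identical(nrow(alt), 1L)
  expect_identical(alt$end, 200L + nchar(gene))
  expect_identical(substr(alt$protein, 72, 72), "Q")
  expect_false(grepl("\\*", substr(alt$protein, 1, nchar(alt$protein) - 1)))
})

test_that("a planted 300-codon ORF yields exactly one call at its interval", {
  set.seed(42)
  prot <- paste0("M", paste(sample(names(crasskit:::AA_BACKGROUND), 299, TRUE,
                                   prob = crasskit:::AA_BACKGROUND),
                            collapse = ""))
  cds <- paste0(paste(crasskit:::back_translate(prot), collapse = ""), "TAA")
  genome <- paste0(crasskit:::random_dna(600, 0.5), cds,
                   crasskit:::random_dna(600, 0.5))
  calls <- call_orfs(genome, genetic_code_table("standard"), min_len = 150L)
  hit <- calls[calls$start <= 600 & calls$end >= 600 + nchar(cds), ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$strand, "+")
})

test_that("calls agree with brute-force start-stop enumeration", {
  set.seed(43)
  for (code_id in c("standard", "TAG_to_Q")) {
    code <- genetic_code_table(code_id)
    for (i in 1:15) {
      g <- crasskit:::random_dna(5000, runif(1, 0.35, 0.6))
      got <- call_orfs(g, code, min_len = 30L)
      want <- oracle_orfs(g, code, min_len = 30L)
      expect_identical(got[, c("start", "end", "strand")],
                       structure(want, row.names = seq_len(nrow(want))))
    }
  }
})

test_that("code inference recovers planted codes and reports evidence", {
  profs <- test_profiles(c("TerL", "MCP", "portal"))
  for (code in c("standard", "TAG_to_Q", "TGA_to_W")) {
    g <- generate_phage(phage_spec(code, code = code), seed = 150)
    seqc <- substr(g$contig, 1, g$truth$circle_len)
    dm <- detect_markers(seqc, profs, seed = 3, genome_id = code)
    ca <- infer_genetic_code(seqc, dm$hits)
    expect_identical(ca$code_id, code)
    if (code == "TAG_to_Q") {
      expect_gte(ca$n_markers_supporting, 2L)
      expect_true(all(ca$evidence$n_TGA == 0L))
    }
  }
  # no marker hits: standard with a no-evidence flag
  ca0 <- infer_genetic_code("ACGT", crasskit:::empty_hits())
  expect_identical(ca0$code_id, "standard")
  expect_true(ca0$no_evidence)
})

test_that("a genome translatable only under TAG_to_Q is handled like Eld241-t0_s_1", {
  # whole genome recoded, markers dense with in-frame TAG only
  profs <- test_profiles(c("TerL", "MCP", "portal"))
  g <- generate_phage(phage_spec("eld", code = "TAG_to_Q",
                                 recoded_region = "whole",
                                 recode_density = 0.08), seed = 151)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  dm <- detect_markers(seqc, profs, seed = 4, genome_id = "eld")
  ca <- infer_genetic_code(seqc, dm$hits)
  expect_identical(ca$code_id, "TAG_to_Q")
  # under the inferred code all marker ORFs are intact full-length
  calls <- call_orfs(seqc, genetic_code_table(ca$code_id))
  ml <- g$truth$marker_loci
  for (i in seq_len(nrow(ml)))
    expect_true(any(calls$start <= ml$start[i] + 3 & calls$end >= ml$end[i]))
  # and under the standard code none are
  calls_std <- call_orfs(seqc, genetic_code_table("standard"))
  for (i in seq_len(nrow(ml)))
    expect_false(any(calls_std$start <= ml$start[i] + 3 &
                       calls_std$end >= ml$end[i]))
})

test_that("split-gene architectures are reconstructed (intron-rich MCP)", {
  # five MCP fragments over two co-directed frames; three separators carry
  # endonuclease cassettes, the in-frame cassette-free one stays unclassified
  profs <- test_profiles()
  ins <- data.frame(marker = "MCP", kind = rep("intron", 4),
                    cassette = c(TRUE, TRUE, TRUE, FALSE),
                    frame_shift = c(TRUE, FALSE, TRUE, FALSE))
  g <- generate_phage(phage_spec("fig7a", length = 14000,
                                 inserts = ins), seed = 152)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  hits <- search_genome(seqc, profs$MCP, readthrough = TRUE, seed = 5)
  sg <- detect_split_genes(seqc, hits,
                           insert_profiles = profs[c("Hint", "endonuclease")],
                           seed = 6)
  expect_s3_class(sg, "split_gene")
  expect_identical(nrow(sg$fragments), 5L)
  expect_identical(sum(sg$separators$kind == "intron"), 3L)
  expect_identical(sum(sg$separators$kind == "unclassified"), 1L)
  expect_identical(length(unique(sign(sg$fragments$frame))), 1L)
  # fragments are disjoint and ordered
  expect_true(all(diff(sg$fragments$start) > 0))
  expect_true(all(sg$fragments$end[-5] <= sg$fragments$start[-1]))
})

test_that("in-frame intein-split TerL yields three fragments, two inteins", {
  profs <- test_profiles()
  ins <- data.frame(marker = "TerL", kind = c("intein", "intein"))
  g <- generate_phage(phage_spec("fig7b", length = 12000, code = "TAG_to_Q",
                                 inserts = ins), seed = 153)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  hits <- search_genome(seqc, profs$TerL, readthrough = TRUE, seed = 7)
  sg <- detect_split_genes(seqc, hits,
                           insert_profiles = profs[c("Hint", "endonuclease")],
                           code = genetic_code_table("TAG_to_Q"), seed = 8)
  expect_identical(nrow(sg$fragments), 3L)
  expect_identical(sg$separators$kind, c("intein", "intein"))
  expect_identical(length(unique(sg$fragments$frame)), 1L)
  # a contiguous marker is not reported as split
  g1 <- generate_phage(phage_spec("solid", length = 12000), seed = 154)
  s1 <- substr(g1$contig, 1, g1$truth$circle_len)
  h1 <- search_genome(s1, profs$TerL, readthrough = TRUE, seed = 9)
  expect_null(detect_split_genes(s1, h1,
                                 insert_profiles = profs[c("Hint", "endonuclease")],
                                 seed = 10))
})

test_that("removing planted separators restores a contiguous marker hit", {
  profs <- test_profiles()
  ins <- data.frame(marker = "portal", kind = c("intron", "intron"))
  g <- generate_phage(phage_spec("heal", length = 12000, inserts = ins),
                      seed = 155)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  it <- g$truth$inserts[order(-g$truth$inserts$start), ]
  healed <- seqc
  for (i in seq_len(nrow(it)))
    healed <- paste0(substr(healed, 1, it$start[i]),
                     substr(healed, it$end[i] + 1, nchar(healed)))
  h <- search_genome(healed, profs$portal, readthrough = TRUE, seed = 11)
  expect_null(detect_split_genes(healed, h,
                                 insert_profiles = profs[c("Hint", "endonuclease")],
                                 seed = 12))
})

test_that("annotation is idempotent for standard genomes and flags pre-emergent suppressors", {
  profs <- test_profiles(c("TerL", "MCP", "portal", "Hint", "endonuclease"))
  # suppressor tRNA present, no recoding: the pre-emergence case
  g <- generate_phage(phage_spec("pre", trnas = c("TTA", "TTG")), seed = 156)
  seqc <- substr(g$contig, 1, g$truth$circle_len)
  ann <- annotate_genome(seqc, profs, trna_annotations = g$truth$trnas,
                         genome_id = "pre", seed = 13)
  expect_identical(ann$code$code_id, "standard")
  expect_identical(ann$trnas$isotype, c("Sup", "Gln"))
  expect_identical(ann$trnas$suppressor_target[1], "TAA")
  # same calls as a direct standard-code run (inference changed nothing)
  direct <- call_orfs(seqc, genetic_code_table("standard"), genome_id = "pre")
  expect_identical(ann$genes, direct)
})
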