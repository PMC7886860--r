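# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (no seeded k-mer tricks, no kernels).

# Terminal repeat: direct comparison over every candidate length.
oracle_terminal_repeat <- function(contig, min_len = 50L, max_len = 200L) {
  n <- nchar(contig)
  best <- NA_integer_
  for (L in seq_len(min(max_len, n %/% 2L))) {
    if (L < min_len) next
    if (substr(contig, 1L, L) == substr(contig, n - L + 1L, n)) best <- L
  }
  if (!is.na(best) && n <= 2L * min_len) return(NA_integer_)
  best
}

# ORF enumeration: for every frame/strand, every maximal stop-free codon
# span, first-start selection; written independently of call_orfs.
oracle_orfs <- function(genome, code, min_len = 60L) {
  stops <- code$stop_codons
  n <- nchar(genome)
  res <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
    for (f in 1:3) {
      n_cod <- (nchar(s) - f + 1L) %/% 3L
      if (n_cod < 1L) next
      cods <- substring(s, f + 3L * (seq_len(n_cod) - 1L),
                        f + 3L * seq_len(n_cod) - 1L)
      stop_idx <- which(cods %in% stops)
      span_edges <- c(0L, stop_idx, n_cod + 1L)
      for (i in seq_len(length(span_edges) - 1L)) {
        a <- span_edges[i] + 1L; b <- span_edges[i + 1L] - 1L
        if (b - a + 1L < min_len) next
        has_stop <- span_edges[i + 1L] <= n_cod
        starts <- which(cods[a:b] == "ATG")
        if (!length(starts)) starts <- which(cods[a:b] == "GTG")
        if (!length(starts)) starts <- which(cods[a:b] == "TTG")
        if (!length(starts)) {
          if (a != 1L) next
          st <- a
        } else st <- a + starts[1] - 1L
        if (b - st + 1L < min_len) next
        last <- if (has_stop) b + 1L else b
        lo <- (f - 1L) + 3L * (st - 1L)
        hi <- (f - 1L) + 3L * last
        if (strand == "+") res <- rbind(res, data.frame(start = lo, end = hi,
                                                        strand = strand))
        else res <- rbind(res, data.frame(start = nchar(s) - hi,
                                          end = nchar(s) - lo,
                                          strand = strand))
      }
    }
  }
  if (is.null(res)) return(res)
  res[order(res$start, res$end), , drop = FALSE]
}

# Global alignment identity of a mutation-only genome pair (DP oracle).
oracle_pair_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")
  Biostrings::pid(al)
}

# Exhaustive k-mer -> LCA dictionary built with plain R containers.
oracle_kmer_index <- function(genomes, tree, k) {
  nodes <- tree$nodes
  leaf_of <- setNames(nodes$node_id, nodes$genome_id)
  ancestors <- function(v) {
    path <- v
    while (nodes$parent_id[v] != 0L) { v <- nodes$parent_id[v]; path <- c(path, v) }
    path
  }
  lca2 <- function(a, b) {
    pa <- rev(ancestors(a)); pb <- rev(ancestors(b))
    m <- min(length(pa), length(pb))
    common <- which(pa[seq_len(m)] == pb[seq_len(m)])
    pa[max(common)]
  }
  canon <- function(s) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    if (s < rc) s else rc
  }
  dict <- new.env(parent = emptyenv())
  for (id in names(genomes)) {
    g <- genomes[[id]]
    node <- leaf_of[[id]]
    for (i in seq_len(nchar(g) - k + 1L)) {
      km <- canon(substr(g, i, i + k - 1L))
      old <- dict[[km]]
      dict[[km]] <- if (is.null(old)) node else lca2(old, node)
    }
  }
  dict
}

# Exhaustive best ungapped placement of a spacer in a genome (both strands).
oracle_spacer_match <- function(spacer, genome) {
  L <- nchar(spacer); n <- nchar(genome)
  best <- -1L
  for (s in c(spacer,
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(spacer))))) {
    sch <- strsplit(s, "")[[1]]
    for (i in seq_len(n - L + 1L)) {
      m <- sum(sch == strsplit(substr(genome, i, i + L - 1L), "")[[1]])
      if (m > best) best <- m
    }
  }
  best
}

# Shared profile library (memoized inside the package).
test_profiles <- function(markers = NULL) {
  p <- crasskit:::cached_profiles()
  if (is.null(markers)) p else p[markers]
}
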