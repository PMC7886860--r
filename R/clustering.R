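# All-vs-all genome comparison, species-level linkage clustering, group
# assignment, and the within-group tree-depth statistic.

#' Pairwise genome similarity by seeded, ungapped local blocks
#'
#' Exact k-mer seeds are chained into collinear (same-diagonal) blocks with
#' ungapped X-drop extension; per-block identity is computed directly. The
#' subject is doubled so circular origin shifts (rotations) are handled, and
#' both subject strands are scanned. `best_hit_identity` is the identity of
#' the highest-scoring block; `query_coverage` is the fraction of query
#' positions covered by blocks with identity at or above `link_identity`.
#' Blocks shorter than `min_block` bp are discarded (the spam filter
#' standing in for a search-tool e-value gate).
#'
#' @param query,subject DNA strings.
#' @param k seed length (default 21).
#' @param min_block minimum chained block length in bp (default 100).
#' @param link_identity identity floor (percent) a block must meet to count
#'   towards coverage (default 90).
#' @param subject_circular double the subject to absorb rotations
#'   (default TRUE).
#' @return a list of class `pair_similarity`: `best_hit_identity`,
#'   `query_coverage` (both percent), `n_blocks`, `blocks` (data.frame).
#' @export
pairwise_similarity <- function(query, subject, k = 21L, min_block = 100L,
                                link_identity = 90, subject_circular = TRUE) {
  if (!nzchar(query) || !nzchar(subject))
    stop("pairwise_similarity: empty genome")
  subj <- if (subject_circular) paste0(subject, subject) else subject
  with_strand <- function(b, s) {
    b <- as.data.frame(b)
    b$strand <- rep(s, nrow(b))
    b
  }
  blocks <- rbind(
    with_strand(cpp_pairwise_blocks(toupper(query), toupper(subj), k,
                                    as.integer(min_block), 50L), "+"),
    with_strand(cpp_pairwise_blocks(toupper(query), revcomp(toupper(subj)), k,
                                    as.integer(min_block), 50L), "-"))
  if (nrow(blocks) == 0L) {
    return(structure(list(best_hit_identity = 0, query_coverage = 0,
                          n_blocks = 0L, blocks = blocks),
                     class = "pair_similarity"))
  }
  best <- blocks[which.max(blocks$score), ]
  good <- blocks[blocks$identity >= link_identity, , drop = FALSE]
  cov <- 0
  if (nrow(good)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = good$qstart + 1L,
                                           end = good$qend))
    cov <- 100 * sum(IRanges::width(ir)) / nchar(query)
  }
  structure(list(best_hit_identity = best$identity,
                 query_coverage = cov, n_blocks = nrow(blocks),
                 blocks = blocks),
            class = "pair_similarity")
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("<pair_similarity> best identity %.1f%%, coverage %.1f%% (%d blocks)\n",
              x$best_hit_identity, x$query_coverage, x$n_blocks))
  invisible(x)
}

#' Species-level linkage clustering of genomes
#'
#' Computes all-vs-all [pairwise_similarity()] and links a pair when the
#' best-hit identity meets `identity_min` and the query coverage meets
#' `coverage_min` in at least one direction (`bidirectional = TRUE` demands
#' both). Clusters are the connected components of the linkage graph;
#' singletons form their own clusters.
#'
#' @param genomes named character vector of genome sequences.
#' @param identity_min identity threshold, percent (default 90).
#' @param coverage_min query-coverage threshold, percent (default 90).
#' @param bidirectional require the criterion in both directions.
#' @param ... passed to [pairwise_similarity()].
#' @return a list with `clusters` (data.frame `genome_id`, `cluster_id`) and
#'   `pairs` (data.frame of directed pair statistics).
#' @export
build_linkage_clusters <- function(genomes, identity_min = 90,
                                   coverage_min = 90, bidirectional = FALSE,
                                   ...) {
  stopifnot(!is.null(names(genomes)))
  ids <- names(genomes)
  n <- length(ids)
  pairs <- NULL
  linked <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ps <- pairwise_similarity(genomes[[i]], genomes[[j]],
                              link_identity = identity_min, ...)
    ok <- ps$best_hit_identity >= identity_min &&
      ps$query_coverage >= coverage_min
    linked[i, j] <- ok
    pairs <- rbind(pairs, data.frame(
      query_id = ids[i], subject_id = ids[j],
      best_hit_identity = ps$best_hit_identity,
      query_coverage = ps$query_coverage, linked = ok,
      stringsAsFactors = FALSE))
  }
  adj <- if (bidirectional) linked & t(linked) else linked | t(linked)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # deterministic ids: number clusters by first member in input order
  first <- vapply(split(seq_len(n), comp), min, numeric(1))
  relabel <- rank(first)[as.character(comp)]
  clusters <- data.frame(genome_id = ids,
                         cluster_id = sprintf("cluster_%03d", relabel),
                         stringsAsFactors = FALSE)
  list(clusters = clusters, pairs = pairs)
}

#' Within-group tree-depth fraction
#'
#' For each group of leaves: the mean patristic distance from the group's
#' most recent common ancestor to its member leaves, divided by the mean
#' root-to-leaf distance over all leaves, as a percentage. A single-leaf
#' group returns 0 by convention (flagged by attribute `singleton`).
#'
#' @param tree an `ape::phylo` tree with branch lengths (rooted), or a path
#'   to / string of newick.
#' @param leaf_groups named character vector mapping leaf label -> group.
#' @return named numeric vector of percentages per group, with attribute
#'   `singleton` marking single-leaf groups.
#' @export
group_depth_fraction <- function(tree, leaf_groups) {
  if (is.character(tree)) tree <- read_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  miss <- setdiff(names(leaf_groups), tree$tip.label)
  if (length(miss))
    stop("leaves absent from tree: ", paste(miss, collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  d <- ape::dist.nodes(tree)
  mean_depth <- mean(d[root, seq_len(n_tip)])
  groups <- unique(leaf_groups)
  out <- numeric(length(groups)); names(out) <- groups
  singleton <- logical(length(groups)); names(singleton) <- groups
  for (g in groups) {
    leaves <- names(leaf_groups)[leaf_groups == g]
    tips <- match(leaves, tree$tip.label)
    if (length(tips) == 1L) { out[g] <- 0; singleton[g] <- TRUE; next }
    mrca <- ape::getMRCA(tree, tips)
    out[g] <- 100 * mean(d[mrca, tips]) / mean_depth
  }
  attr(out, "singleton") <- singleton
  out
}

# Amino-acid k-mer set of a protein string.
aa_kmers <- function(protein, k = 5L) {
  n <- nchar(protein)
  if (n < k) return(character(0))
  unique(substring(protein, seq_len(n - k + 1L), seq.int(k, n)))
}

#' Assign a genome to a crAss-like group by its TerL protein
#'
#' Nearest-reference assignment: the genome's TerL (translation of its best
#' readthrough TerL hit under the given code) is compared to labeled
#' reference TerL proteins by shared amino-acid 5-mer fraction; the label of
#' the closest reference wins, and the margin to the runner-up group is
#' reported (margin near 0 flags a low-confidence call).
#'
#' @param genome DNA string.
#' @param references named character vector, group label -> reference TerL
#'   protein (defaults to [group_references()]).
#' @param terl_profile TerL profile for the search (bundled by default).
#' @param code the genome's [genetic_code_table()].
#' @param seed integer seed.
#' @return a list: `group` (label or `NA` if no TerL), `margin`,
#'   `similarities` (named vector), `low_confidence`.
#' @export
assign_group <- function(genome, references = group_references(),
                         terl_profile = cached_profiles()$TerL,
                         code = genetic_code_table("standard"), seed = 1) {
  hits <- search_genome(genome, terl_profile, code = code, readthrough = TRUE,
                        seed = seed)
  if (nrow(hits) == 0L)
    return(list(group = NA_character_, margin = NA_real_,
                similarities = NULL, low_confidence = TRUE))
  b <- hits[which.max(hits$aa_score), ]
  seg <- substr(genome, b$start + 1L, b$end)
  if (b$strand == "-") seg <- revcomp(seg)
  prot <- gsub("\\*", "X", translate_dna(seg, code))
  qk <- aa_kmers(prot)
  sims <- vapply(references, function(ref) {
    rk <- aa_kmers(ref)
    if (!length(qk) || !length(rk)) return(0)
    length(intersect(qk, rk)) / min(length(qk), length(rk))
  }, numeric(1))
  ord <- order(sims, decreasing = TRUE)
  margin <- sims[ord[1]] - if (length(sims) > 1L) sims[ord[2]] else 0
  list(group = names(sims)[ord[1]], margin = unname(margin),
       similarities = sims, low_confidence = margin < 0.05)
}
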