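# k-mer LCA read classification and abundance redistribution.

#' Build a taxonomy tree
#'
#' @param nodes data.frame with columns `node_id` (integers 1..n),
#'   `parent_id` (0 for the root), `rank`, `name`, and optionally
#'   `genome_id` (set on leaves carrying genomes) and `group` (group label
#'   attached at a node).
#' @return validated object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  n <- nrow(nodes)
  if (!setequal(nodes$node_id, seq_len(n)))
    stop("node_id must be exactly 1..n")
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  if (sum(nodes$parent_id == 0L) != 1L) stop("tree must have a single root")
  if (is.null(nodes$genome_id)) nodes$genome_id <- NA_character_
  if (is.null(nodes$group)) nodes$group <- NA_character_
  gid <- nodes$genome_id[!is.na(nodes$genome_id)]
  if (anyDuplicated(gid)) stop("duplicate genome ids in tree")
  # depth computation doubles as a cycle check
  depth <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- i; d <- 0L
    while (nodes$parent_id[v] != 0L) {
      v <- nodes$parent_id[v]; d <- d + 1L
      if (d > n) stop("taxonomy tree contains a cycle")
    }
    depth[i] <- d
  }
  nodes$depth <- depth
  structure(list(nodes = nodes), class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree>", nrow(x$nodes), "nodes,",
      sum(!is.na(x$nodes$genome_id)), "genome leaves\n")
  invisible(x)
}

#' Build a two-level taxonomy (root -> groups -> genomes)
#'
#' @param genome_groups named character vector, genome id -> group label.
#' @return a `taxonomy_tree`.
#' @export
group_taxonomy <- function(genome_groups) {
  groups <- unique(genome_groups)
  n_grp <- length(groups)
  nodes <- data.frame(
    node_id = seq_len(1L + n_grp + length(genome_groups)),
    parent_id = c(0L, rep(1L, n_grp),
                  1L + match(genome_groups, groups)),
    rank = c("root", rep("group", n_grp),
             rep("genome", length(genome_groups))),
    name = c("root", groups, names(genome_groups)),
    genome_id = c(NA_character_, rep(NA_character_, n_grp),
                  names(genome_groups)),
    group = c(NA_character_, groups, rep(NA_character_, length(genome_groups))),
    stringsAsFactors = FALSE)
  taxonomy_tree(nodes)
}

#' Build the k-mer LCA index over a genome database
#'
#' Canonical (strand-minimal) k-mers of every genome map to the LCA of all
#' leaves containing them.
#'
#' @param genomes named character vector of genome sequences.
#' @param tree a [taxonomy_tree()] whose leaves carry all genome ids.
#' @param k odd k-mer length (default 31).
#' @return an object of class `kmer_index` (`ptr`, `k`, `tree`,
#'   `n_kmers`, `genome_ids`).
#' @export
build_index <- function(genomes, tree, k = 31L) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (k %% 2L == 0L) stop("k must be odd")
  if (anyDuplicated(names(genomes))) stop("duplicate genome ids")
  leaf_of <- setNames(tree$nodes$node_id, tree$nodes$genome_id)
  miss <- setdiff(names(genomes), names(leaf_of))
  if (length(miss))
    stop("genomes not attached to tree leaves: ", paste(miss, collapse = ", "))
  ptr <- cpp_build_kmer_index(unname(genomes),
                              as.integer(leaf_of[names(genomes)]),
                              as.integer(tree$nodes$parent_id), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), tree = tree,
                 n_kmers = cpp_index_size(ptr),
                 genome_ids = names(genomes)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k =", x$k, "|", x$n_kmers, "k-mers,",
      length(x$genome_ids), "genomes\n")
  invisible(x)
}

#' Classify reads against a k-mer LCA index
#'
#' Each read votes with its database k-mers; the read is assigned to the
#' node maximizing the summed vote weight along its root path (the
#' leaf-most node of the max-weight root-to-leaf path), ties resolved
#' towards the shallower node. Reads with no database k-mer, and reads
#' shorter than k, are unclassified (node 0).
#'
#' @param reads character vector of read sequences.
#' @param index a [build_index()] object.
#' @return integer vector of node ids (0 = unclassified), named by read
#'   names when present.
#' @export
classify_reads <- function(reads, index) {
  stopifnot(inherits(index, "kmer_index"))
  nodes <- cpp_classify_reads(index$ptr, unname(as.character(reads)),
                              as.integer(index$tree$nodes$parent_id))
  names(nodes) <- names(reads)
  nodes
}

# leaf descendants per node
leaf_descendants <- function(tree) {
  nodes <- tree$nodes
  is_leaf <- !is.na(nodes$genome_id)
  desc <- vector("list", nrow(nodes))
  ord <- order(nodes$depth, decreasing = TRUE)
  for (v in ord) {
    if (is_leaf[v]) desc[[v]] <- v
    p <- nodes$parent_id[v]
    if (p != 0L) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  lapply(desc, function(d) sort(unique(d)))
}

# largest-remainder integer apportionment of `total` by weights w
largest_remainder <- function(total, w) {
  if (total == 0L) return(integer(length(w)))
  if (all(w == 0)) w <- rep(1, length(w))
  exact <- total * w / sum(w)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0L) {
    ord <- order(exact - base, seq_along(w), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Redistribute internal-node read counts to genome leaves
#'
#' Processing internal nodes root-downward, each internal node's count is
#' split among its descendant leaves proportionally to those leaves' unique
#' (leaf-assigned) counts; when all descendant leaves have zero unique
#' counts the split is equal. Integer conservation is exact
#' (largest-remainder rounding).
#'
#' @param raw_counts named integer vector, node id -> read count (classified
#'   raw counts; missing nodes count 0).
#' @param tree a [taxonomy_tree()].
#' @return named integer vector of leaf counts (names = genome ids).
#' @export
redistribute <- function(raw_counts, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  nodes <- tree$nodes
  n <- nrow(nodes)
  counts <- integer(n)
  idx <- as.integer(names(raw_counts))
  counts[idx] <- counts[idx] + as.integer(raw_counts)
  is_leaf <- !is.na(nodes$genome_id)
  unique_leaf <- ifelse(is_leaf, counts, 0L)
  desc <- leaf_descendants(tree)
  out <- unique_leaf
  for (v in order(nodes$depth)) {
    if (is_leaf[v] || counts[v] == 0L) next
    leaves <- desc[[v]]
    if (!length(leaves)) next  # no genome leaves below: count is dropped
    add <- largest_remainder(counts[v], unique_leaf[leaves])
    out[leaves] <- out[leaves] + add
  }
  setNames(out[is_leaf], nodes$genome_id[is_leaf])
}

#' Summarize leaf counts into per-group read fractions
#'
#' @param leaf_counts named vector from [redistribute()].
#' @param tree a [taxonomy_tree()] with `group` labels on group nodes, or a
#'   named character vector genome id -> group.
#' @return data.frame `group`, `reads`, `fraction` (percent of classified
#'   reads); leaves under no labeled group report under `"other"`.
#' @export
summarize_groups <- function(leaf_counts, tree) {
  if (inherits(tree, "taxonomy_tree")) {
    nodes <- tree$nodes
    grp_of <- setNames(rep(NA_character_, nrow(nodes)), nodes$node_id)
    for (v in order(nodes$depth)) {
      g <- nodes$group[v]
      p <- nodes$parent_id[v]
      inh <- if (p != 0L) grp_of[[p]] else NA_character_
      grp_of[[v]] <- if (!is.na(g)) g else inh
    }
    leaf_nodes <- nodes$node_id[!is.na(nodes$genome_id)]
    genome_groups <- setNames(grp_of[as.character(leaf_nodes)],
                              nodes$genome_id[!is.na(nodes$genome_id)])
  } else genome_groups <- tree
  g <- genome_groups[names(leaf_counts)]
  g[is.na(g)] <- "other"
  tot <- sum(leaf_counts)
  agg <- aggregate(list(reads = as.integer(leaf_counts)),
                   by = list(group = unname(g)), FUN = sum)
  agg$fraction <- if (tot > 0) 100 * agg$reads / tot else 0
  agg[order(-agg$reads), , drop = FALSE]
}

#' Per-genome and per-group abundance from a read set
#'
#' Classifies reads, tabulates raw per-node counts, redistributes internal
#' counts to leaves and summarizes group fractions.
#'
#' @param reads character vector of reads.
#' @param index a [build_index()] object.
#' @return an object of class `abundance_table`: `raw_counts` (per node),
#'   `n_unclassified`, `leaf_counts`, `group_fractions`, `leaf_fractions`.
#' @export
abundance_table <- function(reads, index) {
  assigned <- classify_reads(reads, index)
  n_uncl <- sum(assigned == 0L)
  tab <- table(assigned[assigned > 0L])
  raw <- setNames(as.integer(tab), names(tab))
  leaf <- redistribute(raw, index$tree)
  tot <- sum(leaf)
  structure(list(raw_counts = raw, n_unclassified = n_uncl,
                 leaf_counts = leaf,
                 leaf_fractions = if (tot) 100 * leaf / tot else leaf * 0,
                 group_fractions = summarize_groups(leaf, index$tree)),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>", sum(x$leaf_counts), "classified reads,",
      x$n_unclassified, "unclassified\n")
  print(x$group_fractions, row.names = FALSE)
  invisible(x)
}
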