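# Gene-family annotation and pangenome rarefaction.

#' Greedy protein clustering by shared 4-mer containment
#'
#' Sequences are sorted by length (descending) and each joins the first
#' existing cluster whose centroid (founder) similarity reaches
#' `similarity_min`, else founds a new cluster. Similarity is the fraction
#' of the shorter sequence's positions covered by amino-acid 4-mers shared
#' with the other sequence (a coverage dialect of the 0.4 threshold: near 1
#' for homologs at moderate divergence, near 0 for unrelated sequences).
#'
#' @param proteins named character vector of protein sequences.
#' @param similarity_min similarity threshold in `[0, 1]` (default 0.4).
#' @return named character vector, protein id -> cluster id (cluster named
#'   after its founder).
#' @export
greedy_cluster_proteins <- function(proteins, similarity_min = 0.4) {
  if (!length(proteins)) stop("greedy_cluster_proteins: no proteins")
  stopifnot(!is.null(names(proteins)))
  ord <- order(-nchar(proteins), names(proteins), method = "radix")
  centroids <- character(0)          # founder ids
  centroid_kmers <- list()
  assignment <- character(length(proteins))
  names(assignment) <- names(proteins)
  for (i in ord) {
    id <- names(proteins)[i]
    seq_i <- proteins[[i]]
    km <- aa_kmers(seq_i, k = 4L)
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      # centroid founded first is at least as long; similarity is measured
      # on the member (the shorter sequence)
      sim <- kmer_coverage_similarity(seq_i, centroid_kmers[[ci]])
      if (sim >= similarity_min) {
        assignment[id] <- centroids[ci]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      centroid_kmers[[length(centroids)]] <- km
      assignment[id] <- id
    }
  }
  setNames(paste0("cl_", unname(assignment[names(proteins)])),
           names(proteins))
}

# Fraction of `protein`'s positions covered by 4-mers present in the
# centroid k-mer set.
kmer_coverage_similarity <- function(protein, centroid_kmers, k = 4L) {
  n <- nchar(protein)
  if (n < k || !length(centroid_kmers)) return(0)
  kms <- substring(protein, seq_len(n - k + 1L), seq.int(k, n))
  hit <- which(kms %in% centroid_kmers)
  if (!length(hit)) return(0)
  covered <- logical(n)
  for (i in hit) covered[i:(i + k - 1L)] <- TRUE
  mean(covered)
}

#' Annotate genes with family labels
#'
#' Precedence: profile class (highest-scoring profile when several hit) >
#' cluster id > unique singleton label.
#'
#' @param gene_ids character vector of gene ids.
#' @param profile_hits data.frame with columns `gene_id`, `profile_name`,
#'   `aa_score` (may be empty/NULL).
#' @param clusters named vector gene id -> cluster id for clustered genes;
#'   genes absent from it (or in singleton clusters, if `singletons_from`
#'   is given) fall through to singleton labels.
#' @param singletons_from optional: when a cluster id appears only once
#'   among unhit genes it is relabeled as a singleton.
#' @return data.frame `gene_id`, `family_label`, `label_source` (one of
#'   profile/cluster/singleton).
#' @export
annotate_families <- function(gene_ids, profile_hits = NULL, clusters = NULL,
                              singletons_from = TRUE) {
  label <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  source <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  if (!is.null(profile_hits) && nrow(profile_hits)) {
    best <- do.call(rbind, lapply(split(profile_hits, profile_hits$gene_id),
                                  function(h) h[which.max(h$aa_score), ]))
    hit_ids <- intersect(best$gene_id, gene_ids)
    label[hit_ids] <- best$profile_name[match(hit_ids, best$gene_id)]
    source[hit_ids] <- "profile"
  }
  todo <- names(label)[is.na(label)]
  if (!is.null(clusters)) {
    cl <- clusters[intersect(todo, names(clusters))]
    if (isTRUE(singletons_from) && length(cl)) {
      sizes <- table(clusters)
      cl <- cl[sizes[cl] > 1L]
    }
    label[names(cl)] <- unname(cl)
    source[names(cl)] <- "cluster"
  }
  todo <- names(label)[is.na(label)]
  label[todo] <- paste0("singleton_", todo)
  source[todo] <- "singleton"
  data.frame(gene_id = gene_ids, family_label = unname(label[gene_ids]),
             label_source = unname(source[gene_ids]),
             stringsAsFactors = FALSE)
}

#' Pangenome rarefaction over random genome orderings
#'
#' For each of `n_orders` random orderings of the genomes, counts the
#' cumulative number of distinct gene-family labels in the first k genomes;
#' reports per-k median and 5/95 percentiles using the nearest-rank
#' definition (ranks `ceiling(0.05 n)` and `ceiling(0.95 n)` on the sorted
#' values; exact at the default 1001 orderings).
#'
#' @param genome_families named list, genome id -> character vector of
#'   family labels (sets; duplicates within a genome are ignored).
#' @param n_orders number of random orderings (default 1001).
#' @param seed integer seed.
#' @return an object of class `rarefaction_result`: `table` (data.frame
#'   `k`, `median`, `p5`, `p95`), `n_orders`, `seed`.
#' @export
rarefaction <- function(genome_families, n_orders = 1001L, seed = 1L) {
  if (!length(genome_families)) stop("rarefaction: no genomes")
  sets <- lapply(genome_families, unique)
  fam_levels <- unique(unlist(sets))
  sets_i <- lapply(sets, function(s) match(s, fam_levels))
  n <- length(sets_i)
  counts <- matrix(0L, nrow = n_orders, ncol = n)
  with_seed(seed, {
    seen <- logical(length(fam_levels))
    for (r in seq_len(n_orders)) {
      ord <- sample.int(n)
      seen[] <- FALSE
      tot <- 0L
      for (k in seq_len(n)) {
        s <- sets_i[[ord[k]]]
        new <- s[!seen[s]]
        seen[new] <- TRUE
        tot <- tot + length(new)
        counts[r, k] <- tot
      }
    }
  })
  nearest_rank <- function(v, p) sort(v)[max(1L, ceiling(p * length(v)))]
  tab <- data.frame(
    k = seq_len(n),
    median = apply(counts, 2, median),
    p5 = apply(counts, 2, nearest_rank, p = 0.05),
    p95 = apply(counts, 2, nearest_rank, p = 0.95))
  structure(list(table = tab, n_orders = n_orders, seed = seed,
                 pangenome_size = length(fam_levels)),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat("<rarefaction_result>", nrow(x$table), "genomes,",
      x$n_orders, "orderings; pangenome size", x$pangenome_size, "\n")
  print(head(x$table), row.names = FALSE)
  if (nrow(x$table) > 6) cat("...\n")
  invisible(x)
}
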