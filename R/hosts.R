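# Host assignment from CRISPR spacer matches and close protein matches.

#' Match CRISPR spacers against phage genomes
#'
#' Short-match engine: exact 12-mer seeds on both strands anchor full-length
#' ungapped placements of each spacer; the best placement per spacer/genome
#' pair is reported. Identity is computed over the full spacer length
#' (unmatched overhangs count as mismatches), and placements below
#' `identity_min` percent are suppressed.
#'
#' @param spacers data.frame with columns `spacer_id`, `sequence`, and
#'   metadata columns `source_assembly`, `taxon_path`
#'   (semicolon-delimited or character), `completeness`.
#' @param phages named character vector of phage genome sequences.
#' @param seed_len exact seed length (default 12).
#' @param identity_min report floor, percent (default 70).
#' @return data.frame of `SpacerMatch` rows: `spacer_id`, `spacer_len`,
#'   `source_assembly`, `taxon_path`, `completeness`, `phage_id`,
#'   `matched_positions`, `identity`, `score` (matches - mismatches),
#'   `start`, `strand`.
#' @export
match_spacers <- function(spacers, phages, seed_len = 12L, identity_min = 70) {
  stopifnot(is.data.frame(spacers), !is.null(names(phages)))
  lens <- nchar(spacers$sequence)
  if (any(lens < 20L | lens > 60L))
    stop("spacer lengths must lie in [20, 60]")
  out <- NULL
  for (i in seq_len(nrow(spacers))) {
    sp <- toupper(spacers$sequence[i]); L <- nchar(sp)
    for (ph in names(phages)) {
      m <- cpp_spacer_best_match(sp, toupper(phages[[ph]]), as.integer(seed_len))
      if (is.na(m$matches)) next
      ident <- 100 * m$matches / L
      if (ident < identity_min) next
      out <- rbind(out, data.frame(
        spacer_id = spacers$spacer_id[i], spacer_len = L,
        source_assembly = spacers$source_assembly[i],
        taxon_path = spacers$taxon_path[i],
        completeness = spacers$completeness[i],
        phage_id = ph, matched_positions = m$matches,
        identity = ident, score = m$matches - (L - m$matches),
        start = m$start, strand = m$strand, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(spacer_id = character(0), spacer_len = integer(0),
                      source_assembly = character(0), taxon_path = character(0),
                      completeness = character(0), phage_id = character(0),
                      matched_positions = integer(0), identity = numeric(0),
                      score = integer(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out
}

#' Assign a host to one phage from its spacer matches
#'
#' A source assembly qualifies when it has (a) one or more matches covering
#' at least 90% of spacer positions, or (b) two or more matches each at 80%
#' identity or better. Among qualifying sources the one containing the highest
#' scoring match wins; ties prefer completely sequenced genomes, then the
#' lexicographically smaller assembly id.
#'
#' @param matches rows of [match_spacers()] for a single phage.
#' @param rule_a_identity identity for the single-hit rule (default 90).
#' @param rule_b_identity identity for the two-hit rule (default 80).
#' @return an object of class `host_assignment` (`phage_id`, `host_taxon`
#'   (leaf of the source taxon path), `source_assembly`, `evidence` one of
#'   `"crispr_one_hit_90"`/`"crispr_two_hits_80"`, `n_support`,
#'   `supporting_matches`), or `NULL` when no source qualifies.
#' @export
assign_host <- function(matches, rule_a_identity = 90, rule_b_identity = 80) {
  if (is.null(matches) || nrow(matches) == 0L) return(NULL)
  stopifnot(length(unique(matches$phage_id)) == 1L)
  qual <- lapply(split(matches, matches$source_assembly), function(mm) {
    a <- any(mm$identity >= rule_a_identity)
    b <- sum(mm$identity >= rule_b_identity) >= 2L
    if (!a && !b) return(NULL)
    list(src = mm$source_assembly[1],
         complete = mm$completeness[1] == "complete",
         best_score = max(mm$score),
         rule = if (a) "crispr_one_hit_90" else "crispr_two_hits_80",
         n_support = if (a) sum(mm$identity >= rule_a_identity)
                     else sum(mm$identity >= rule_b_identity),
         matches = mm)
  })
  qual <- Filter(Negate(is.null), qual)
  if (!length(qual)) return(NULL)
  score <- vapply(qual, `[[`, numeric(1), "best_score")
  complete <- vapply(qual, `[[`, logical(1), "complete")
  src <- vapply(qual, `[[`, character(1), "src")
  ord <- order(-score, !complete, src)
  w <- qual[[ord[1]]]
  path <- strsplit(w$matches$taxon_path[1], ";", fixed = TRUE)[[1]]
  structure(list(phage_id = matches$phage_id[1],
                 host_taxon = path[length(path)],
                 source_assembly = w$src, evidence = w$rule,
                 n_support = w$n_support, supporting_matches = w$matches),
            class = "host_assignment")
}

#' @export
print.host_assignment <- function(x, ...) {
  cat("<host_assignment>", x$phage_id, "->", x$host_taxon,
      sprintf("[%s, n=%d, %s]\n", x$evidence, x$n_support, x$source_assembly))
  invisible(x)
}

#' Assign hosts to every phage in a match table
#'
#' @param matches full [match_spacers()] output.
#' @param ... passed to [assign_host()].
#' @return data.frame: `phage_id`, `host_taxon`, `source_assembly`,
#'   `evidence`, `n_support` (phages with no qualifying source omitted).
#' @export
assign_hosts <- function(matches, ...) {
  rows <- lapply(split(matches, matches$phage_id), function(mm) {
    ha <- assign_host(mm, ...)
    if (is.null(ha)) return(NULL)
    data.frame(phage_id = ha$phage_id, host_taxon = ha$host_taxon,
               source_assembly = ha$source_assembly, evidence = ha$evidence,
               n_support = ha$n_support, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out))
    out <- data.frame(phage_id = character(0), host_taxon = character(0),
                      source_assembly = character(0), evidence = character(0),
                      n_support = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Verify a taxonomic assignment from a set of hit taxon paths
#'
#' Walks ranks from the leaf upward and returns the lowest-rank taxon that
#' accounts for at least `threshold` percent of all hits ("safe"
#' affiliation). If no taxon reaches the threshold even at the root, the
#' root is returned with a warning flag.
#'
#' @param hit_taxa list (or semicolon-delimited character vector) of taxon
#'   paths, each root -> leaf.
#' @param threshold percent of hits required (default 75).
#' @return a list: `taxon`, `rank_depth` (1 = root), `fraction` (percent of
#'   hits under the returned taxon), `at_root_warning`.
#' @export
verify_taxonomy <- function(hit_taxa, threshold = 75) {
  if (is.character(hit_taxa)) hit_taxa <- strsplit(hit_taxa, ";", fixed = TRUE)
  if (!length(hit_taxa)) stop("verify_taxonomy: no hits")
  n <- length(hit_taxa)
  depth <- max(lengths(hit_taxa))
  for (d in seq.int(depth, 1L)) {
    at_d <- vapply(hit_taxa, function(p)
      if (length(p) >= d) p[d] else NA_character_, character(1))
    tab <- sort(table(at_d), decreasing = TRUE)
    if (length(tab) && 100 * tab[1] / n >= threshold)
      return(list(taxon = names(tab)[1], rank_depth = d,
                  fraction = 100 * as.numeric(tab[1]) / n,
                  at_root_warning = FALSE))
  }
  roots <- vapply(hit_taxa, `[`, character(1), 1L)
  tab <- sort(table(roots), decreasing = TRUE)
  list(taxon = names(tab)[1], rank_depth = 1L,
       fraction = 100 * as.numeric(tab[1]) / n, at_root_warning = TRUE)
}

# Identity and query coverage of a protein pair: global/local alignment via
# Biostrings (a simple affine alignment; coverage measured on the query).
protein_pair_stats <- function(query, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(al))
  sub <- as.character(Biostrings::alignedSubject(al))
  pc <- strsplit(pat, "")[[1]]; sc <- strsplit(sub, "")[[1]]
  aligned <- pc != "-" & sc != "-"
  n_match <- sum(pc == sc & aligned)
  n_cols <- sum(aligned)
  ident <- if (n_cols) 100 * n_match / n_cols else 0
  cov <- 100 * sum(pc != "-") / nchar(query)
  c(identity = ident, coverage = cov)
}

#' Protein-match host evidence with per-phylum enrichment
#'
#' Counts phage-protein/reference-protein pairs passing both thresholds
#' (inclusive: identity >= `identity_min` percent over >= `coverage_min`
#' percent of the query length) per reference phylum, and reports fold
#' enrichment = (fraction of matches in a phylum) / (that phylum's fraction
#' of the reference database).
#'
#' @param phage_proteins named character vector of phage protein sequences.
#' @param reference data.frame with columns `protein_id`, `sequence`,
#'   `phylum`.
#' @param identity_min percent identity threshold (default 50).
#' @param coverage_min percent query-coverage threshold (default 66).
#' @return a list: `matches` (data.frame `query_id`, `subject_id`, `phylum`,
#'   `identity`, `coverage`), `by_phylum` (data.frame `phylum`, `n_matches`,
#'   `match_fraction`, `db_fraction`, `fold_enrichment`).
#' @export
protein_host_evidence <- function(phage_proteins, reference,
                                  identity_min = 50, coverage_min = 66) {
  if (is.null(reference) || nrow(reference) == 0L)
    stop("protein_host_evidence: empty reference")
  matches <- NULL
  for (q in names(phage_proteins)) {
    for (j in seq_len(nrow(reference))) {
      st <- protein_pair_stats(phage_proteins[[q]], reference$sequence[j])
      if (st[["identity"]] >= identity_min && st[["coverage"]] >= coverage_min)
        matches <- rbind(matches, data.frame(
          query_id = q, subject_id = reference$protein_id[j],
          phylum = reference$phylum[j], identity = st[["identity"]],
          coverage = st[["coverage"]], stringsAsFactors = FALSE))
    }
  }
  db_tab <- table(reference$phylum)
  phyla <- names(db_tab)
  n_match <- if (is.null(matches)) setNames(rep(0L, length(phyla)), phyla)
             else table(factor(matches$phylum, levels = phyla))
  total <- sum(n_match)
  by_phylum <- data.frame(
    phylum = phyla,
    n_matches = as.integer(n_match),
    match_fraction = if (total) as.numeric(n_match) / total else 0,
    db_fraction = as.numeric(db_tab) / nrow(reference),
    stringsAsFactors = FALSE)
  by_phylum$fold_enrichment <- ifelse(
    by_phylum$db_fraction > 0 & total > 0,
    by_phylum$match_fraction / by_phylum$db_fraction, NA_real_)
  list(matches = matches, by_phylum = by_phylum)
}
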