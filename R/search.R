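# Six-frame profile search with empirically calibrated significance.
#
# The scan is a gapless local segment search (per profile/sequence diagonal)
# rather than a fixed-length window: local segments keep score additivity
# and make fragments of split genes (shorter than the profile) detectable.
# Significance is calibrated per genome: the maximum segment score is
# measured on n_null shuffles of the genome's own six-frame translation
# (subsampled to at most null_m residues), a Gumbel location/scale is fitted
# by moments, and the location is shifted by beta*log(N/m) to rescale the
# null to the full search space of N residues.

EULER_GAMMA <- 0.5772156649015329

# Translate all six frames; returns a list of frame records with residue
# row indices for the scoring kernel and the mapping back to forward
# nucleotide coordinates.
six_frame_residues <- function(genome, code, readthrough) {
  genome <- toupper(genome)
  n <- nchar(genome)
  rc <- revcomp(genome)
  stops_as <- if (readthrough) "X" else "invalid"
  frames <- list()
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      seq_use <- if (strand == "+") genome else rc
      aa <- translate_dna(substr(seq_use, f, n), code)
      if (nchar(aa) == 0L) next
      frames[[length(frames) + 1L]] <- list(
        frame = if (strand == "+") f else -f,
        strand = strand, offset = f - 1L, n = n,
        rows = aa_to_rows(aa, stops_as = stops_as))
    }
  }
  frames
}

# Map a residue interval [a, b) (0-based, within one frame) to forward-strand
# nucleotide coordinates (0-based half-open).
frame_to_nt <- function(fr, a, b) {
  lo <- fr$offset + 3L * a
  hi <- fr$offset + 3L * b
  if (fr$strand == "+") c(lo, hi) else c(fr$n - hi, fr$n - lo)
}

empty_hits <- function() {
  data.frame(profile_name = character(0), genome_id = character(0),
             frame = integer(0), strand = character(0),
             start = integer(0), end = integer(0),
             aa_score = numeric(0), evalue = numeric(0),
             col_start = integer(0), col_end = integer(0),
             readthrough = logical(0), stringsAsFactors = FALSE)
}

# Fit the null and scan one profile over precomputed frames.
scan_profile_frames <- function(frames, profile, genome_id, n_null, null_m,
                                evalue_max, readthrough, null_seed) {
  S <- profile$scores
  pool <- unlist(lapply(frames, function(fr) fr$rows[fr$rows >= 0L]))
  n_space <- length(pool)
  if (n_space < profile$length) return(empty_hits())
  m <- min(null_m, n_space)
  nulls <- cpp_null_max_scores(as.integer(pool), S, as.integer(n_null),
                               as.integer(m), as.integer(null_seed))
  beta <- sd(nulls) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) beta <- 1
  mu <- mean(nulls) - EULER_GAMMA * beta
  nf <- n_space / m  # extreme-value rescaling to the full search space
  score_min <- mu + beta * (log(nf) - log(evalue_max))

  res <- lapply(frames, function(fr) {
    seg <- cpp_profile_scan(as.integer(fr$rows), S, score_min)
    if (nrow(seg) == 0L) return(NULL)
    nt <- t(vapply(seq_len(nrow(seg)),
                   function(i) frame_to_nt(fr, seg$start[i], seg$end[i]),
                   integer(2)))
    data.frame(profile_name = profile$name, genome_id = genome_id,
               frame = fr$frame, strand = fr$strand,
               start = nt[, 1], end = nt[, 2],
               aa_score = seg$score,
               evalue = nf * exp(-(seg$score - mu) / beta),
               col_start = seg$cstart, col_end = seg$cend,
               readthrough = readthrough, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, res)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits())
  merge_frame_hits(hits)
}

# Overlapping same-frame hits are represented by the best-scoring hit.
merge_frame_hits <- function(hits) {
  keep <- lapply(split(hits, hits$frame), function(h) {
    h <- h[order(h$start, -h$aa_score), , drop = FALSE]
    cluster <- integer(nrow(h)); cur <- 0L; cur_end <- -1L
    for (i in seq_len(nrow(h))) {
      if (h$start[i] >= cur_end) { cur <- cur + 1L; cur_end <- h$end[i] }
      else cur_end <- max(cur_end, h$end[i])
      cluster[i] <- cur
    }
    do.call(rbind, lapply(split(h, cluster),
                          function(g) g[which.max(g$aa_score), , drop = FALSE]))
  })
  out <- do.call(rbind, keep)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search a genome for a marker protein with a scoring profile
#'
#' Scans all six reading frames with gapless local segments against the
#' profile. In readthrough mode, stop codons translate as `X` (scoring the
#' background, i.e. 0), so a stop-interrupted marker still accrues score; in
#' normal mode stops are impassable. Significance is an empirical e-value
#' from `n_null` shuffles of the genome's own translation with a fitted
#' Gumbel tail rescaled to the full search space; hits with
#' `evalue < evalue_max` are returned, overlapping same-frame hits collapsed
#' to the best-scoring one.
#'
#' @param genome DNA string.
#' @param profile a [build_profile()] object.
#' @param code a [genetic_code_table()] used for translation.
#' @param readthrough logical; translate stop codons as `X`.
#' @param n_null number of null shuffles (default 200).
#' @param evalue_max e-value cutoff (default 0.05).
#' @param null_m residues per null replicate before extreme-value rescaling.
#' @param seed integer seed for the null shuffles.
#' @param genome_id identifier carried into the hit table.
#' @return data.frame of hits: `profile_name`, `genome_id`, `frame`
#'   (+1..+3/-1..-3), `strand`, `start`, `end` (0-based half-open,
#'   forward-strand coordinates), `aa_score` (half-bits), `evalue`,
#'   `col_start`, `col_end` (profile columns matched), `readthrough`.
#' @export
search_genome <- function(genome, profile, code = genetic_code_table("standard"),
                          readthrough = FALSE, n_null = 200, evalue_max = 0.05,
                          null_m = 3000, seed = 1, genome_id = "genome") {
  if (!nzchar(genome)) stop("search_genome: empty genome")
  if (nchar(genome) < 3 * profile$length) return(empty_hits())
  frames <- six_frame_residues(genome, code, readthrough)
  with_seed(seed, {
    scan_profile_frames(frames, profile, genome_id, n_null, null_m,
                        evalue_max, readthrough, child_seed())
  })
}

#' Detect a panel of marker proteins in one genome
#'
#' Runs [search_genome()] for every profile in `profiles` (sharing one
#' six-frame translation) and reports, per profile, presence and the best
#' hit.
#'
#' @inheritParams search_genome
#' @param profiles named list of profiles, e.g. from [load_profiles()].
#' @return a list with `table` (one row per profile: `profile_name`,
#'   `present`, best `aa_score`, `evalue`, `start`, `end`, `frame`) and
#'   `hits` (all retained hits across profiles).
#' @export
detect_markers <- function(genome, profiles, code = genetic_code_table("standard"),
                           readthrough = TRUE, n_null = 200, evalue_max = 0.05,
                           null_m = 3000, seed = 1, genome_id = "genome") {
  if (!nzchar(genome)) stop("detect_markers: empty genome")
  frames <- six_frame_residues(genome, code, readthrough)
  all_hits <- with_seed(seed, {
    do.call(rbind, lapply(profiles, function(p) {
      scan_profile_frames(frames, p, genome_id, n_null, null_m,
                          evalue_max, readthrough, child_seed())
    }))
  })
  if (is.null(all_hits)) all_hits <- empty_hits()
  tab <- do.call(rbind, lapply(names(profiles), function(nm) {
    h <- all_hits[all_hits$profile_name == nm, , drop = FALSE]
    if (nrow(h) == 0L)
      data.frame(profile_name = nm, present = FALSE, aa_score = NA_real_,
                 evalue = NA_real_, start = NA_integer_, end = NA_integer_,
                 frame = NA_integer_, stringsAsFactors = FALSE)
    else {
      b <- h[which.max(h$aa_score), ]
      data.frame(profile_name = nm, present = TRUE, aa_score = b$aa_score,
                 evalue = b$evalue, start = b$start, end = b$end,
                 frame = b$frame, stringsAsFactors = FALSE)
    }
  }))
  rownames(tab) <- NULL
  list(table = tab, hits = all_hits)
}

#' Marker conservation matrix across a genome cohort
#'
#' Assembles the presence/absence matrix of marker profiles across genomes
#' (the gene-conservation pattern view).
#'
#' @param genomes named character vector of genome sequences.
#' @param profiles named list of profiles.
#' @param ... passed to [detect_markers()].
#' @return logical matrix, genomes x profiles.
#' @export
conservation_matrix <- function(genomes, profiles, ...) {
  stopifnot(!is.null(names(genomes)))
  rows <- lapply(names(genomes), function(id) {
    dm <- detect_markers(genomes[[id]], profiles, genome_id = id, ...)
    setNames(dm$table$present, dm$table$profile_name)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(genomes)
  mat
}
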