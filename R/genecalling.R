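# Code-aware ORF calling, genetic-code inference, split-gene detection.

#' Call ORFs under a genetic code table
#'
#' A deliberately simple caller: in each of the six frames, maximal
#' stop-free codon spans under the code are enumerated; the gene starts at
#' the first ATG in the span (fallback GTG, then TTG) and runs to the
#' terminating stop codon (included in the interval). Spans shorter than
#' `min_len` codons are discarded. A span with no start codon yields a call
#' only when it abuts the sequence start (flagged `no_start`); a span
#' reaching the sequence end without a stop is flagged `runs_off_end`.
#'
#' @param genome DNA string.
#' @param code a [genetic_code_table()].
#' @param min_len minimum span length in codons (default 60).
#' @param genome_id identifier carried into the calls.
#' @return data.frame of calls: `gene_id`, `genome_id`, `start`, `end`
#'   (0-based half-open, forward coordinates), `strand`, `frame`, `code_id`,
#'   `protein`, `no_start`, `runs_off_end`.
#' @export
call_orfs <- function(genome, code = genetic_code_table("standard"),
                      min_len = 60L, genome_id = "genome") {
  if (!nzchar(genome)) stop("call_orfs: empty genome")
  genome <- toupper(genome)
  n <- nchar(genome)
  rc <- revcomp(genome)
  out <- NULL
  for (f in 1:3) {
    for (strand in c("+", "-")) {
      seq_use <- if (strand == "+") genome else rc
      cs <- codons_of(seq_use, f - 1L)
      if (length(cs) == 0L) next
      is_stop <- cs %in% code$stop_codons
      # maximal stop-free spans (codon indices, 1-based)
      bound <- c(0L, which(is_stop), length(cs) + 1L)
      for (b in seq_len(length(bound) - 1L)) {
        lo <- bound[b] + 1L; hi <- bound[b + 1L] - 1L
        if (hi - lo + 1L < min_len) next
        has_stop <- bound[b + 1L] <= length(cs)
        span <- cs[lo:hi]
        st_rel <- match("ATG", span)
        if (is.na(st_rel)) st_rel <- match("GTG", span)
        if (is.na(st_rel)) st_rel <- match("TTG", span)
        no_start <- FALSE
        if (is.na(st_rel)) {
          if (lo == 1L) { st_rel <- 1L; no_start <- TRUE } else next
        }
        first_cod <- lo + st_rel - 1L
        if (hi - first_cod + 1L < min_len) next
        last_cod <- if (has_stop) hi + 1L else hi  # include stop codon
        a <- (f - 1L) + 3L * (first_cod - 1L)     # 0-based on seq_use
        b2 <- (f - 1L) + 3L * last_cod
        if (strand == "+") { g_start <- a; g_end <- b2 }
        else { g_start <- n - b2; g_end <- n - a }
        prot <- translate_dna(paste(span[st_rel:length(span)], collapse = ""),
                              code)
        out <- rbind(out, data.frame(
          genome_id = genome_id, start = g_start, end = g_end,
          strand = strand, frame = if (strand == "+") f else -f,
          code_id = code$code_id, protein = prot,
          no_start = no_start, runs_off_end = !has_stop,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), code_id = character(0),
                      protein = character(0), no_start = logical(0),
                      runs_off_end = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  if (nrow(out)) out$gene_id <- sprintf("%s_g%03d", genome_id, seq_len(nrow(out)))
  else out$gene_id <- character(0)
  rownames(out) <- NULL
  out[, c("gene_id", setdiff(names(out), "gene_id"))]
}

#' Infer the genetic code of a genome from marker-gene stop codons
#'
#' Counts in-frame TAA/TAG/TGA codons inside readthrough marker hits
#' (TerL, MCP, portal by default). Decision rule: if at least
#' `min_markers` markers each contain at least `min_stops` in-frame TAG and
#' the total in-frame TGA count over all markers is zero, the code is
#' `TAG_to_Q`; symmetrically for `TGA_to_W`; otherwise `standard`.
#'
#' @param genome DNA string.
#' @param marker_hits readthrough hit table from [search_genome()] /
#'   [detect_markers()] restricted to the evidence markers; the best hit per
#'   marker is used.
#' @param min_markers minimum markers supporting reassignment (default 2).
#' @param min_stops minimum in-frame reassigned stops per marker (default 2).
#' @return an object of class `code_assignment`: `genome_id`, `code_id`,
#'   `evidence` (per-marker stop counts), `n_markers_supporting`,
#'   `no_evidence` flag.
#' @export
infer_genetic_code <- function(genome, marker_hits, min_markers = 2L,
                               min_stops = 2L) {
  genome_id <- if (nrow(marker_hits)) marker_hits$genome_id[1] else "genome"
  if (nrow(marker_hits) == 0L) {
    return(structure(list(genome_id = genome_id, code_id = "standard",
                          evidence = NULL, n_markers_supporting = 0L,
                          no_evidence = TRUE), class = "code_assignment"))
  }
  best <- do.call(rbind, lapply(split(marker_hits, marker_hits$profile_name),
                                function(h) h[which.max(h$aa_score), ]))
  ev <- do.call(rbind, lapply(seq_len(nrow(best)), function(i) {
    cnt <- count_inframe_stops(genome, best$start[i], best$end[i],
                               best$strand[i])
    data.frame(marker = best$profile_name[i], n_TAA = cnt[["n_TAA"]],
               n_TAG = cnt[["n_TAG"]], n_TGA = cnt[["n_TGA"]],
               stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  tag_support <- sum(ev$n_TAG >= min_stops)
  tga_support <- sum(ev$n_TGA >= min_stops)
  code_id <- "standard"; n_support <- 0L
  if (tag_support >= min_markers && sum(ev$n_TGA) == 0L) {
    code_id <- "TAG_to_Q"; n_support <- tag_support
  } else if (tga_support >= min_markers && sum(ev$n_TAG) == 0L) {
    code_id <- "TGA_to_W"; n_support <- tga_support
  }
  structure(list(genome_id = genome_id, code_id = code_id, evidence = ev,
                 n_markers_supporting = n_support, no_evidence = FALSE),
            class = "code_assignment")
}

#' @export
print.code_assignment <- function(x, ...) {
  cat("<code_assignment>", x$genome_id, "->", x$code_id,
      if (isTRUE(x$no_evidence)) "(no evidence)" else
        sprintf("(%d markers supporting)", x$n_markers_supporting), "\n")
  if (!is.null(x$evidence)) print(x$evidence)
  invisible(x)
}

#' Detect a split (intron/intein-interrupted) marker gene
#'
#' Consecutive hits of one marker profile within `max_span` bp are merged
#' into a single split gene. Each separator (the gap between consecutive
#' fragments) is classified: a Hint-domain hit with preserved frame means
#' intein; an endonuclease-domain hit or a frame change means intron;
#' otherwise unclassified.
#'
#' @param genome DNA string.
#' @param marker_hits readthrough hit table for one marker (all fragments).
#' @param insert_profiles list with elements `Hint` and `endonuclease`
#'   (defaults to the bundled profiles).
#' @param code genome's [genetic_code_table()].
#' @param max_span maximum span of one split gene in bp (default 15000).
#' @param evalue_max confidence gate on the fragment hits considered for
#'   architecture calls (default 1e-3; tighter than the 0.05 discovery gate
#'   because fragment hits of genuine markers score far above it).
#' @param seed seed for the separator domain scans.
#' @return `NULL` when the marker is a single contiguous hit; otherwise an
#'   object of class `split_gene`: `genome_id`, `marker_name`, `fragments`
#'   (data.frame `start`, `end`, `frame`), `separators` (data.frame `start`,
#'   `end`, `kind`).
#' @export
detect_split_genes <- function(genome, marker_hits,
                               insert_profiles = cached_profiles()[c("Hint", "endonuclease")],
                               code = genetic_code_table("standard"),
                               max_span = 15000L, evalue_max = 1e-3, seed = 1) {
  if (nrow(marker_hits) == 0L) return(NULL)
  stopifnot(length(unique(marker_hits$profile_name)) == 1L)
  marker_hits <- marker_hits[marker_hits$evalue < evalue_max, , drop = FALSE]
  if (nrow(marker_hits) == 0L) return(NULL)
  h <- marker_hits[order(marker_hits$start), , drop = FALSE]
  # group hits within max_span of the previous fragment
  grp <- cumsum(c(0L, diff(h$start) > max_span)) + 1L
  h <- h[grp == grp[which.max(h$aa_score)], , drop = FALSE]
  if (nrow(h) < 2L) return(NULL)
  seps <- NULL
  for (i in seq_len(nrow(h) - 1L)) {
    s0 <- h$end[i]; s1 <- h$start[i + 1L]
    margin <- 30L
    lo <- max(0L, s0 - margin); hi <- min(nchar(genome), s1 + margin)
    sep_seq <- substr(genome, lo + 1L, hi)
    frame_change <- h$frame[i] != h$frame[i + 1L]
    kind <- "unclassified"
    if (nchar(sep_seq) >= 60L) {
      hint <- search_genome(sep_seq, insert_profiles$Hint, code = code,
                            readthrough = TRUE, seed = seed)
      endo <- search_genome(sep_seq, insert_profiles$endonuclease, code = code,
                            readthrough = TRUE, seed = seed + 1L)
      if (nrow(hint) > 0L && !frame_change) kind <- "intein"
      else if (nrow(endo) > 0L || frame_change) kind <- "intron"
    } else if (frame_change) kind <- "intron"
    seps <- rbind(seps, data.frame(start = s0, end = s1, kind = kind,
                                   stringsAsFactors = FALSE))
  }
  structure(list(genome_id = h$genome_id[1],
                 marker_name = h$profile_name[1],
                 fragments = data.frame(start = h$start, end = h$end,
                                        frame = h$frame),
                 separators = seps),
            class = "split_gene")
}

#' @export
print.split_gene <- function(x, ...) {
  cat("<split_gene>", x$marker_name, "on", x$genome_id, "|",
      nrow(x$fragments), "fragments,",
      paste(x$separators$kind, collapse = "+"), "\n")
  invisible(x)
}

#' Annotate a genome end to end
#'
#' Orchestrates marker search (readthrough), genetic-code inference,
#' code-aware ORF calling under the inferred code, split-gene detection per
#' detected marker, and suppressor tRNA flagging.
#'
#' @param genome DNA string.
#' @param profiles profile library (bundled set by default); the markers
#'   used for code inference are TerL, MCP and portal.
#' @param trna_annotations optional data.frame of tRNA loci with columns
#'   `start`, `end`, `anticodon` (tRNA discovery itself is out of scope;
#'   loci are consumed as annotations).
#' @param genome_id identifier.
#' @param seed integer seed (null calibration).
#' @param min_len minimum ORF length in codons.
#' @return a list with `code` (a `code_assignment`), `genes` (ORF calls
#'   under the inferred code), `markers` (marker table + hits),
#'   `split_genes` (list of `split_gene`), `trnas` (annotation table with
#'   `isotype` and `suppressor_target`).
#' @export
annotate_genome <- function(genome, profiles = cached_profiles(),
                            trna_annotations = NULL, genome_id = "genome",
                            seed = 1, min_len = 60L) {
  evidence_markers <- intersect(c("TerL", "MCP", "portal"), names(profiles))
  dm <- detect_markers(genome, profiles[evidence_markers], readthrough = TRUE,
                       seed = seed, genome_id = genome_id)
  code <- infer_genetic_code(genome, dm$hits)
  code_tab <- genetic_code_table(code$code_id)
  genes <- call_orfs(genome, code_tab, min_len = min_len,
                     genome_id = genome_id)
  split_genes <- list()
  for (m in unique(dm$hits$profile_name)) {
    sg <- detect_split_genes(genome,
                             dm$hits[dm$hits$profile_name == m, , drop = FALSE],
                             insert_profiles = profiles[c("Hint", "endonuclease")],
                             code = code_tab, seed = seed)
    if (!is.null(sg)) split_genes[[m]] <- sg
  }
  trnas <- NULL
  if (!is.null(trna_annotations) && nrow(trna_annotations)) {
    cls <- lapply(trna_annotations$anticodon, classify_trna_suppressor)
    trnas <- cbind(trna_annotations,
                   isotype = vapply(cls, `[[`, character(1), "isotype"),
                   suppressor_target = vapply(cls, `[[`, character(1),
                                              "suppressor_target"))
  }
  list(genome_id = genome_id, code = code, genes = genes, markers = dm,
       split_genes = split_genes, trnas = trnas)
}
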