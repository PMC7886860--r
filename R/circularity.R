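# Circular contig detection via exact terminal direct repeats.

#' Find the terminal direct repeat of a contig
#'
#' A contig is "circular" when its first L and last L bases are exactly
#' identical for some L in `[min_len, max_len]` (same strand, no
#' mismatches). The longest qualifying L is returned, trimming maximal
#' redundancy when repeats are nested.
#'
#' @param contig DNA string.
#' @param min_len minimum repeat length in bp (default 50).
#' @param max_len maximum repeat length in bp (default 200).
#' @return integer repeat length, or `NA_integer_` if none qualifies (also
#'   when the contig is shorter than `2 * min_len`).
#' @export
find_terminal_repeat <- function(contig, min_len = 50L, max_len = 200L) {
  n <- nchar(contig)
  if (n <= 2L * min_len) return(NA_integer_)
  hi <- min(max_len, n %/% 2L)
  for (L in seq.int(hi, min_len)) {
    if (substr(contig, 1L, L) == substr(contig, n - L + 1L, n))
      return(as.integer(L))
  }
  NA_integer_
}

#' Trim a circular contig to a circular genome
#'
#' When a terminal direct repeat is found, the trailing copy is removed
#' (the leading copy is kept) and the repeat length recorded; sequence
#' orientation is preserved.
#'
#' @inheritParams find_terminal_repeat
#' @param id genome identifier.
#' @param rotate_canonical if `TRUE`, rotate the trimmed circle to its
#'   lexicographically minimal rotation (off by default; downstream
#'   comparisons are rotation-aware).
#' @return an object of class `circular_genome` (`genome_id`, `sequence`,
#'   `repeat_len`, `original_len`), or `NULL` when no repeat qualifies.
#' @export
circularize <- function(contig, id = "contig", min_len = 50L, max_len = 200L,
                        rotate_canonical = FALSE) {
  L <- find_terminal_repeat(contig, min_len, max_len)
  if (is.na(L)) return(NULL)
  n <- nchar(contig)
  seq <- substr(contig, 1L, n - L)
  if (rotate_canonical) seq <- minimal_rotation(seq)
  structure(list(genome_id = id, sequence = seq, repeat_len = L,
                 original_len = n),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat("<circular_genome>", x$genome_id, "|", nchar(x$sequence), "bp circle,",
      x$repeat_len, "bp terminal repeat\n")
  invisible(x)
}

# Lexicographically minimal rotation (Booth-style linear scan is overkill at
# these sizes; direct comparison over candidate starts keyed by the minimal
# character suffices).
minimal_rotation <- function(x) {
  n <- nchar(x)
  dbl <- paste0(x, x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  cand <- which(ch == min(ch))
  best <- substr(dbl, cand[1], cand[1] + n - 1L)
  for (i in cand[-1]) {
    r <- substr(dbl, i, i + n - 1L)
    if (r < best) best <- r
  }
  best
}

#' Extend a circular genome back to contig form
#'
#' Appends the first `repeat_len` bases to the end; the inverse of
#' [circularize()] on sequences.
#'
#' @param sequence trimmed circle sequence.
#' @param repeat_len repeat length to re-append.
#' @return DNA string with the terminal repeat restored.
#' @export
extend_circular <- function(sequence, repeat_len) {
  paste0(sequence, substr(sequence, 1L, repeat_len))
}

#' Screen a contig pool for circular genomes
#'
#' @param contigs named character vector of contig sequences.
#' @inheritParams find_terminal_repeat
#' @return a list with `report` (data.frame: `contig_id`, `original_len`,
#'   `repeat_len`, `circular`) and `genomes` (list of `circular_genome`).
#' @export
screen_circular <- function(contigs, min_len = 50L, max_len = 200L) {
  stopifnot(!is.null(names(contigs)))
  genomes <- list()
  rep_len <- integer(length(contigs))
  for (i in seq_along(contigs)) {
    cg <- circularize(contigs[[i]], names(contigs)[i], min_len, max_len)
    if (is.null(cg)) rep_len[i] <- NA_integer_
    else {
      rep_len[i] <- cg$repeat_len
      genomes[[cg$genome_id]] <- cg
    }
  }
  list(report = data.frame(contig_id = names(contigs),
                           original_len = nchar(contigs),
                           repeat_len = rep_len,
                           circular = !is.na(rep_len),
                           stringsAsFactors = FALSE, row.names = NULL),
       genomes = genomes)
}
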