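# Position-specific scoring profiles for marker-protein detection.

# Amino-acid alphabet used by the scoring kernels; X (unknown / readthrough
# stop) is the last row and always scores 0 (= background).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Robinson & Robinson background amino-acid frequencies.
AA_BACKGROUND <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Map an amino-acid string to 0-based rows of the score matrix; `invalid`
# says what to do with '*' (stop): either treat as X or mark impassable (-1).
aa_to_rows <- function(aa, stops_as = c("invalid", "X")) {
  stops_as <- match.arg(stops_as)
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_ALPHABET) - 1L
  idx[is.na(idx) & ch != "*"] <- length(AA_ALPHABET) - 1L  # unknowns -> X
  if (stops_as == "X") idx[ch == "*"] <- length(AA_ALPHABET) - 1L
  else idx[ch == "*"] <- -1L
  idx
}

#' Build a position-specific scoring profile from a protein alignment
#'
#' Per-column log-odds scores (in half-bits) of observed residue frequencies
#' against a fixed background, with a pseudocount of `0.5 * background` added
#' to each column's counts. Columns with more than 50% gap characters are
#' dropped. The last alphabet row (`X`) scores 0 everywhere, so unknown
#' residues and readthrough-translated stops are background-neutral.
#'
#' @param alignment named character vector of aligned protein sequences
#'   (equal lengths; `-` or `.` for gaps), or a `Biostrings::AAStringSet`.
#' @param name profile name (e.g. `"TerL"`).
#' @param group_tags optional character vector of group labels the profile
#'   represents.
#' @return an object of class `crass_profile` with elements `name`, `length`
#'   (columns), `scores` (alphabet x columns matrix, half-bits), `consensus`
#'   (majority-residue string), `background`, `group_tags`.
#' @export
build_profile <- function(alignment, name, group_tags = character(0)) {
  if (methods::is(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (length(alignment) < 2L)
    stop("build_profile: alignment needs at least 2 sequences")
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("build_profile: aligned sequences have inconsistent lengths")
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  mat <- mat[, gap_frac <= 0.5, drop = FALSE]
  if (ncol(mat) == 0L) stop("build_profile: no columns survive gap filtering")

  aa20 <- names(AA_BACKGROUND)
  scores <- matrix(0, nrow = length(AA_ALPHABET), ncol = ncol(mat),
                   dimnames = list(AA_ALPHABET, NULL))
  consensus <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j]
    obs <- obs[obs %in% aa20]
    cnt <- table(factor(obs, levels = aa20))
    freq <- (cnt + 0.5 * AA_BACKGROUND) / (sum(cnt) + 0.5)
    scores[aa20, j] <- 2 * log2(as.numeric(freq) / AA_BACKGROUND)
    consensus[j] <- if (length(obs)) names(which.max(cnt)) else "A"
  }
  structure(list(name = name, length = ncol(mat), scores = scores,
                 consensus = paste(consensus, collapse = ""),
                 background = AA_BACKGROUND, group_tags = group_tags),
            class = "crass_profile")
}

#' @export
print.crass_profile <- function(x, ...) {
  cat("<crass_profile>", x$name, "|", x$length, "columns\n")
  invisible(x)
}

#' Score a protein sequence against a profile, column for column
#'
#' Gapless scoring of `protein` aligned to profile columns starting at
#' column 1; used as the additivity reference and by group assignment.
#'
#' @param profile a [build_profile()] object.
#' @param protein amino-acid string (length <= profile length scores the
#'   leading columns).
#' @return total score in half-bits.
#' @export
score_sequence <- function(profile, protein) {
  rows <- aa_to_rows(protein, stops_as = "X") + 1L
  ncol <- min(length(rows), profile$length)
  sum(profile$scores[cbind(rows[seq_len(ncol)], seq_len(ncol))])
}

#' Load the bundled marker-profile library
#'
#' Reads the synthetic marker alignments shipped under
#' `inst/extdata/profiles` (generated in-repo with a fixed seed; they emulate
#' the conservation structure of the crAss-like marker roster: TerL, MCP,
#' portal, gene75, IHF_53, PDDEXK_a, primase, DnaB, Ttub, Tstab, plus the
#' insert-domain profiles Hint and endonuclease) and builds one profile per
#' manifest row.
#'
#' @param dir directory containing `manifest.tsv` and alignment FASTA files;
#'   defaults to the bundled set.
#' @param markers optional character vector restricting which profiles load.
#' @return named list of `crass_profile` objects.
#' @export
load_profiles <- function(dir = system.file("extdata", "profiles",
                                            package = "crasskit"),
                          markers = NULL) {
  man <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  if (!is.null(markers)) man <- man[man$name %in% markers, , drop = FALSE]
  profs <- lapply(seq_len(nrow(man)), function(i) {
    aln <- read_fasta(file.path(dir, man$file[i]))
    tags <- if (is.na(man$group_tags[i]) || man$group_tags[i] == "") character(0)
            else strsplit(man$group_tags[i], ",", fixed = TRUE)[[1]]
    p <- build_profile(aln, man$name[i], group_tags = tags)
    p$marker_class <- man$marker_class[i]
    p
  })
  setNames(profs, man$name)
}
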