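# Genetic code tables, translation, and suppressor tRNA classification.

# Standard bacterial code, codon -> single-letter amino acid ('*' = stop).
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Genetic code tables used by crAss-like phages
#'
#' Three code tables are supported: the standard bacterial code, the code
#' with TAG reassigned to glutamine, and the code with TGA reassigned to
#' tryptophan. These are the two stop-codon reassignments observed in
#' crAss-like phages; TAA is never a reassignment candidate here.
#'
#' @param code_id one of `"standard"`, `"TAG_to_Q"`, `"TGA_to_W"`.
#' @return an object of class `genetic_code_table` with elements `code_id`,
#'   `table` (named codon -> amino-acid vector, `"*"` marking stops),
#'   `stop_codons`, and `reassignments`.
#' @examples
#' genetic_code_table("TAG_to_Q")$stop_codons  # "TAA" "TGA"
#' @export
genetic_code_table <- function(code_id = c("standard", "TAG_to_Q", "TGA_to_W")) {
  code_id <- match.arg(code_id)
  tab <- STANDARD_CODE
  reassign <- character(0)
  if (code_id == "TAG_to_Q") {
    tab["TAG"] <- "Q"; reassign <- c(TAG = "Q")
  } else if (code_id == "TGA_to_W") {
    tab["TGA"] <- "W"; reassign <- c(TGA = "W")
  }
  structure(list(code_id = code_id, table = tab,
                 stop_codons = names(tab)[tab == "*"],
                 reassignments = reassign),
            class = "genetic_code_table")
}

#' @export
print.genetic_code_table <- function(x, ...) {
  cat("<genetic_code_table>", x$code_id,
      "| stops:", paste(x$stop_codons, collapse = ","), "\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split a DNA string into codons starting at `offset` (0-based).
codons_of <- function(dna, offset = 0L) {
  n <- nchar(dna)
  starts <- seq.int(offset + 1L, n - 2L, by = 3L)
  if (length(starts) == 0L || offset + 3L > n) return(character(0))
  substring(dna, starts, starts + 2L)
}

#' Translate DNA under a genetic code table
#'
#' Translation is codon-by-codon from position 1 of `dna`; trailing partial
#' codons are dropped. Stops render as `"*"`, codons with ambiguous bases as
#' `"X"`.
#'
#' @param dna a single DNA string.
#' @param code a [genetic_code_table()].
#' @return a single amino-acid string.
#' @export
translate_dna <- function(dna, code = genetic_code_table("standard")) {
  cs <- codons_of(toupper(dna))
  if (length(cs) == 0L) return("")
  aa <- unname(code$table[cs])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Classify a tRNA anticodon as an isotype or stop-codon suppressor
#'
#' A tRNA is a suppressor iff the reverse complement of its anticodon
#' (5'->3') is one of the standard stop codons TAA, TAG, TGA; exactly the
#' anticodons TTA, CTA and TCA qualify. Non-suppressors are assigned the
#' standard-code isotype of the codon they decode.
#'
#' @param anticodon a 3-mer over A/C/G/T (5'->3').
#' @return a list with `isotype` (three-letter amino-acid name or `"Sup"`)
#'   and `suppressor_target` (the suppressed stop codon, or `NA`).
#' @examples
#' classify_trna_suppressor("TTA")  # suppressor of TAA
#' classify_trna_suppressor("TTG")  # Gln
#' @export
classify_trna_suppressor <- function(anticodon) {
  anticodon <- toupper(anticodon)
  if (!is.character(anticodon) || length(anticodon) != 1L ||
      nchar(anticodon) != 3L || grepl("[^ACGT]", anticodon))
    stop("anticodon must be a single 3-mer over A/C/G/T")
  codon <- revcomp(anticodon)
  aa1 <- unname(STANDARD_CODE[codon])
  if (aa1 == "*")
    return(list(isotype = "Sup", suppressor_target = codon))
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  list(isotype = unname(three[aa1]), suppressor_target = NA_character_)
}

# Count in-frame stop-codon occurrences of the three standard stops within
# an interval [start, end) on the given strand, reading codons in the frame
# anchored at `start` (forward) or `end` (reverse).
count_inframe_stops <- function(genome, start, end, strand = "+") {
  seg <- substr(genome, start + 1L, end)
  if (strand == "-") seg <- revcomp(seg)
  cs <- codons_of(toupper(seg))
  c(n_TAA = sum(cs == "TAA"), n_TAG = sum(cs == "TAG"), n_TGA = sum(cs == "TGA"))
}
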