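# Format readers/writers and pipeline configuration.
#
# Internal coordinates are 0-based half-open everywhere; conversion to
# 1-based inclusive happens only at format boundaries (GFF3).

#' Read a FASTA file
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33, constant quality)
#' @param reads named character vector.
#' @param path file path.
#' @param quality_char constant per-base quality character (default `"I"`,
#'   Q40).
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (anyDuplicated(names(reads))) stop("duplicate read ids")
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads),
                           "+",
                           vapply(nchar(reads),
                                  function(n) strrep(quality_char, n),
                                  character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write features to GFF3
#'
#' Internal 0-based half-open intervals convert to GFF3 1-based inclusive.
#'
#' @param features data.frame with columns `seqid`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, and optionally `score`, `source`,
#'   `attributes` (preformatted `key=value;...` strings).
#' @param path file path.
#' @export
write_gff3 <- function(features, path) {
  stopifnot(all(c("seqid", "type", "start", "end", "strand") %in%
                  names(features)))
  if (any(features$end < features$start)) stop("interval end before start")
  df <- data.frame(
    seqid = features$seqid,
    source = features$source %||% "crasskit",
    type = features$type,
    start = features$start + 1L,
    end = features$end,
    score = features$score %||% ".",
    strand = features$strand,
    phase = ".",
    attributes = features$attributes %||% ".",
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 file back into internal coordinates
#' @param path file path.
#' @return data.frame with 0-based half-open `start`/`end`.
#' @export
read_gff3 <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- c("seqid", "source", "type", "start", "end", "score",
                 "strand", "phase", "attributes")
  df$start <- df$start - 1L
  df
}

#' Read a newick tree
#' @param x path to a newick file, or a newick string.
#' @return an `ape::phylo` object.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Write a tree to newick
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a TSV report
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Pipeline configuration
#'
#' Collects every numeric threshold of the pipeline with its default
#' (values printed in the underlying analysis where one exists: 50-200 bp
#' repeats, e-value < 0.05, 90/90 clustering, 90%/80% spacer rules, 75%
#' taxonomy, 50%/66% protein match, 0.4 protein clustering, 1001
#' orderings).
#'
#' @param ... overrides of the defaults.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    repeat_min = 50L, repeat_max = 200L,
    evalue_max = 0.05, n_null = 200L, null_m = 3000L,
    min_orf_codons = 60L,
    code_min_markers = 2L, code_min_stops = 2L,
    split_max_span = 15000L,
    cluster_identity_min = 90, cluster_coverage_min = 90,
    cluster_k = 21L, cluster_min_block = 100L,
    spacer_rule_a_identity = 90, spacer_rule_b_identity = 80,
    spacer_identity_min = 70, spacer_seed_len = 12L,
    taxonomy_threshold = 75,
    protein_identity_min = 50, protein_coverage_min = 66,
    protein_cluster_similarity = 0.4,
    abundance_k = 31L,
    rarefaction_orders = 1001L,
    seed = as.integer(seed))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(repeat_min >= 1, repeat_max >= repeat_min,
              evalue_max > 0, n_null >= 10,
              cluster_identity_min >= 0, cluster_identity_min <= 100,
              cluster_coverage_min >= 0, cluster_coverage_min <= 100,
              spacer_rule_a_identity >= spacer_rule_b_identity,
              taxonomy_threshold > 50, taxonomy_threshold <= 100,
              protein_cluster_similarity > 0, protein_cluster_similarity <= 1,
              abundance_k %% 2 == 1, rarefaction_orders >= 1)
  })
  cfg
}

#' Write / read a pipeline config as YAML
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Hash of a configuration (for report provenance)
#' @param cfg a [pipeline_config()].
#' @return md5 string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}
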