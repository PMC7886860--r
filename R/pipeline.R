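# End-to-end orchestration: contigs + reads + spacers -> workspace of
# reports. Stage order: circularity -> marker search -> code inference +
# annotation -> clustering + group assignment -> host assignment ->
# abundance -> pangenome. Each stage logs a funnel line (counts in/out) so
# synthetic funnels are auditable; all reports carry the config hash.

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

# overlap fraction of hit within gene, used to attach profile hits to calls
attach_hits_to_genes <- function(genes, hits) {
  if (is.null(hits) || nrow(hits) == 0L || nrow(genes) == 0L) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(hits))) {
    ov <- pmax(0L, pmin(genes$end, hits$end[i]) - pmax(genes$start, hits$start[i]))
    frac <- ov / (hits$end[i] - hits$start[i])
    j <- which(frac >= 0.5 & genes$strand == hits$strand[i])
    if (length(j))
      out <- rbind(out, data.frame(gene_id = genes$gene_id[j],
                                   profile_name = hits$profile_name[i],
                                   aa_score = hits$aa_score[i],
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Run the full discovery-and-annotation pipeline
#'
#' @param contigs named character vector of contig sequences, or a FASTA
#'   path.
#' @param reads optional named character vector of reads, or a FASTQ path
#'   (abundance stage skipped when absent).
#' @param spacers optional spacer table (`spacer_id`, `sequence`,
#'   `source_assembly`, `taxon_path`, `completeness`) or TSV path (host
#'   stage skipped when absent).
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()].
#' @param profiles profile library.
#' @return invisibly, a list with the per-stage objects and report paths.
#' @export
run_pipeline <- function(contigs, reads = NULL, spacers = NULL,
                         out_dir = tempfile("crasskit_ws_"),
                         config = pipeline_config(),
                         profiles = cached_profiles()) {
  if (is.character(contigs) && length(contigs) == 1L && file.exists(contigs))
    contigs <- read_fasta(contigs)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (is.character(spacers) && length(spacers) == 1L && file.exists(spacers))
    spacers <- read_tsv(spacers)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  write_config(config, file.path(out_dir, "config.yaml"))
  paths <- list(config = file.path(out_dir, "config.yaml"))

  ## 1. circularity
  circ <- screen_circular(contigs, config$repeat_min, config$repeat_max)
  genomes <- vapply(circ$genomes, `[[`, character(1), "sequence")
  stage_log("circularity", "%d contigs in, %d circular genomes",
            length(contigs), length(genomes))
  write_tsv(circ$report, paths$cmags <- file.path(out_dir, "cmags.tsv"))
  write_fasta(genomes, file.path(out_dir, "cmags.fasta"))

  ## 2-3. markers, code inference, annotation
  annotations <- list()
  code_rows <- NULL; gff_rows <- NULL
  for (id in names(genomes)) {
    ann <- annotate_genome(genomes[[id]], profiles = profiles,
                           genome_id = id, seed = config$seed,
                           min_len = config$min_orf_codons)
    annotations[[id]] <- ann
    ev <- ann$code$evidence
    code_rows <- rbind(code_rows, data.frame(
      genome_id = id, code_id = ann$code$code_id,
      n_markers_supporting = ann$code$n_markers_supporting,
      evidence = if (is.null(ev)) "" else
        paste(sprintf("%s:%d/%d/%d", ev$marker, ev$n_TAA, ev$n_TAG, ev$n_TGA),
              collapse = ";"),
      stringsAsFactors = FALSE))
    g <- ann$genes
    if (nrow(g))
      gff_rows <- rbind(gff_rows, data.frame(
        seqid = id, type = "gene", start = g$start, end = g$end,
        strand = g$strand,
        attributes = sprintf("ID=%s;genetic_code=%s", g$gene_id, g$code_id),
        stringsAsFactors = FALSE))
    h <- ann$markers$hits
    if (nrow(h))
      gff_rows <- rbind(gff_rows, data.frame(
        seqid = id, type = "protein_match", start = h$start, end = h$end,
        strand = h$strand,
        attributes = sprintf("Name=%s;evalue=%.3g", h$profile_name, h$evalue),
        stringsAsFactors = FALSE))
  }
  n_recoded <- sum(code_rows$code_id != "standard")
  stage_log("annotation", "%d genomes annotated, %d with alternative codes",
            length(genomes), n_recoded)
  write_tsv(code_rows, paths$codes <- file.path(out_dir, "code_assignments.tsv"))
  if (!is.null(gff_rows))
    write_gff3(gff_rows, paths$gff <- file.path(out_dir, "annotation.gff3"))

  ## 4. clustering + groups
  clusters <- NULL; groups_tab <- NULL
  if (length(genomes) >= 2L) {
    cl <- build_linkage_clusters(genomes,
                                 identity_min = config$cluster_identity_min,
                                 coverage_min = config$cluster_coverage_min,
                                 k = config$cluster_k,
                                 min_block = config$cluster_min_block)
    clusters <- cl$clusters
    stage_log("clustering", "%d genomes -> %d clusters", length(genomes),
              length(unique(clusters$cluster_id)))
    write_tsv(clusters, paths$clusters <- file.path(out_dir, "clusters.tsv"))
    write_tsv(cl$pairs, file.path(out_dir, "pairs.tsv"))
  }
  refs <- group_references(profiles)
  groups_tab <- do.call(rbind, lapply(names(genomes), function(id) {
    code <- genetic_code_table(code_rows$code_id[code_rows$genome_id == id])
    ga <- assign_group(genomes[[id]], references = refs,
                       terl_profile = profiles$TerL, code = code,
                       seed = config$seed)
    data.frame(genome_id = id, group = ga$group %||% NA_character_,
               margin = ga$margin, low_confidence = ga$low_confidence,
               stringsAsFactors = FALSE)
  }))
  rownames(groups_tab) <- NULL
  write_tsv(groups_tab, paths$groups <- file.path(out_dir, "groups.tsv"))

  ## 5. hosts
  hosts <- NULL
  if (!is.null(spacers) && length(genomes)) {
    sm <- match_spacers(spacers, genomes,
                        seed_len = config$spacer_seed_len,
                        identity_min = config$spacer_identity_min)
    hosts <- assign_hosts(sm, rule_a_identity = config$spacer_rule_a_identity,
                          rule_b_identity = config$spacer_rule_b_identity)
    stage_log("hosts", "%d spacer matches -> hosts for %d/%d phages",
              nrow(sm), nrow(hosts), length(genomes))
    write_tsv(hosts, paths$hosts <- file.path(out_dir, "hosts.tsv"))
  } else stage_log("hosts", "skipped (no spacer database)")

  ## 6. abundance
  abundance <- NULL
  if (!is.null(reads) && length(reads) && length(genomes)) {
    gg <- setNames(groups_tab$group, groups_tab$genome_id)
    gg[is.na(gg)] <- "unassigned"
    tree <- group_taxonomy(gg)
    idx <- build_index(genomes, tree, k = config$abundance_k)
    abundance <- abundance_table(reads, idx)
    stage_log("abundance", "%d reads, %d classified",
              length(reads), sum(abundance$leaf_counts))
    write_tsv(abundance$group_fractions,
              paths$abundance <- file.path(out_dir, "abundance_groups.tsv"))
    write_tsv(data.frame(genome_id = names(abundance$leaf_counts),
                         reads = as.integer(abundance$leaf_counts),
                         fraction = as.numeric(abundance$leaf_fractions)),
              file.path(out_dir, "abundance_genomes.tsv"))
  } else stage_log("abundance", "skipped (no reads)")

  ## 7. pangenome
  pangenome <- NULL
  all_genes <- do.call(rbind, lapply(annotations, `[[`, "genes"))
  if (!is.null(all_genes) && nrow(all_genes)) {
    gene_hits <- do.call(rbind, lapply(annotations, function(a)
      attach_hits_to_genes(a$genes, a$markers$hits)))
    prots <- setNames(gsub("\\*$", "", all_genes$protein), all_genes$gene_id)
    cl <- greedy_cluster_proteins(prots,
                                  similarity_min = config$protein_cluster_similarity)
    fams <- annotate_families(all_genes$gene_id, gene_hits, cl)
    fam_by_genome <- split(fams$family_label, all_genes$genome_id)
    pangenome <- rarefaction(fam_by_genome,
                             n_orders = config$rarefaction_orders,
                             seed = config$seed)
    stage_log("pangenome", "%d genes, %d families; pangenome size %d",
              nrow(fams), length(unique(fams$family_label)),
              pangenome$pangenome_size)
    write_tsv(fams, file.path(out_dir, "gene_families.tsv"))
    write_tsv(pangenome$table,
              paths$rarefaction <- file.path(out_dir, "rarefaction.tsv"))
  }

  manifest <- data.frame(report = names(paths),
                         path = basename(unlist(paths)),
                         config_hash = hash, stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(list(out_dir = out_dir, config = config, config_hash = hash,
                 circular = circ, annotations = annotations,
                 code_assignments = code_rows, clusters = clusters,
                 groups = groups_tab, hosts = hosts, abundance = abundance,
                 pangenome = pangenome, paths = paths))
}
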