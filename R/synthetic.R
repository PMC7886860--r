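# Synthetic community generator: phage genomes, host genomes with CRISPR
# arrays, decoy contigs, and read sets, all with serialized ground truth.
#
# Every signal the pipeline detects is planted here: exact terminal direct
# repeats, marker genes derived from the bundled profile consensus at
# controlled divergence, stop-codon reassignment confined to a recoded
# region, group I intron / intein cassettes splitting marker ORFs, tRNA loci
# (including suppressors), CRISPR spacers sampled with mutations from the
# phages, and reads drawn from an abundance vector with substitution errors.

CRASS_GROUPS <- c("Alpha-Gamma", "Beta", "Delta", "Epsilon", "Zeta")

# The read-fraction mix across groups reported for the human gut virome
# (Alpha-Gamma 53.7%, Delta/Epsilon/Zeta 13-18%, Beta 1.6%); used as the
# default community composition.
CRASS_GROUP_MIX <- c("Alpha-Gamma" = 0.537, "Delta" = 0.18, "Epsilon" = 0.15,
                     "Zeta" = 0.117, "Beta" = 0.016)

.pkg_cache <- new.env(parent = emptyenv())

cached_profiles <- function() {
  if (is.null(.pkg_cache$profiles)) .pkg_cache$profiles <- load_profiles()
  .pkg_cache$profiles
}

#' Random DNA at a given GC content
#' @param n length in bp.
#' @param gc GC fraction.
#' @return DNA string.
#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Mutate a protein: each selected position changes to a uniformly random
# *different* residue; exactly round(divergence * n) positions change.
mutate_protein <- function(aa, divergence) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  n_mut <- round(divergence * length(ch))
  if (n_mut > 0) {
    pos <- sample(seq_along(ch), n_mut)
    for (p in pos) {
      alt <- setdiff(names(AA_BACKGROUND), ch[p])
      ch[p] <- sample(alt, 1)
    }
  }
  paste(ch, collapse = "")
}

# Mutate DNA by substitutions at exactly `n_mut` positions (or at `rate`).
# `protect` keeps an interval of positions mutation-free.
mutate_dna <- function(dna, rate = NULL, n_mut = NULL, protect = NULL) {
  ch <- strsplit(toupper(dna), "", fixed = TRUE)[[1]]
  if (is.null(n_mut)) n_mut <- rbinom(1, length(ch), rate)
  cand <- seq_along(ch)
  if (!is.null(protect)) cand <- setdiff(cand, protect)
  if (n_mut > length(cand)) stop("mutate_dna: too many mutations requested")
  if (n_mut > 0) {
    pos <- sample_safe(cand, n_mut)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Mutate a genome by random substitutions
#'
#' @param genome DNA string.
#' @param rate per-base substitution probability.
#' @param seed integer seed.
#' @return mutated DNA string.
#' @export
mutate_genome <- function(genome, rate, seed) {
  with_seed(seed, mutate_dna(genome, rate = rate))
}

# Uniform synonymous back-translation of a protein under the standard code;
# never emits TAA/TAG/TGA, so marker CDSs are stop-free until recoding
# plants reassigned stops. Returns a character vector of codons.
back_translate <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  sense <- split(names(STANDARD_CODE)[STANDARD_CODE != "*"],
                 STANDARD_CODE[STANDARD_CODE != "*"])
  vapply(ch, function(a) {
    opts <- sense[[a]]
    if (is.null(opts)) stop("back_translate: unknown residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Group reference TerL proteins
#'
#' The bundled per-group TerL reference proteins (members of the bundled
#' TerL alignment, 25% diverged from its ancestor): phage generation draws
#' each genome's TerL from its group's reference, and group assignment
#' compares back to these references.
#'
#' @param ... ignored (compatibility).
#' @param dir profile data directory (bundled set by default).
#' @return named character vector, group -> reference TerL protein.
#' @export
group_references <- function(..., dir = system.file("extdata", "profiles",
                                                    package = "crasskit")) {
  if (is.null(.pkg_cache$group_refs)) {
    refs <- read_fasta(file.path(dir, "group_refs.synthetic.afa"))
    .pkg_cache$group_refs <- refs[CRASS_GROUPS]
  }
  .pkg_cache$group_refs
}

#' Specification of one synthetic phage genome
#'
#' @param genome_id identifier.
#' @param length target genome (circle) length in bp.
#' @param gc backbone GC content.
#' @param repeat_len exact terminal direct repeat length in bp
#'   (50-200), or `NA` for a linear contig.
#' @param code genetic code: `"standard"`, `"TAG_to_Q"` or `"TGA_to_W"`.
#' @param recoded_region `"whole"` (default) or a character vector of marker
#'   names whose span forms the recoded ("late gene") region.
#' @param recode_density fraction of codons in the recoded part of each
#'   marker rewritten to the reassigned stop codon (minimum 2 per marker).
#' @param markers marker names to plant (must exist in the profile library).
#' @param marker_divergence amino-acid divergence of planted markers from
#'   the profile consensus (TerL: from the group reference).
#' @param marker_strands strand per marker (`"+"`/`"-"`, recycled).
#' @param inserts data.frame with columns `marker`, `kind`
#'   (`"intron"`/`"intein"`), and optionally `cassette` (logical, plant the
#'   endonuclease/Hint domain; default TRUE) and `frame_shift` (logical,
#'   introns only; default TRUE).
#' @param trnas character vector of tRNA anticodons to plant.
#' @param group_label one of the crAss-like groups.
#' @return a `phage_spec` list.
#' @export
phage_spec <- function(genome_id, length = 10000L, gc = 0.45,
                       repeat_len = 100L, code = "standard",
                       recoded_region = "whole", recode_density = 0.05,
                       markers = c("TerL", "MCP", "portal"),
                       marker_divergence = 0.15,
                       marker_strands = "+",
                       inserts = NULL, trnas = character(0),
                       group_label = "Alpha-Gamma") {
  code <- match.arg(code, c("standard", "TAG_to_Q", "TGA_to_W"))
  group_label <- match.arg(group_label, CRASS_GROUPS)
  if (!is.na(repeat_len) && (repeat_len < 50L || repeat_len > 200L))
    stop("repeat_len must be in [50, 200] or NA")
  if (!is.null(inserts)) {
    bad <- setdiff(inserts$marker, markers)
    if (length(bad))
      stop("insert refers to marker(s) not in the genome: ",
           paste(bad, collapse = ", "))
    if (is.null(inserts$cassette)) inserts$cassette <- TRUE
    if (is.null(inserts$frame_shift)) inserts$frame_shift <- TRUE
    inserts$frame_shift[inserts$kind == "intein"] <- FALSE
  }
  structure(list(genome_id = genome_id, length = as.integer(length), gc = gc,
                 repeat_len = repeat_len, code = code,
                 recoded_region = recoded_region,
                 recode_density = recode_density, markers = markers,
                 marker_divergence = marker_divergence,
                 marker_strands = rep(marker_strands, length.out = length(markers)),
                 inserts = inserts, trnas = trnas, group_label = group_label),
            class = "phage_spec")
}

# Choose k ordered interior cut points (codon indices, between 1 and
# n_cod - 1) with at least min_frag codons between consecutive cuts and at
# the ends.
choose_cuts <- function(n_cod, k, min_frag = 40L) {
  slack <- n_cod - (k + 1L) * min_frag
  if (slack < 0L)
    stop("marker too short for ", k, " inserts with fragments >= ",
         min_frag, " codons")
  extra <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  min_frag * seq_len(k) + extra
}

# Build a marker gene (with optional recoding and inserts) as a feature:
# returns seq plus truth intervals relative to the feature start.
make_marker_feature <- function(name, protein, code, recode, density,
                                inserts, profiles, gc) {
  codons <- back_translate(protein)
  n_aa <- length(codons)
  stop_codon <- "TAA"

  if (recode && code != "standard") {
    stopc <- if (code == "TAG_to_Q") "TAG" else "TGA"
    target_aa <- if (code == "TAG_to_Q") "Q" else "W"
    elig <- 2:n_aa  # keep the ATG start intact
    pref <- elig[substr(protein, elig, elig) == target_aa]
    n_target <- max(2L, round(density * n_aa))
    pos <- if (length(pref) >= n_target) sample_safe(pref, n_target)
           else c(pref, sample_safe(setdiff(elig, pref), n_target - length(pref)))
    codons[pos] <- stopc
    p <- strsplit(protein, "", fixed = TRUE)[[1]]
    p[pos] <- target_aa
    protein <- paste(p, collapse = "")
  }

  n_ins <- if (is.null(inserts)) 0L else nrow(inserts)
  cuts <- if (n_ins > 0L) choose_cuts(n_aa, n_ins) else integer(0)
  bounds <- c(0L, cuts, n_aa)

  pieces <- character(0)
  frag_rel <- NULL; ins_rel <- NULL
  pos <- 0L
  for (i in seq_len(n_ins + 1L)) {
    frag_cod <- codons[(bounds[i] + 1L):bounds[i + 1L]]
    frag_seq <- paste(frag_cod, collapse = "")
    frag_rel <- rbind(frag_rel,
                      data.frame(start = pos, end = pos + nchar(frag_seq)))
    pieces <- c(pieces, frag_seq)
    pos <- pos + nchar(frag_seq)
    if (i <= n_ins) {
      kind <- inserts$kind[i]
      cassette <- isTRUE(inserts$cassette[i])
      fshift <- isTRUE(inserts$frame_shift[i])
      if (kind == "intein") {
        cass_aa <- mutate_protein(profiles$Hint$consensus, 0.1)
        ins_seq <- paste(back_translate(cass_aa), collapse = "")
        # in-frame by construction (multiple of 3, no stops)
      } else {
        cass <- if (cassette) {
          cass_aa <- mutate_protein(profiles$endonuclease$consensus, 0.1)
          paste0("ATG", paste(back_translate(cass_aa), collapse = ""), "TAA")
        } else ""
        pad <- 220L + sample.int(160L, 2L)
        ins_seq <- paste0(random_dna(pad[1], gc), cass, random_dna(pad[2], gc))
        rem <- nchar(ins_seq) %% 3L
        want <- if (fshift) (rem == 0L) else (rem != 0L)
        if (want) {
          add <- if (fshift) 1L else (3L - rem) %% 3L
          if (add == 0L) add <- 3L
          ins_seq <- paste0(ins_seq, random_dna(add, gc))
        }
      }
      detectable <- if (kind == "intein") "intein"
                    else if (cassette || (nchar(ins_seq) %% 3L != 0L)) "intron"
                    else "unclassified"
      ins_rel <- rbind(ins_rel,
                       data.frame(start = pos, end = pos + nchar(ins_seq),
                                  kind = kind, cassette = cassette,
                                  frame_shift = nchar(ins_seq) %% 3L != 0L,
                                  detectable_as = detectable,
                                  stringsAsFactors = FALSE))
      pieces <- c(pieces, ins_seq)
      pos <- pos + nchar(ins_seq)
    }
  }
  pieces <- c(pieces, stop_codon)
  seq <- paste(pieces, collapse = "")
  frag_rel$end[nrow(frag_rel)] <- frag_rel$end[nrow(frag_rel)] + 3L  # stop codon
  list(seq = seq, protein = protein, fragments = frag_rel, inserts = ins_rel)
}

sample_safe <- function(x, n) {
  if (n <= 0L) return(integer(0))
  if (length(x) == 1L) return(rep(x, length.out = n))
  sample(x, min(n, length(x)))
}

# Flip relative intervals for a minus-strand feature of total length len.
flip_rel <- function(df, len) {
  if (is.null(df) || nrow(df) == 0L) return(df)
  s <- len - df$end; e <- len - df$start
  df$start <- s; df$end <- e
  df[order(df$start), , drop = FALSE]
}

#' Generate one synthetic phage genome with planted truth
#'
#' Assembles a genome from an i.i.d. random backbone, marker genes
#' (back-translated profile consensus mutated to the requested divergence;
#' TerL derives from the group reference), optional stop-codon recoding,
#' intron/intein inserts, tRNA loci and an exact terminal direct repeat.
#'
#' @param spec a [phage_spec()].
#' @param seed integer seed; identical seed and spec give byte-identical
#'   output.
#' @param profiles profile library (defaults to the bundled set).
#' @return a list with `contig` (the emitted sequence, terminal repeat
#'   included when requested) and `truth` (class `phage_truth`).
#' @export
generate_phage <- function(spec, seed, profiles = cached_profiles()) {
  stopifnot(inherits(spec, "phage_spec"))
  missing_p <- setdiff(c(spec$markers,
                         if (!is.null(spec$inserts)) c("Hint", "endonuclease")),
                       names(profiles))
  if (length(missing_p))
    stop("profiles missing for: ", paste(missing_p, collapse = ", "))
  with_seed(seed, {
    refs <- group_references(profiles)
    features <- list()
    for (i in seq_along(spec$markers)) {
      m <- spec$markers[i]
      base <- if (m == "TerL") refs[[spec$group_label]]
              else profiles[[m]]$consensus
      prot <- mutate_protein(base, spec$marker_divergence)
      prot <- paste0("M", substr(prot, 2, nchar(prot)))
      recode_this <- spec$code != "standard" &&
        (identical(spec$recoded_region, "whole") || m %in% spec$recoded_region)
      ins_m <- if (!is.null(spec$inserts))
        spec$inserts[spec$inserts$marker == m, , drop = FALSE] else NULL
      if (!is.null(ins_m) && nrow(ins_m) == 0L) ins_m <- NULL
      feat <- make_marker_feature(m, prot, spec$code, recode_this,
                                  spec$recode_density, ins_m, profiles, spec$gc)
      strand <- spec$marker_strands[i]
      if (strand == "-") {
        len <- nchar(feat$seq)
        feat$seq <- revcomp(feat$seq)
        feat$fragments <- flip_rel(feat$fragments, len)
        feat$inserts <- flip_rel(feat$inserts, len)
      }
      features[[length(features) + 1L]] <-
        list(type = "marker", name = m, strand = strand,
             seq = feat$seq, protein = feat$protein,
             fragments = feat$fragments, inserts = feat$inserts,
             recoded = recode_this)
    }
    for (ac in spec$trnas) {
      body <- random_dna(76, spec$gc)
      substr(body, 35, 37) <- toupper(ac)
      features[[length(features) + 1L]] <-
        list(type = "trna", name = paste0("tRNA-", ac), strand = "+",
             seq = body, anticodon = toupper(ac))
    }

    feat_len <- sum(vapply(features, function(f) nchar(f$seq), numeric(1)))
    n_gap <- length(features) + 1L
    backbone_total <- spec$length - feat_len
    if (backbone_total < 60L * n_gap)
      stop("genome length ", spec$length,
           " too short for the requested features (need > ",
           feat_len + 60L * n_gap, " bp)")
    w <- as.vector(stats::rmultinom(1, backbone_total - 60L * n_gap,
                                    rep(1, n_gap))) + 60L

    parts <- character(0); pos <- 0L
    marker_loci <- NULL; insert_tab <- NULL; trna_tab <- NULL
    marker_proteins <- character(0)
    for (i in seq_along(features)) {
      gap <- random_dna(w[i], spec$gc)
      parts <- c(parts, gap); pos <- pos + w[i]
      f <- features[[i]]
      if (f$type == "marker") {
        fr <- f$fragments; fr$start <- fr$start + pos; fr$end <- fr$end + pos
        marker_loci <- rbind(marker_loci, data.frame(
          marker = f$name, start = pos, end = pos + nchar(f$seq),
          strand = f$strand, n_fragments = nrow(fr),
          fragments = paste(sprintf("%d-%d", fr$start, fr$end), collapse = ","),
          recoded = f$recoded, stringsAsFactors = FALSE))
        marker_proteins[f$name] <- f$protein
        if (!is.null(f$inserts)) {
          it <- f$inserts; it$start <- it$start + pos; it$end <- it$end + pos
          it$marker <- f$name
          insert_tab <- rbind(insert_tab, it)
        }
      } else {
        trna_tab <- rbind(trna_tab, data.frame(
          start = pos, end = pos + 76L, anticodon = f$anticodon,
          stringsAsFactors = FALSE))
      }
      parts <- c(parts, f$seq); pos <- pos + nchar(f$seq)
    }
    parts <- c(parts, random_dna(w[n_gap], spec$gc))
    core <- paste(parts, collapse = "")

    recoded_region <- if (spec$code == "standard") NULL
      else if (identical(spec$recoded_region, "whole")) c(0L, nchar(core))
      else {
        ml <- marker_loci[marker_loci$marker %in% spec$recoded_region, ]
        c(min(ml$start), max(ml$end))
      }

    contig <- if (is.na(spec$repeat_len)) core
              else extend_circular(core, spec$repeat_len)
    truth <- structure(list(
      genome_id = spec$genome_id,
      repeat_len = spec$repeat_len,
      code = spec$code,
      recoded_region = recoded_region,
      group_label = spec$group_label,
      circle_len = nchar(core),
      marker_loci = marker_loci,
      marker_proteins = marker_proteins,
      inserts = insert_tab,
      trnas = trna_tab), class = "phage_truth")
    list(contig = contig, truth = truth)
  })
}

#' Specification of one synthetic host assembly
#'
#' @param assembly_id identifier.
#' @param taxon_path character vector of taxon names, root to leaf.
#' @param completeness `"complete"` or `"draft"`.
#' @param spacers data.frame with columns `source_phage` and `mutations`
#'   (substitutions planted in each spacer), and optionally `length`
#'   (spacer length in bp, default sampled in 28-38).
#' @return a `host_spec` list.
#' @export
host_spec <- function(assembly_id, taxon_path, completeness = "draft",
                      spacers = NULL) {
  completeness <- match.arg(completeness, c("complete", "draft"))
  structure(list(assembly_id = assembly_id, taxon_path = taxon_path,
                 completeness = completeness, spacers = spacers),
            class = "host_spec")
}

#' Generate a synthetic host assembly carrying a CRISPR array
#'
#' Spacers are substrings of the named source phages mutated at exactly
#' `mutations` positions, embedded in a repeat-spacer-...-repeat array
#' (fixed 30-bp repeat) on one contig.
#'
#' @param spec a [host_spec()].
#' @param phages named character vector of phage genome sequences.
#' @param seed integer seed.
#' @return a list with `contig`, and `truth` (class `host_truth`:
#'   `assembly_id`, `taxon_path`, `completeness`, `spacers` data.frame with
#'   `spacer_id`, `sequence`, `source_phage`, `source_start`, `mutations`).
#' @export
generate_host <- function(spec, phages, seed) {
  stopifnot(inherits(spec, "host_spec"))
  sp <- spec$spacers
  if (is.null(sp) || nrow(sp) == 0L) stop("host spec has no spacers")
  missing_ph <- setdiff(sp$source_phage, names(phages))
  if (length(missing_ph))
    stop("spacer source phage(s) absent: ", paste(missing_ph, collapse = ", "))
  with_seed(seed, {
    if (is.null(sp$length))
      sp$length <- sample(28:38, nrow(sp), replace = TRUE)
    if (any(sp$length < 25L | sp$length > 45L))
      stop("spacer lengths must lie in [25, 45]")
    if (any(sp$mutations >= sp$length))
      stop("mutations must be fewer than spacer length")
    repeat30 <- random_dna(30, 0.4)
    seqs <- character(nrow(sp)); starts <- integer(nrow(sp))
    for (i in seq_len(nrow(sp))) {
      g <- phages[[sp$source_phage[i]]]
      L <- sp$length[i]
      if (L > nchar(g)) stop("spacer longer than source phage")
      st <- sample.int(nchar(g) - L + 1L, 1L)
      raw <- substr(g, st, st + L - 1L)
      # mutations avoid one 14 bp window so the protospacer keeps an exact
      # seed-length stretch (mirrors how real spacer matches are anchored)
      anchor <- sample.int(L - 13L, 1L)
      seqs[i] <- mutate_dna(raw, n_mut = sp$mutations[i],
                            protect = anchor:(anchor + 13L))
      starts[i] <- st - 1L
    }
    array <- paste0(repeat30,
                    paste(vapply(seqs, function(s) paste0(s, repeat30),
                                 character(1)), collapse = ""))
    contig <- paste0(random_dna(1500, 0.5), array, random_dna(1500, 0.5))
    truth <- structure(list(
      assembly_id = spec$assembly_id, taxon_path = spec$taxon_path,
      completeness = spec$completeness,
      spacers = data.frame(
        spacer_id = sprintf("%s_sp%02d", spec$assembly_id, seq_len(nrow(sp))),
        sequence = seqs, source_phage = sp$source_phage,
        source_start = starts, mutations = sp$mutations,
        length = sp$length, stringsAsFactors = FALSE)),
      class = "host_truth")
    list(contig = contig, truth = truth)
  })
}

#' Specification of a read community
#'
#' @param abundance named numeric vector of genome fractions (non-negative,
#'   summing to 1 within 1e-9).
#' @param n_reads number of reads to draw.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(abundance, n_reads, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  if (any(abundance < 0) || abs(sum(abundance) - 1) > 1e-9)
    stop("abundance fractions must be non-negative and sum to 1")
  structure(list(abundance = abundance, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' Draw a read set from a synthetic community
#'
#' Reads are drawn from genomes proportionally to the abundance vector;
#' circular genomes are sampled across the origin (the join); each base is
#' substituted with probability `error_rate`. Roughly half the reads come
#' from the reverse strand.
#'
#' @param community a [community_spec()].
#' @param genomes named character vector of genome (circle) sequences
#'   covering all names in the abundance vector.
#' @param circular logical; sample across the origin join (default TRUE).
#' @return a list with `reads` (named character vector; names are read ids)
#'   and `truth` (data.frame: `read_id`, `origin`, `start`, `strand`).
#' @export
generate_reads <- function(community, genomes, circular = TRUE) {
  stopifnot(inherits(community, "community_spec"))
  ab <- community$abundance
  if (!all(names(ab) %in% names(genomes)))
    stop("abundance names missing from genomes: ",
         paste(setdiff(names(ab), names(genomes)), collapse = ", "))
  if (community$n_reads < 1L) stop("n_reads must be >= 1")
  glen <- nchar(genomes[names(ab)])
  if (community$read_length > min(glen))
    stop("read_length exceeds the shortest genome")
  with_seed(community$seed, {
    origin <- sample(seq_along(ab), community$n_reads, replace = TRUE,
                     prob = ab)
    len <- glen[origin]
    start <- if (circular) floor(runif(community$n_reads) * len)
             else floor(runif(community$n_reads) * (len - community$read_length + 1))
    pool <- vapply(genomes[names(ab)], function(g)
      if (circular) paste0(g, substr(g, 1, community$read_length)) else g,
      character(1))
    reads <- cpp_sample_reads(unname(pool), as.integer(origin),
                              as.integer(start), community$read_length,
                              community$error_rate, child_seed())
    rc <- runif(community$n_reads) < 0.5
    reads[rc] <- revcomp(reads[rc])
    ids <- sprintf("read_%06d", seq_len(community$n_reads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, origin = names(ab)[origin],
                            start = start, strand = ifelse(rc, "-", "+"),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a contig pool of phage contigs plus decoys
#'
#' Phage contigs are emitted as given (terminal repeats included); decoys
#' alternate between i.i.d. random sequences and shuffled copies of phage
#' sequences (mono-nucleotide composition preserved). Any decoy that by
#' chance carries a qualifying exact terminal repeat is reshuffled.
#'
#' @param phage_contigs named character vector of phage contig sequences.
#' @param decoys number of decoy contigs.
#' @param seed integer seed.
#' @param decoy_len_range length range for random decoys.
#' @return a list with `contigs` (named character vector) and `truth`
#'   (data.frame: `contig_id`, `class` in phage/decoy_random/decoy_shuffled).
#' @export
generate_contig_pool <- function(phage_contigs, decoys, seed,
                                 decoy_len_range = c(3000L, 12000L)) {
  with_seed(seed, {
    dec <- character(decoys)
    cls <- character(decoys)
    for (i in seq_len(decoys)) {
      shuffled <- i %% 2L == 0L && length(phage_contigs) > 0L
      repeat {
        s <- if (shuffled) {
          src <- phage_contigs[[sample.int(length(phage_contigs), 1L)]]
          paste(sample(strsplit(src, "", fixed = TRUE)[[1]]), collapse = "")
        } else {
          random_dna(sample(seq(decoy_len_range[1], decoy_len_range[2]), 1L),
                     runif(1, 0.35, 0.6))
        }
        if (is.na(find_terminal_repeat(s))) break
      }
      dec[i] <- s
      cls[i] <- if (shuffled) "decoy_shuffled" else "decoy_random"
    }
    names(dec) <- sprintf("decoy_%03d", seq_len(decoys))
    contigs <- c(phage_contigs, dec)
    ord <- sample(seq_along(contigs))
    contigs <- contigs[ord]
    truth <- data.frame(contig_id = names(contigs),
                        class = c(rep("phage", length(phage_contigs)),
                                  cls)[ord],
                        stringsAsFactors = FALSE)
    list(contigs = contigs, truth = truth)
  })
}

#' Generate a cohort of species clusters
#'
#' Generates `n_species` unrelated base phages and, for each, `members`
#' genomes at the given within-species divergence (substitutions only), for
#' clustering validation.
#'
#' @param n_species number of species.
#' @param members genomes per species.
#' @param divergence within-species per-base substitution rate.
#' @param seed integer seed.
#' @param length genome length passed to [phage_spec()].
#' @param ... further arguments to [phage_spec()].
#' @return a list with `genomes` (named character vector) and `truth`
#'   (data.frame: `genome_id`, `species`).
#' @export
generate_species_cohort <- function(n_species = 3L, members = 5L,
                                    divergence = 0.02, seed = 1L,
                                    length = 10000L, ...) {
  with_seed(seed, {
    genomes <- character(0); truth <- NULL
    for (s in seq_len(n_species)) {
      base_id <- sprintf("sp%02d_g01", s)
      base <- generate_phage(phage_spec(base_id, length = length, ...),
                             seed = child_seed())
      circle <- substr(base$contig, 1L,
                       nchar(base$contig) - base$truth$repeat_len)
      genomes[[base_id]] <- circle
      truth <- rbind(truth, data.frame(genome_id = base_id,
                                       species = sprintf("species_%02d", s)))
      for (m in seq_len(members - 1L)) {
        id <- sprintf("sp%02d_g%02d", s, m + 1L)
        genomes[[id]] <- mutate_dna(circle, rate = divergence)
        truth <- rbind(truth, data.frame(genome_id = id,
                                         species = sprintf("species_%02d", s)))
      }
    }
    list(genomes = genomes, truth = truth)
  })
}
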