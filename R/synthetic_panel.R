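# Synthetic wheat-like panel generator.
#
# Emits the inputs the downstream analysis consumes -- per-line coverage
# summaries, binned read-count tracks, a genotype matrix and contig alignment
# records -- directly under a stated statistical model, together with a
# ground-truth table of which lines carry which introgression. Alignment is
# never simulated read-by-read: per bin, mapped read counts are Poisson with
# rate depth * alignable_length / read_length, and covered bases follow the
# Lander-Waterman expectation breadth = 1 - exp(-depth) on the alignable
# fraction of the bin.

#' Specify one introgression feature for the synthetic panel
#'
#' @param feature_id Character identifier, e.g. `"seg2NvS"`.
#' @param chrom Chromosome (or contig) the feature lives on.
#' @param start,end 1-based inclusive interval of the feature on `chrom`.
#' @param carriers Character vector of line ids that carry the feature.
#' @param type One of `"segment"` (a wild-relative segment present in the
#'   matching reference but not the diverged one), `"translocation"` (a
#'   wheat arm replaced by an alien arm, detectable as an arm-sized coverage
#'   loss plus alignment to the alien chromosome of a composite reference),
#'   or `"contig_haplotype"` (a haplotype carried on an assembled contig
#'   appended to the composite reference).
#' @return A list of class `intro_feature`.
#' @export
introgression_spec <- function(feature_id, chrom, start, end, carriers,
                               type = c("segment", "translocation",
                                        "contig_haplotype")) {
  type <- match.arg(type)
  stopifnot(is.character(feature_id), length(feature_id) == 1L,
            start >= 1, end >= start)
  structure(
    list(feature_id = feature_id, chrom = chrom, start = as.numeric(start),
         end = as.numeric(end), carriers = as.character(carriers),
         type = type),
    class = "intro_feature"
  )
}

default_chromosomes <- function(chrom_length = 4e7) {
  stats::setNames(
    rep(chrom_length, 21),
    paste0(rep(1:7, each = 3), c("A", "B", "D"))
  )
}

default_introgressions <- function(line_ids) {
  list(
    # ~2.5% of 2A: cross-reference coverage gain of ~2 percentage points.
    introgression_spec("seg2NvS", "2A", 1, 1e6, line_ids[1:5], "segment"),
    # 23% of 1B: the short arm replaced by the alien (rye-like) arm.
    introgression_spec("trans1RS", "1B", 1, 9.2e6, line_ids[6:9],
                       "translocation"),
    # Haplotype on the appended contig; three carrier lines.
    introgression_spec("hapGb3", "contigGb3", 1, 2.8e6, line_ids[10:12],
                       "contig_haplotype")
  )
}

#' Configuration of the synthetic panel
#'
#' Defaults describe a panel of 30 inbred lines sequenced at 5-20x mean
#' depth, a 21-chromosome wheat-like genome scaled to 40 Mb per chromosome,
#' one wild-relative segment on 2A, one rye-like arm translocation on 1B
#' with a matching alien chromosome, and one haplotype contig with three
#' carrier-specific regions.
#'
#' @param n_lines Number of inbred lines.
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width in bp for chromosome read-count tracks.
#' @param depth_range Length-2 numeric; per-line mean depths are drawn
#'   uniformly from this range (defaults 5-20x).
#' @param read_length Read length in bp.
#' @param introgressions List of [introgression_spec()] objects; `NULL`
#'   gives the default three features.
#' @param epsilon_conserved Fraction of alien sequence conserved enough to
#'   attract alignments from lines that do not carry it (in `[0, 1)`).
#' @param alien_chrom_name,alien_chrom_length Alien chromosome appended to
#'   the composite reference.
#' @param alien_arm_fraction Fraction of the alien chromosome homologous to
#'   the translocated arm (carriers align fully there).
#' @param contig_name,contig_length,contig_bin_size Haplotype contig
#'   appended to the composite reference and its (finer) track bin width.
#' @param contig_unique_regions 2-column matrix of bp intervals on the
#'   contig that only haplotype carriers cover.
#' @param contig_junk_regions 2-column matrix of bp intervals (assembly
#'   artifacts) that no line covers beyond conserved background.
#' @param contig_window,contig_target Reference window (bp interval and
#'   sequence) used when simulating contig-to-reference alignment records.
#' @param het_error Residual heterozygous-call rate for the inbred panel.
#' @param n_sites Number of variant sites simulated.
#' @param maf_range Range of the uniform true-allele-frequency spectrum.
#' @param mq_high,mq_low Mean mapping quality of well-matched vs
#'   conserved-background alignments.
#' @param mean_baseq Mean base quality reported in coverage records.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 30,
                       chromosomes = default_chromosomes(),
                       bin_size = 1e6,
                       depth_range = c(5, 20),
                       read_length = 150,
                       introgressions = NULL,
                       epsilon_conserved = 0.01,
                       alien_chrom_name = "1R",
                       alien_chrom_length = 4e7,
                       alien_arm_fraction = 0.3,
                       contig_name = "contigGb3",
                       contig_length = 2.8e6,
                       contig_bin_size = 1e5,
                       contig_unique_regions = rbind(c(4e5 + 1, 5e5),
                                                     c(1.2e6 + 1, 1.5e6),
                                                     c(2.2e6 + 1, 2.4e6)),
                       contig_junk_regions = rbind(c(1, 1e5),
                                                   c(1e6 + 1, 1.1e6),
                                                   c(2.7e6 + 1, 2.8e6)),
                       contig_window = c(597e6, 609e6),
                       contig_target = "7D",
                       het_error = 0.005,
                       n_sites = 3000,
                       maf_range = c(0, 0.5),
                       mq_high = 35,
                       mq_low = 12,
                       mean_baseq = 36,
                       seed = 1) {
  line_ids <- sprintf("L%02d", seq_len(n_lines))
  if (is.null(introgressions)) {
    introgressions <- default_introgressions(line_ids)
  }
  cfg <- structure(
    list(n_lines = n_lines, line_ids = line_ids, chromosomes = chromosomes,
         bin_size = bin_size, depth_range = depth_range,
         read_length = read_length, introgressions = introgressions,
         epsilon_conserved = epsilon_conserved,
         alien_chrom_name = alien_chrom_name,
         alien_chrom_length = alien_chrom_length,
         alien_arm_fraction = alien_arm_fraction,
         contig_name = contig_name, contig_length = contig_length,
         contig_bin_size = contig_bin_size,
         contig_unique_regions = contig_unique_regions,
         contig_junk_regions = contig_junk_regions,
         contig_window = contig_window, contig_target = contig_target,
         het_error = het_error, n_sites = n_sites, maf_range = maf_range,
         mq_high = mq_high, mq_low = mq_low, mean_baseq = mean_baseq,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_lines < 1) stopf("n_lines must be >= 1")
  if (any(config$chromosomes <= 0)) stopf("chromosome lengths must be > 0")
  if (is.null(names(config$chromosomes))) stopf("chromosomes must be named")
  if (config$bin_size <= 0) stopf("bin_size must be > 0")
  if (any(config$depth_range <= 0)) stopf("depth_range must be positive")
  if (config$read_length <= 0) stopf("read_length must be > 0")
  if (config$epsilon_conserved < 0 || config$epsilon_conserved >= 1) {
    stopf("epsilon_conserved must lie in [0, 1)")
  }
  if (config$alien_arm_fraction < 0 || config$alien_arm_fraction > 1) {
    stopf("alien_arm_fraction must lie in [0, 1]")
  }
  for (feat in config$introgressions) {
    len <- feature_seq_length(config, feat$chrom)
    if (is.na(len)) {
      stopf("feature '%s': unknown sequence '%s'", feat$feature_id, feat$chrom)
    }
    if (feat$start < 1 || feat$end > len) {
      stopf("feature '%s': interval outside its sequence", feat$feature_id)
    }
    unknown <- setdiff(feat$carriers, config$line_ids)
    if (length(unknown)) {
      stopf("feature '%s': unknown carrier line(s) %s", feat$feature_id,
            paste(unknown, collapse = ", "))
    }
  }
  # Overlapping features on one chromosome are rejected.
  by_chrom <- split(config$introgressions,
                    vapply(config$introgressions, `[[`, "", "chrom"))
  for (feats in by_chrom) {
    if (length(feats) < 2) next
    ivs <- do.call(rbind, lapply(feats, function(f) c(f$start, f$end)))
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    if (any(ivs[-1, 1] <= ivs[-nrow(ivs), 2])) {
      stopf("overlapping introgression intervals on chromosome '%s'",
            feats[[1]]$chrom)
    }
  }
  invisible(config)
}

feature_seq_length <- function(config, seqname) {
  if (seqname %in% names(config$chromosomes)) {
    return(unname(config$chromosomes[seqname]))
  }
  if (identical(seqname, config$alien_chrom_name)) {
    return(config$alien_chrom_length)
  }
  if (identical(seqname, config$contig_name)) {
    return(config$contig_length)
  }
  NA_real_
}

reference_ids <- c("REF_MATCH", "REF_OTHER", "REF_COMPOSITE")

# Sequence table (name, length) for one of the three references.
reference_sequences <- function(config, reference_id) {
  if (!reference_id %in% reference_ids) {
    stopf("unknown reference_id '%s' (expected one of %s)", reference_id,
          paste(reference_ids, collapse = ", "))
  }
  seqs <- data.frame(name = names(config$chromosomes),
                     length = unname(config$chromosomes),
                     role = "wheat", stringsAsFactors = FALSE)
  if (reference_id == "REF_COMPOSITE") {
    extra <- data.frame(
      name = c(config$alien_chrom_name, config$contig_name),
      length = c(config$alien_chrom_length, config$contig_length),
      role = c("alien", "contig"), stringsAsFactors = FALSE
    )
    seqs <- rbind(seqs, extra)
  }
  seqs
}

#' Build the synthetic panel: three references and a truth table
#'
#' Returns descriptions of the three reference genomes the study design
#' assumes -- `REF_MATCH` (carries the segment features, like an adapted
#' cultivar reference), `REF_OTHER` (lacks them, like the standard
#' reference), and `REF_COMPOSITE` (`REF_OTHER` plus an alien chromosome and
#' the haplotype contig) -- together with the per-line ground truth:
#' simulated mean depth and carrier flags for every feature.
#'
#' @param config A [sim_config()].
#' @return A list of class `intro_panel` with elements `config`,
#'   `references` (named list of sequence tables) and `truth` (data frame
#'   with `line_id`, `depth` and one logical column per feature).
#' @export
build_panel <- function(config) {
  validate_sim_config(config)
  depths <- with_seed(derive_seed(config$seed, 1L), {
    round(stats::runif(config$n_lines, config$depth_range[1],
                       config$depth_range[2]), 2)
  })
  truth <- data.frame(line_id = config$line_ids, depth = depths,
                      stringsAsFactors = FALSE)
  for (feat in config$introgressions) {
    truth[[feat$feature_id]] <- truth$line_id %in% feat$carriers
  }
  structure(
    list(config = config,
         references = stats::setNames(
           lapply(reference_ids, reference_sequences, config = config),
           reference_ids
         ),
         truth = truth),
    class = "intro_panel"
  )
}

# Intervals (2-col matrix, bp, 1-based) of `seqname` where line `line_id`
# only aligns through conserved background (epsilon) rather than matching
# sequence, for the given reference.
conserved_only_intervals <- function(config, truth, line_id, reference_id,
                                     seqname, seqlen) {
  row <- truth[truth$line_id == line_id, , drop = FALSE]
  ivs <- NULL
  add <- function(ivs, start, end) rbind(ivs, c(start, end))

  if (seqname %in% names(config$chromosomes)) {
    for (feat in config$introgressions) {
      if (!identical(feat$chrom, seqname)) next
      carrier <- isTRUE(row[[feat$feature_id]])
      if (feat$type == "segment") {
        # REF_MATCH carries the alien segment: non-carriers fall back to
        # conserved background there. The other references carry the native
        # segment instead, which carriers lack.
        if (reference_id == "REF_MATCH" && !carrier) {
          ivs <- add(ivs, feat$start, feat$end)
        }
        if (reference_id != "REF_MATCH" && carrier) {
          ivs <- add(ivs, feat$start, feat$end)
        }
      } else if (feat$type == "translocation") {
        # Every wheat reference carries the wheat arm the carriers lost.
        if (carrier) ivs <- add(ivs, feat$start, feat$end)
      }
    }
  } else if (identical(seqname, config$alien_chrom_name)) {
    arm_end <- round(config$alien_arm_fraction * seqlen)
    trans_feats <- Filter(function(f) f$type == "translocation",
                          config$introgressions)
    carrier <- any(vapply(trans_feats,
                          function(f) isTRUE(row[[f$feature_id]]), logical(1)))
    if (carrier) {
      if (arm_end < seqlen) ivs <- add(ivs, arm_end + 1, seqlen)
    } else {
      ivs <- add(ivs, 1, seqlen)
    }
  } else if (identical(seqname, config$contig_name)) {
    hap_feats <- Filter(function(f) f$type == "contig_haplotype",
                        config$introgressions)
    carrier <- any(vapply(hap_feats,
                          function(f) isTRUE(row[[f$feature_id]]), logical(1)))
    if (!carrier && !is.null(config$contig_unique_regions)) {
      ivs <- rbind(ivs, config$contig_unique_regions)
    }
    if (!is.null(config$contig_junk_regions)) {
      ivs <- rbind(ivs, config$contig_junk_regions)
    }
  }
  ivs
}

# Simulate one line x one sequence: Poisson reads per bin, Lander-Waterman
# covered bases on the alignable fraction, and the per-sequence aggregates.
simulate_sequence <- function(config, depth, eps_ivs, seqlen, bin_size) {
  eps <- config$epsilon_conserved
  rl <- config$read_length
  n_bins <- ceiling(seqlen / bin_size)
  starts <- (seq_len(n_bins) - 1) * bin_size + 1
  ends <- pmin(seq_len(n_bins) * bin_size, seqlen)
  bin_len <- ends - starts + 1

  cons_len <- vapply(seq_len(n_bins), function(i) {
    interval_overlap(starts[i], ends[i], eps_ivs)
  }, numeric(1))
  match_len <- bin_len - cons_len
  align_len <- match_len + eps * cons_len

  lambda <- depth * align_len / rl
  reads <- stats::rpois(n_bins, lambda)
  local_depth <- ifelse(align_len > 0, reads * rl / align_len, 0)
  covered <- round(align_len * (1 - exp(-local_depth)))

  w_match <- ifelse(align_len > 0, match_len / align_len, 0)
  total_reads <- sum(reads)
  meanmapq <- if (total_reads > 0) {
    sum(reads * (w_match * config$mq_high + (1 - w_match) * config$mq_low)) /
      total_reads
  } else {
    0
  }
  list(reads = reads, covered = covered,
       numreads = total_reads, covbases = sum(covered),
       meandepth = total_reads * rl / seqlen, meanmapq = meanmapq)
}

#' Simulate per-line coverage against one reference
#'
#' For every line in the truth table, draws binned mapped-read counts
#' (Poisson with rate `depth * alignable_length / read_length`) over every
#' sequence of the chosen reference, derives covered bases from the
#' Lander-Waterman expectation `1 - exp(-depth)` on the alignable fraction
#' of each bin, and aggregates them into one coverage record per sequence
#' (the samtools-coverage summary the detectors consume). Alignability is 1
#' where the line's genome matches the reference and `epsilon_conserved`
#' where only conserved background remains (alien sequence against a line
#' that does not carry it, or lost wheat arms in translocation carriers).
#' Mean mapping quality is the read-weighted mix of `mq_high` (matching)
#' and `mq_low` (conserved background).
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [build_panel()].
#' @param reference_id `"REF_MATCH"`, `"REF_OTHER"` or `"REF_COMPOSITE"`.
#' @return A list with `records` (named list: line id -> coverage table,
#'   one row per sequence) and `tracks` (named list: line id -> named list
#'   of [binned_track()] objects with read counts per bin). Deterministic
#'   given `config$seed`.
#' @export
simulate_coverage <- function(config, truth, reference_id) {
  validate_sim_config(config)
  seqs <- reference_sequences(config, reference_id)
  ref_offset <- match(reference_id, reference_ids)

  with_seed(derive_seed(config$seed, 10L + ref_offset), {
    records <- list()
    tracks <- list()
    for (li in seq_len(nrow(truth))) {
      line_id <- truth$line_id[li]
      depth <- truth$depth[li]
      rec_rows <- vector("list", nrow(seqs))
      line_tracks <- vector("list", nrow(seqs))
      for (si in seq_len(nrow(seqs))) {
        seqname <- seqs$name[si]
        seqlen <- seqs$length[si]
        bs <- if (identical(seqname, config$contig_name)) {
          config$contig_bin_size
        } else {
          config$bin_size
        }
        eps_ivs <- conserved_only_intervals(config, truth, line_id,
                                            reference_id, seqname, seqlen)
        sim <- simulate_sequence(config, depth, eps_ivs, seqlen, bs)
        rec_rows[[si]] <- data.frame(
          rname = seqname, startpos = 1, endpos = seqlen,
          numreads = sim$numreads, covbases = sim$covbases,
          coverage = round(100 * sim$covbases / seqlen, 4),
          meandepth = round(sim$meandepth, 4),
          meanbaseq = round(config$mean_baseq + stats::rnorm(1, 0, 0.2), 2),
          meanmapq = round(sim$meanmapq, 2),
          stringsAsFactors = FALSE
        )
        line_tracks[[si]] <- binned_track(seqname, bs, sim$reads,
                                          value_kind = "reads",
                                          seq_length = seqlen)
      }
      rec <- do.call(rbind, rec_rows)
      attr(rec, "line_id") <- line_id
      records[[line_id]] <- coverage_table(rec)
      tracks[[line_id]] <- stats::setNames(line_tracks, seqs$name)
    }
    list(records = records, tracks = tracks)
  })
}

#' Simulate a genotype matrix for the panel
#'
#' Sites carry a true alternate-allele frequency drawn uniformly from
#' `maf_range`; each inbred line is homozygous alternate with that
#' probability, a residual heterozygous call occurs at rate `het_error`,
#' and a genotype is missing with probability `exp(-depth/2)` so that
#' missingness rises as sequencing depth falls. Sites are annotated with a
#' sequence-ontology term drawn from a genome-realistic spectrum (mostly
#' intergenic/intron) so impact summaries can be exercised.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [build_panel()].
#' @return A list with `matrix` (a [genotype_matrix()]) and `site_truth`
#'   (data frame of true allele frequencies per site).
#' @export
simulate_genotypes <- function(config, truth) {
  validate_sim_config(config)
  if (config$n_lines < 2) stopf("genotype simulation needs n_lines >= 2")
  n <- config$n_sites
  with_seed(derive_seed(config$seed, 20L), {
    chrom <- sample(names(config$chromosomes), n, replace = TRUE)
    pos <- floor(stats::runif(n, 1, config$chromosomes[chrom])) + 0
    ord <- order(chrom, pos)
    chrom <- chrom[ord]
    pos <- pos[ord]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    p_alt <- stats::runif(n, max(config$maf_range[1], 1e-9),
                          config$maf_range[2])
    so_pool <- c("intergenic_variant", "intron_variant",
                 "upstream_gene_variant", "downstream_gene_variant",
                 "synonymous_variant", "missense_variant", "stop_gained",
                 "splice_region_variant")
    so_prob <- c(0.55, 0.2, 0.08, 0.08, 0.04, 0.035, 0.005, 0.01)
    so <- sample(so_pool, n, replace = TRUE, prob = so_prob)

    geno <- matrix(NA_integer_, nrow = n, ncol = config$n_lines)
    for (j in seq_len(config$n_lines)) {
      g <- ifelse(stats::runif(n) < p_alt, 2L, 0L)
      is_het <- stats::runif(n) < config$het_error
      g[is_het] <- 1L
      miss <- stats::runif(n) < exp(-truth$depth[j] / 2)
      g[miss] <- NA_integer_
      geno[, j] <- g
    }
    sites <- data.frame(chrom = chrom, pos = pos, ref = unname(ref),
                        alt = unname(alt), so_term = so,
                        stringsAsFactors = FALSE)
    list(matrix = genotype_matrix(sites, geno, truth$line_id),
         site_truth = data.frame(chrom = chrom, pos = pos, p_alt = p_alt))
  })
}

#' Simulate contig-to-reference alignment records
#'
#' Generates PAF-like records for assembled contigs aligned back to a
#' reference chromosome: `n_true` haplotype contigs falling inside the
#' configured target window with mapping quality above 20, plus decoys that
#' either land outside the window or align with low mapping quality. A
#' record is labelled part of the haplotype exactly when it lies fully
#' inside the window with MQ > 20.
#'
#' @param config A [sim_config()] (uses `contig_window` and
#'   `contig_target`).
#' @param n_true Number of genuine haplotype contigs.
#' @param n_decoy Number of decoy records (split between out-of-window and
#'   low-MQ).
#' @return A data frame of alignment records with a logical
#'   `is_haplotype` truth column.
#' @export
simulate_contig_alignments <- function(config, n_true = 6, n_decoy = 6) {
  validate_sim_config(config)
  win <- config$contig_window
  if (length(win) != 2 || win[1] >= win[2]) {
    stopf("contig_window must be an increasing bp interval")
  }
  with_seed(derive_seed(config$seed, 30L), {
    make_rec <- function(id, start, span, mq) {
      data.frame(contig_id = id, contig_len = span,
                 target = config$contig_target,
                 target_start = start, target_end = start + span,
                 mq = mq, strand = sample(c("+", "-"), 1),
                 blocks = as.character(round(span * stats::runif(1, 0.2, 0.9))),
                 stringsAsFactors = FALSE)
    }
    recs <- list()
    wspan <- win[2] - win[1]
    for (i in seq_len(n_true)) {
      span <- round(stats::runif(1, 2e4, 8e5))
      start <- round(stats::runif(1, win[1], win[2] - span))
      recs[[length(recs) + 1]] <-
        make_rec(sprintf("ctg_true_%02d", i), start, span,
                 round(stats::runif(1, 25, 60)))
    }
    n_low <- floor(n_decoy / 2)
    for (i in seq_len(n_decoy)) {
      span <- round(stats::runif(1, 2e4, 8e5))
      if (i <= n_low) {
        # In window but ambiguous mapping.
        start <- round(stats::runif(1, win[1], win[2] - span))
        mq <- round(stats::runif(1, 0, 20))
      } else {
        # Confident mapping but outside the window.
        start <- round(stats::runif(1, max(1, win[1] - 5e7), win[1] - span))
        mq <- round(stats::runif(1, 25, 60))
      }
      recs[[length(recs) + 1]] <-
        make_rec(sprintf("ctg_decoy_%02d", i), start, span, mq)
    }
    out <- do.call(rbind, recs)
    out$is_haplotype <- out$target_start >= win[1] & out$target_end <= win[2] &
      out$mq > 20
    contig_alignments(out)
  })
}
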