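# Multi-stage pipeline driver: simulate -> pav -> contig -> vcfstats ->
# diversity, under one configuration, with a manifest of every output file
# and its checksum so a rerun with the same seed is verifiably identical.

pipeline_stages <- c("simulate", "pav", "contig", "vcfstats", "diversity")

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of `c("simulate", "pav", "contig", "vcfstats",
#'   "diversity")`; stages always execute in dependency order. Non-simulate
#'   stages read the files the simulate stage wrote into `out_dir`.
#' @param sim A [sim_config()].
#' @param thresholds A [pav_thresholds()].
#' @param filter A [filter_config()].
#' @param diversity_window Window width (bp) for the diversity track.
#' @param seed Overrides `sim$seed` when non-`NULL`; recorded in the
#'   manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       stages = pipeline_stages,
                       sim = sim_config(),
                       thresholds = pav_thresholds(),
                       filter = filter_config(),
                       diversity_window = 1e6,
                       seed = NULL) {
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, stages = stages, sim = sim,
         thresholds = thresholds, filter = filter,
         diversity_window = diversity_window),
    class = "run_config"
  )
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order. The simulate stage
#' writes the panel truth table, per-line coverage tables for the three
#' references, alien-chromosome and contig bedgraph tracks, the genotype
#' VCF, the contig-alignment PAF and the configuration as YAML. The pav
#' stage reads the coverage tables back and writes presence-absence calls
#' with their evidence; the contig stage selects window/MQ-passing
#' alignments from the PAF and writes the composite layout; vcfstats
#' filters the VCF at 3% and 5% MAF and writes type counts, per-sample
#' allele summaries and per-arm site counts; diversity writes the windowed
#' per-base diversity track and the neighbor-joining tree of the filtered
#' sites.
#'
#' @param rc A [run_config()].
#' @return Invisibly, the manifest data frame (`stage`, `path`, `md5`),
#'   also written to `manifest.tsv` in `out_dir`. Reruns with the same
#'   configuration and seed produce byte-identical outputs.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(stage = character(0), path = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  emit <- function(stage, path) {
    manifest[nrow(manifest) + 1L, ] <<-
      list(stage, path, unname(tools::md5sum(path)))
  }
  run_stage <- function(stage, body) {
    tryCatch(body, error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  p <- function(...) file.path(rc$out_dir, ...)
  need <- function(path) {
    if (!file.exists(path)) stopf("missing input: %s", path)
    path
  }
  cfg <- rc$sim
  stages <- pipeline_stages[pipeline_stages %in% rc$stages]

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      panel <- build_panel(cfg)
      utils::write.table(panel$truth, p("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("simulate", p("truth.tsv"))
      yaml::write_yaml(config_as_yaml(cfg), p("config.yaml"))
      emit("simulate", p("config.yaml"))
      for (ref_id in names(panel$references)) {
        sim <- simulate_coverage(cfg, panel$truth, ref_id)
        dir.create(p("coverage", ref_id), recursive = TRUE,
                   showWarnings = FALSE)
        for (line_id in names(sim$records)) {
          f <- p("coverage", ref_id, paste0(line_id, ".tsv"))
          write_coverage_table(sim$records[[line_id]], f)
          emit("simulate", f)
        }
        if (ref_id == "REF_COMPOSITE") {
          dir.create(p("tracks"), showWarnings = FALSE)
          for (line_id in names(sim$tracks)) {
            for (seqname in c(cfg$alien_chrom_name, cfg$contig_name)) {
              f <- p("tracks", sprintf("%s_%s.bedgraph", line_id, seqname))
              write_bedgraph(sim$tracks[[line_id]][[seqname]], f)
              emit("simulate", f)
            }
          }
        }
      }
      g <- simulate_genotypes(cfg, panel$truth)
      write_vcf(g$matrix, p("panel.vcf"))
      emit("simulate", p("panel.vcf"))
      aln <- simulate_contig_alignments(cfg)
      write_paf(aln, p("contigs.paf"))
      emit("simulate", p("contigs.paf"))
    })
  }

  if ("pav" %in% stages) {
    run_stage("pav", {
      truth <- utils::read.delim(need(p("truth.tsv")))
      covs <- lapply(reference_ids, function(ref_id) {
        recs <- lapply(truth$line_id, function(line_id) {
          rec <- read_coverage_table(
            need(p("coverage", ref_id, paste0(line_id, ".tsv")))
          )
          attr(rec, "line_id") <- line_id
          rec
        })
        list(records = stats::setNames(recs, truth$line_id))
      })
      names(covs) <- reference_ids
      calls <- call_panel_pav(cfg, covs$REF_MATCH, covs$REF_OTHER,
                              covs$REF_COMPOSITE, rc$thresholds)
      utils::write.table(calls, p("pav_calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("pav", p("pav_calls.tsv"))
    })
  }

  if ("contig" %in% stages) {
    run_stage("contig", {
      aln <- read_paf(need(p("contigs.paf")))
      sel <- select_contigs(aln, cfg$contig_target, cfg$contig_window[1],
                            cfg$contig_window[2], mq_min = 20)
      comp <- build_composite(sel)
      utils::write.table(comp$layout, p("composite_layout.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("contig", p("composite_layout.tsv"))
    })
  }

  if ("vcfstats" %in% stages) {
    run_stage("vcfstats", {
      gm <- read_vcf(need(p("panel.vcf")))
      maf3 <- filter_sites(gm, filter_config(0.03, rc$filter$max_missing,
                                             rc$filter$max_het))
      maf5 <- filter_sites(gm, filter_config(0.05, rc$filter$max_missing,
                                             rc$filter$max_het))
      counts <- rbind(
        data.frame(set = "raw", type = c("SNP", "INS", "DEL"),
                   count = as.integer(table(factor(
                     classify_variant_type(gm$sites$ref, gm$sites$alt),
                     levels = c("SNP", "INS", "DEL")
                   )))),
        data.frame(set = "MAF3", type = names(maf3$counts),
                   count = as.integer(maf3$counts)),
        data.frame(set = "MAF5", type = names(maf5$counts),
                   count = as.integer(maf5$counts))
      )
      utils::write.table(counts, p("variant_counts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("vcfstats", p("variant_counts.tsv"))
      utils::write.table(sample_allele_summary(gm), p("allele_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("vcfstats", p("allele_summary.tsv"))
      cen <- cfg$chromosomes / 2
      arms <- bin_by_arm(maf5$matrix$sites, cen)
      utils::write.table(
        data.frame(arm = names(arms), count = as.integer(arms)),
        p("arm_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit("vcfstats", p("arm_counts.tsv"))
    })
  }

  if ("diversity" %in% stages) {
    run_stage("diversity", {
      gm <- read_vcf(need(p("panel.vcf")))
      flt <- filter_sites(gm, rc$filter)$matrix
      track <- windowed_pi(flt, rc$diversity_window, cfg$chromosomes)
      utils::write.table(track, p("pi_track.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("diversity", p("pi_track.tsv"))
      d <- ibs_distance_matrix(flt)
      writeLines(neighbor_joining(d), p("tree.nwk"))
      emit("diversity", p("tree.nwk"))
    })
  }

  utils::write.table(manifest, p("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

# Flatten a sim_config into YAML-friendly scalars and lists.
config_as_yaml <- function(cfg) {
  out <- unclass(cfg)
  out$chromosomes <- as.list(cfg$chromosomes)
  out$introgressions <- lapply(cfg$introgressions, unclass)
  out$contig_unique_regions <- apply(cfg$contig_unique_regions, 1, as.list)
  out$contig_junk_regions <- apply(cfg$contig_junk_regions, 1, as.list)
  out
}
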