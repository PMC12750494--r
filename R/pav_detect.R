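# Presence-absence calling of introgressions from coverage evidence.
#
# Three decision procedures, one per feature class:
#  * cross-reference coverage gain for a segment carried by one reference
#    but not the other (e.g. a ~2 percentage-point gain on the homologous
#    chromosome when switching to the segment-bearing reference);
#  * arm-sized coverage loss on the wheat chromosome that lost its arm to a
#    translocation (~23% below the line's genome-wide baseline), validated
#    by alignment to the alien chromosome of a composite reference (~30%
#    breadth at high MQ for carriers; <2% breadth and <1x depth otherwise);
#  * coverage change between a haplotype contig and the reference region it
#    maps to (small change for carriers, ~30% drop otherwise), refined by
#    carrier-specific high-coverage regions along the contig.

#' Decision thresholds for presence-absence calling
#'
#' @param delta_pp_min Minimum cross-reference coverage gain (percentage
#'   points) to call a segment present (default 2).
#' @param drop_rel_min Minimum relative breadth drop below the line
#'   baseline to call an arm loss (default 0.15, between the ~23% drop a
#'   translocated arm produces and noise).
#' @param alien_present_breadth_min Minimum alien-chromosome breadth (%)
#'   for a carrier call (default 20; carriers show ~30%).
#' @param alien_absent_breadth_max,alien_absent_depth_max Maximum breadth
#'   (%) and mean depth (x) compatible with absence (defaults 2 and 1).
#' @param mq_present_min Minimum mean MQ treated as confident alien-
#'   chromosome evidence (default 30).
#' @param mq_filter_min Mean MQ below which alignments count as
#'   conserved-background noise (default 20).
#' @param region_ratio_min Minimum carrier/non-carrier depth ratio for a
#'   differential bin (default 5).
#' @param region_carrier_depth_min Minimum carrier mean depth (x) for a
#'   differential bin (default 2).
#' @param region_merge_gap Qualifying bins separated by at most this many
#'   non-qualifying bins are merged (default 1).
#' @param region_min_len Minimum region length in bins (default 1).
#' @param contig_change_boundary Contig-vs-reference coverage change (%)
#'   separating carriers (below) from non-carriers (default 20, between the
#'   ~10% change of carriers and the ~30% drop of non-carriers).
#' @return A list of class `pav_thresholds`.
#' @export
pav_thresholds <- function(delta_pp_min = 2.0,
                           drop_rel_min = 0.15,
                           alien_present_breadth_min = 20,
                           alien_absent_breadth_max = 2,
                           alien_absent_depth_max = 1,
                           mq_present_min = 30,
                           mq_filter_min = 20,
                           region_ratio_min = 5,
                           region_carrier_depth_min = 2,
                           region_merge_gap = 1,
                           region_min_len = 1,
                           contig_change_boundary = 20) {
  th <- structure(as.list(environment()), class = "pav_thresholds")
  if (any(unlist(th) < 0)) stopf("thresholds must be non-negative")
  if (th$alien_absent_breadth_max >= th$alien_present_breadth_min) {
    stopf("alien_absent_breadth_max must be < alien_present_breadth_min")
  }
  th
}

pav_call <- function(line_id, feature_id, status, evidence) {
  ev <- as.list(evidence)
  if (any(!is.finite(unlist(ev)))) stopf("non-finite evidence value")
  out <- data.frame(line_id = line_id %||% NA_character_,
                    feature_id = feature_id, status = status,
                    stringsAsFactors = FALSE)
  for (nm in names(ev)) out[[nm]] <- ev[[nm]]
  class(out) <- c("pav_call", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_line <- function(record) attr(record, "line_id", exact = TRUE)

#' Segment presence-absence from a cross-reference coverage gain
#'
#' Compares the coverage percentage of the homologous chromosome of one
#' line against the reference that carries the segment versus the one that
#' does not. A gain of at least `delta_pp_min` percentage points calls the
#' segment present; a loss calls it absent (lines without the segment lose
#' coverage when switching to the segment-bearing reference); anything in
#' between is ambiguous.
#'
#' @param record_carrier_ref,record_other_ref One-row coverage records for
#'   the same line and chromosome against the segment-bearing and the
#'   segment-free reference.
#' @param thresholds A [pav_thresholds()].
#' @param feature_id Feature label recorded on the call.
#' @return A one-row `pav_call` data frame with `delta_pp` evidence.
#' @export
call_segment_pav_cross_ref <- function(record_carrier_ref, record_other_ref,
                                       thresholds = pav_thresholds(),
                                       feature_id = "segment") {
  la <- record_line(record_carrier_ref)
  lb <- record_line(record_other_ref)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stopf("records come from different lines ('%s' vs '%s')", la, lb)
  }
  delta_pp <- record_carrier_ref$coverage[1] - record_other_ref$coverage[1]
  status <- if (delta_pp >= thresholds$delta_pp_min) {
    "present"
  } else if (delta_pp < 0) {
    "absent"
  } else {
    "ambiguous"
  }
  pav_call(la %||% lb, feature_id, status, list(delta_pp = delta_pp))
}

#' Arm-loss screen: breadth drop below the line baseline
#'
#' Computes the relative drop of the target chromosome's breadth below the
#' line's genome-wide baseline (unweighted mean breadth over the remaining
#' chromosomes). A drop of at least `drop_rel_min` flags a candidate
#' translocation.
#'
#' @param records Coverage table for one line over its wheat chromosomes.
#' @param target_chrom Chromosome screened for an arm loss.
#' @param thresholds A [pav_thresholds()].
#' @param feature_id Feature label recorded on the call.
#' @return A one-row `pav_call` with `relative_drop` and `baseline`
#'   evidence.
#' @export
call_arm_loss <- function(records, target_chrom,
                          thresholds = pav_thresholds(),
                          feature_id = "arm_loss") {
  if (!target_chrom %in% records$rname) {
    stopf("target chromosome '%s' not among records", target_chrom)
  }
  baseline <- line_baseline(records, exclude = target_chrom)
  if (baseline == 0) stopf("baseline breadth is zero")
  target <- chromosome_breadth(records[records$rname == target_chrom, ,
                                       drop = FALSE])[1]
  drop <- (baseline - target) / baseline
  status <- if (drop >= thresholds$drop_rel_min) "present" else "absent"
  pav_call(record_line(records), feature_id, status,
           list(relative_drop = drop, baseline = baseline))
}

#' Validate a translocation against the alien chromosome
#'
#' From alignment to the composite reference: carriers show substantial
#' breadth of the alien chromosome at confident mapping quality, while
#' non-carriers show only trace breadth (conserved background) at very low
#' mean depth. Everything else is ambiguous.
#'
#' @param record_alien One-row coverage record of the alien chromosome.
#' @param thresholds A [pav_thresholds()].
#' @param feature_id Feature label recorded on the call.
#' @return A one-row `pav_call` with `alien_breadth`, `alien_meandepth`
#'   and `mean_mq` evidence.
#' @export
validate_alien_chromosome <- function(record_alien,
                                      thresholds = pav_thresholds(),
                                      feature_id = "alien_validation") {
  cov <- record_alien$coverage[1]
  dep <- record_alien$meandepth[1]
  mq <- record_alien$meanmapq[1]
  status <- if (cov >= thresholds$alien_present_breadth_min &&
                mq >= thresholds$mq_present_min) {
    "present"
  } else if (cov < thresholds$alien_absent_breadth_max &&
             dep < thresholds$alien_absent_depth_max) {
    "absent"
  } else {
    "ambiguous"
  }
  pav_call(record_line(record_alien), feature_id, status,
           list(alien_breadth = cov, alien_meandepth = dep, mean_mq = mq))
}

#' Find carrier-specific high-coverage regions along a contig
#'
#' Per bin, the ratio of the carrier-group mean depth to the non-carrier
#' mean depth (stabilized by a pseudocount) must reach `region_ratio_min`
#' while the carrier mean reaches `region_carrier_depth_min`; qualifying
#' bins separated by at most `region_merge_gap` non-qualifying bins are
#' merged, and regions shorter than `region_min_len` bins are dropped.
#'
#' @param tracks Named list (line id -> [binned_track()], `value_kind`
#'   `"depth"`) over one contig, all on the same bin grid.
#' @param carriers Character vector of carrier line ids (at least one
#'   carrier and one non-carrier required).
#' @param thresholds A [pav_thresholds()].
#' @param pseudocount Added to the non-carrier mean before the ratio
#'   (default 0.1x).
#' @return Data frame of half-open bin intervals (`start_bin`, `end_bin`,
#'   0-based) in coordinate order.
#' @export
find_differential_regions <- function(tracks, carriers,
                                      thresholds = pav_thresholds(),
                                      pseudocount = 0.1) {
  ids <- names(tracks)
  if (!length(intersect(ids, carriers)) || !length(setdiff(ids, carriers))) {
    stopf("need at least one carrier and one non-carrier track")
  }
  grid <- vapply(tracks, function(t) {
    paste(t$rname, t$bin_size, length(t$values), sep = "|")
  }, "")
  if (length(unique(grid)) != 1) stopf("tracks are not on the same bin grid")

  vals <- do.call(rbind, lapply(tracks, `[[`, "values"))
  is_car <- ids %in% carriers
  car_mean <- colMeans(vals[is_car, , drop = FALSE])
  non_mean <- colMeans(vals[!is_car, , drop = FALSE])
  qualifies <- (car_mean / (non_mean + pseudocount) >=
                  thresholds$region_ratio_min) &
    (car_mean >= thresholds$region_carrier_depth_min)

  merge_bins(qualifies, thresholds$region_merge_gap,
             thresholds$region_min_len)
}

# Merge a logical bin mask into half-open [start_bin, end_bin) regions.
merge_bins <- function(qualifies, merge_gap, min_len) {
  idx <- which(qualifies)
  empty <- data.frame(start_bin = integer(0), end_bin = integer(0))
  if (!length(idx)) return(empty)
  breaks <- which(diff(idx) > merge_gap + 1)
  starts <- idx[c(1, breaks + 1)]
  ends <- idx[c(breaks, length(idx))]
  out <- data.frame(start_bin = starts - 1L, end_bin = ends)
  out <- out[out$end_bin - out$start_bin >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contig-vs-reference coverage change
#'
#' The absolute difference between the coverage percentage of the
#' reference region and of the haplotype contig for one line: carriers show
#' a small change (the contig is largely theirs to cover), non-carriers a
#' large drop. A change strictly below `contig_change_boundary` calls the
#' haplotype present.
#'
#' @param record_contig,record_ref_region One-row coverage records of the
#'   contig and of the reference region it maps to, same line.
#' @param thresholds A [pav_thresholds()].
#' @param feature_id Feature label recorded on the call.
#' @return A one-row `pav_call` with `coverage_change` evidence.
#' @export
compare_contig_vs_reference <- function(record_contig, record_ref_region,
                                        thresholds = pav_thresholds(),
                                        feature_id = "contig_haplotype") {
  change <- abs(record_ref_region$coverage[1] - record_contig$coverage[1])
  status <- if (change < thresholds$contig_change_boundary) {
    "present"
  } else {
    "absent"
  }
  pav_call(record_line(record_contig), feature_id, status,
           list(coverage_change = change))
}

#' Run all presence-absence detectors over a simulated panel
#'
#' Orchestrates the three decision procedures for every line: the
#' cross-reference gain for each segment feature, the arm-loss screen plus
#' alien-chromosome validation for each translocation feature, and the
#' contig-vs-reference comparison for each contig haplotype feature.
#'
#' @param config A [sim_config()].
#' @param cov_match,cov_other,cov_composite Outputs of
#'   [simulate_coverage()] for the three references (or equivalently
#'   structured coverage data).
#' @param thresholds A [pav_thresholds()].
#' @return Data frame of calls, one row per line x detector, with a
#'   `detector` column distinguishing the arm-loss screen from the alien
#'   validation for translocation features.
#' @export
call_panel_pav <- function(config, cov_match, cov_other, cov_composite,
                           thresholds = pav_thresholds()) {
  calls <- list()
  add <- function(call, detector) {
    call$detector <- detector
    calls[[length(calls) + 1]] <<- call
  }
  wheat <- names(config$chromosomes)
  for (line_id in names(cov_other$records)) {
    rec_match <- cov_match$records[[line_id]]
    rec_other <- cov_other$records[[line_id]]
    rec_comp <- cov_composite$records[[line_id]]
    for (feat in config$introgressions) {
      if (feat$type == "segment") {
        a <- rec_match[rec_match$rname == feat$chrom, , drop = FALSE]
        b <- rec_other[rec_other$rname == feat$chrom, , drop = FALSE]
        attr(a, "line_id") <- line_id
        attr(b, "line_id") <- line_id
        add(call_segment_pav_cross_ref(a, b, thresholds, feat$feature_id),
            "segment_cross_ref")
      } else if (feat$type == "translocation") {
        wheat_rec <- rec_other[rec_other$rname %in% wheat, , drop = FALSE]
        attr(wheat_rec, "line_id") <- line_id
        add(call_arm_loss(wheat_rec, feat$chrom, thresholds,
                          feat$feature_id), "arm_loss")
        alien <- rec_comp[rec_comp$rname == config$alien_chrom_name, ,
                          drop = FALSE]
        attr(alien, "line_id") <- line_id
        add(validate_alien_chromosome(alien, thresholds, feat$feature_id),
            "alien_validation")
      } else if (feat$type == "contig_haplotype") {
        ctg <- rec_comp[rec_comp$rname == config$contig_name, , drop = FALSE]
        ref <- rec_comp[rec_comp$rname == config$contig_target, ,
                        drop = FALSE]
        attr(ctg, "line_id") <- line_id
        attr(ref, "line_id") <- line_id
        add(compare_contig_vs_reference(ctg, ref, thresholds,
                                        feat$feature_id), "contig_change")
      }
    }
  }
  out <- do.call(rbind, lapply(calls, function(x) {
    base <- x[, c("line_id", "feature_id", "status", "detector")]
    ev <- setdiff(names(x), names(base))
    base$evidence <- paste(sprintf("%s=%.4g", ev, unlist(x[, ev])),
                           collapse = ";")
    base
  }))
  rownames(out) <- NULL
  out
}
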