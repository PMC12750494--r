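# Presence-absence decision procedures.

test_that("segment calls follow the cross-reference coverage gain rule", {
  th <- pav_thresholds()
  present <- call_segment_pav_cross_ref(mk_rec("2A", 86, line_id = "L1"),
                                        mk_rec("2A", 84, line_id = "L1"), th)
  expect_equal(present$status, "present")
  expect_equal(present$delta_pp, 2)

  amb <- call_segment_pav_cross_ref(mk_rec("2A", 84), mk_rec("2A", 84), th)
  expect_equal(amb$status, "ambiguous")
  expect_equal(amb$delta_pp, 0)

  absent <- call_segment_pav_cross_ref(mk_rec("2A", 83), mk_rec("2A", 84.5),
                                       th)
  expect_equal(absent$status, "absent")
  expect_equal(absent$delta_pp, -1.5)

  expect_error(
    call_segment_pav_cross_ref(mk_rec("2A", 86, line_id = "L1"),
                               mk_rec("2A", 84, line_id = "L2"), th),
    "different lines"
  )
})

test_that("segment calling is antisymmetric above the threshold", {
  th <- pav_thresholds()
  set.seed(3)
  for (rep in 1:20) {
    ca <- round(runif(1, 50, 95), 2)
    delta <- sample(c(-1, 1), 1) * runif(1, th$delta_pp_min, 10)
    a <- mk_rec("2A", ca)
    b <- mk_rec("2A", ca - delta)
    fwd <- call_segment_pav_cross_ref(a, b, th)$status
    rev <- call_segment_pav_cross_ref(b, a, th)$status
    expect_equal(sort(c(fwd, rev)), c("absent", "present"))
  }
})

test_that("arm loss is a relative breadth drop below the line baseline", {
  th <- pav_thresholds()
  recs <- coverage_table(rbind(as.data.frame(mk_rec("1B", 66)),
                               as.data.frame(mk_rec("1A", 86)),
                               as.data.frame(mk_rec("2A", 86))))
  call <- call_arm_loss(recs, "1B", th)
  expect_equal(call$status, "present")
  expect_equal(call$relative_drop, (0.86 - 0.66) / 0.86, tolerance = 1e-12)

  flat <- coverage_table(rbind(as.data.frame(mk_rec("1B", 86)),
                               as.data.frame(mk_rec("1A", 86))))
  expect_equal(call_arm_loss(flat, "1B", th)$status, "absent")
  # All breadths equal: no chromosome shows a drop.
  for (chrom in flat$rname) {
    expect_equal(call_arm_loss(flat, chrom, th)$relative_drop, 0)
  }

  zero <- coverage_table(rbind(as.data.frame(mk_rec("1B", 50)),
                               as.data.frame(mk_rec("1A", 0))))
  expect_error(call_arm_loss(zero, "1B", th), "zero")
  expect_error(call_arm_loss(flat, "5D", th), "not among")
})

test_that("alien-chromosome validation separates carriers from background", {
  th <- pav_thresholds()
  carrier <- validate_alien_chromosome(mk_rec("1R", 30, meanmapq = 35), th)
  expect_equal(carrier$status, "present")

  non <- validate_alien_chromosome(mk_rec("1R", 1.5, meandepth = 0.4), th)
  expect_equal(non$status, "absent")

  odd <- validate_alien_chromosome(mk_rec("1R", 10, meanmapq = 25), th)
  expect_equal(odd$status, "ambiguous")
  # High breadth at low MQ is evidence of mismapping, not presence.
  lowq <- validate_alien_chromosome(mk_rec("1R", 35, meanmapq = 18), th)
  expect_equal(lowq$status, "ambiguous")
})

test_that("differential regions merge qualifying bins as specified", {
  th <- pav_thresholds()
  mk_tracks <- function(car_vals, non_vals, n_non = 3) {
    tracks <- c(list(C1 = binned_track("ctg", 1e5, car_vals, "depth")),
                lapply(seq_len(n_non), function(i) {
                  binned_track("ctg", 1e5, non_vals, "depth")
                }))
    names(tracks)[-1] <- paste0("N", seq_len(n_non))
    tracks
  }
  # Carrier depth 10 on 0-based bins 3-5, zero elsewhere.
  car <- rep(0, 10)
  car[4:6] <- 10
  regions <- find_differential_regions(mk_tracks(car, rep(0, 10)), "C1", th)
  expect_equal(regions, data.frame(start_bin = 3L, end_bin = 6L))

  # Identical groups: no signal anywhere.
  same <- find_differential_regions(mk_tracks(car, car), "C1", th)
  expect_equal(nrow(same), 0)

  # A single-bin gap inside a region is bridged; min_len prunes slivers.
  car2 <- rep(0, 12)
  car2[c(3, 5, 6, 10)] <- 10
  r2 <- find_differential_regions(mk_tracks(car2, rep(0, 12)), "C1", th)
  expect_equal(r2$start_bin, c(2L, 9L))
  expect_equal(r2$end_bin, c(6L, 10L))

  expect_error(
    find_differential_regions(mk_tracks(car, rep(0, 10)), character(0), th),
    "carrier"
  )
  bad <- mk_tracks(car, rep(0, 10))
  bad$N1 <- binned_track("ctg", 1e5, rep(0, 7), "depth")
  expect_error(find_differential_regions(bad, "C1", th), "bin grid")
})

test_that("differential regions are invariant to uniform depth scaling", {
  th <- pav_thresholds()
  set.seed(8)
  vals <- matrix(runif(5 * 20, 0, 1), nrow = 5)
  vals[1:2, 6:9] <- vals[1:2, 6:9] + 12
  tracks <- lapply(seq_len(5), function(i) {
    binned_track("ctg", 1e5, vals[i, ], "depth")
  })
  names(tracks) <- c("C1", "C2", "N1", "N2", "N3")
  base <- find_differential_regions(tracks, c("C1", "C2"), th,
                                    pseudocount = 0.1)
  scale <- 7
  scaled <- lapply(tracks, function(t) {
    binned_track(t$rname, t$bin_size, t$values * scale, "depth")
  })
  th_scaled <- pav_thresholds(region_carrier_depth_min =
                                th$region_carrier_depth_min * scale)
  expect_equal(
    find_differential_regions(scaled, c("C1", "C2"), th_scaled,
                              pseudocount = 0.1 * scale),
    base
  )
})

test_that("contig-vs-reference change separates carriers at the boundary", {
  th <- pav_thresholds()
  expect_equal(
    compare_contig_vs_reference(mk_rec("ctg", 83), mk_rec("7D", 93), th)$status,
    "present"
  )
  expect_equal(
    compare_contig_vs_reference(mk_rec("ctg", 63), mk_rec("7D", 93), th)$status,
    "absent"
  )
  # Exactly at the boundary: strict less-than, so absent.
  at <- compare_contig_vs_reference(mk_rec("ctg", 73), mk_rec("7D", 93), th)
  expect_equal(at$coverage_change, 20)
  expect_equal(at$status, "absent")
})

test_that("thresholds validate their own consistency", {
  expect_error(pav_thresholds(alien_absent_breadth_max = 25),
               "alien_absent_breadth_max")
  expect_error(pav_thresholds(drop_rel_min = -1), "non-negative")
})
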