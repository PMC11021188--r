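# Nucleus segmentation, body detection, identity/state classification and
# cell-cycle tracking rules.

test_that("segment_nuclei recovers simulated nuclei", {
  g <- voxel_grid(c(20, 64, 64), c(0.3, 0.15, 0.15))
  nuc <- gen_nuclei(2, g, seed = 6, radius_um = c(2.0, 2.0, 2.0))
  img <- array(2, g$shape)
  img[nuc$labels > 0L] <- 50
  set.seed(1)
  img <- img + array(stats::rnorm(length(img), 0, 0.5), dim(img))
  seg <- segment_nuclei(volume_image(img, g), min_volume = 100L)
  expect_equal(max(seg), 2L)
  # per-nucleus Jaccard >= 0.95 against truth (labels may be permuted)
  for (i in 1:2) {
    tmask <- nuc$labels == i
    j <- max(vapply(1:2, function(k) {
      smask <- seg == k
      sum(tmask & smask) / sum(tmask | smask)
    }, numeric(1)))
    expect_gte(j, 0.95)
  }

  # blob below min volume excluded
  small <- array(0, c(12, 24, 24))
  small[6, 12, 12] <- 100
  seg2 <- segment_nuclei(volume_image(small,
                                      voxel_grid(c(12, 24, 24),
                                                 c(0.3, 0.15, 0.15))),
                         min_volume = 50L)
  expect_equal(max(seg2), 0L)
})

test_that("detect_bodies finds thresholded components within nuclei", {
  g <- voxel_grid(c(16, 48, 48), c(0.3, 0.2, 0.2))
  nuc <- gen_nuclei(1, g, seed = 2, radius_um = c(1.8, 3.0, 3.0))

  # uniform image below threshold -> none
  flat <- volume_image(array(5, g$shape), g, channel = "ser2p")
  expect_length(detect_bodies(flat, intensity_threshold = 10,
                              nuclei = nuc$labels), 0L)

  # two blobs in one nucleus -> two records with the right nucleus label
  sched <- list(list(bodies = list(
    list(identity = "mir430", state = "elongating", appear = 0,
         radius_um = 0.5, intensity = 40),
    list(identity = "mir430", state = "elongating", appear = 0,
         radius_um = 0.5, intensity = 40)),
    fusion_frame = NA, breakdown_frame = NA))
  tl <- gen_timelapse(nuc, sched, n_frames = 1, seed = 3, baseline = 0)
  got <- detect_bodies(tl$frames[[1]]$ser2p, intensity_threshold = 20,
                       min_size = 2, nuclei = tl$labels)
  expect_length(got, 2L)
  expect_true(all(vapply(got, `[[`, numeric(1), "nucleus") == 1))

  # centroids within 1 voxel of the scheduled truth
  tc <- do.call(rbind, lapply(tl$truth$schedule[[1]]$bodies, `[[`,
                              "center_um"))
  for (b in got) {
    d_vox <- sqrt(rowSums(sweep(sweep(tc, 2, b$centroid_um), 2,
                                g$spacing, `/`)^2))
    expect_lt(min(d_vox), 1)
  }

  # threshold is required
  expect_error(detect_bodies(flat, nuclei = nuc$labels), "threshold")
})

test_that("merge_by_reference merges fragments over one reporter object", {
  g <- voxel_grid(c(8, 16, 16), c(0.3, 0.2, 0.2))
  nucl <- array(1L, g$shape)
  img <- array(0, g$shape)
  # two Ser2P fragments over one reporter object
  img[4, 4:6, 4:6] <- 30
  img[4, 4:6, 9:11] <- 30
  vi <- volume_image(img, g, channel = "ser2p")
  frags <- detect_bodies(vi, intensity_threshold = 10, min_size = 2,
                         nuclei = nucl)
  expect_length(frags, 2L)
  ref_obj <- array(FALSE, g$shape); ref_obj[4, 4:6, 4:11] <- TRUE
  merged <- merge_by_reference(frags, list(which(ref_obj)))
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$n_voxels, sum(vapply(frags, `[[`, numeric(1),
                                                "n_voxels")))
  # intensities summed
  expect_equal(merged[[1]]$intensity$ser2p[["total"]],
               sum(vapply(frags, function(b)
                 b$intensity$ser2p[["total"]], numeric(1))))

  # fragments over distinct references stay unmerged
  refA <- array(FALSE, g$shape); refA[4, 4:6, 4:6] <- TRUE
  refB <- array(FALSE, g$shape); refB[4, 4:6, 9:11] <- TRUE
  expect_length(merge_by_reference(frags, list(which(refA), which(refB))),
                2L)
  # no overlap with any reference: unchanged
  refC <- array(FALSE, g$shape); refC[8, 14:16, 14:16] <- TRUE
  expect_length(merge_by_reference(frags, list(which(refC))), 2L)
  # merging never increases the count (property over random scenes)
  expect_lte(length(merged), length(frags))
})

test_that("classify_identity follows the reporter-overlap rule", {
  g <- voxel_grid(c(8, 16, 16), c(0.3, 0.2, 0.2))
  nucl <- array(1L, g$shape)
  img <- array(0, g$shape)
  img[4, 4:6, 4:6] <- 30    # body A
  img[4, 10:12, 10:12] <- 30  # body B
  bodies <- detect_bodies(volume_image(img, g, channel = "ser2p"),
                          intensity_threshold = 10, min_size = 2,
                          nuclei = nucl)
  movie <- array(FALSE, g$shape); movie[4, 4:6, 4:6] <- TRUE
  cls <- classify_identity(bodies, list(which(movie)))
  ids <- vapply(cls, `[[`, character(1), "identity")
  ys <- vapply(cls, function(b) b$centroid_um[2], numeric(1))
  expect_equal(ids[order(ys)], c("mir430", "ectopic"))

  # empty reporter channel -> all ectopic
  cls2 <- classify_identity(bodies, list())
  expect_true(all(vapply(cls2, `[[`, character(1), "identity") ==
                    "ectopic"))
})

test_that("classify_state pairs channels greedily and one-to-one", {
  mk <- function(y, vox) make_body(1, 0, c(1, y, 1), state = NA, vox = vox)

  # coincident Ser5P + Ser2P -> one initiating-elongating record
  st <- classify_state(list(mk(1.0, 1:5)), list(mk(1.05, 6:10)),
                       pairing_radius = 0.5)
  expect_length(st, 1L)
  expect_equal(st[[1]]$state, "initiating-elongating")

  # lone Ser5P -> initiating; lone Ser2P -> elongating
  st2 <- classify_state(list(mk(1.0, 1:5)), list(), 0.5)
  expect_equal(st2[[1]]$state, "initiating")
  st3 <- classify_state(list(), list(mk(1.0, 1:5)), 0.5)
  expect_equal(st3[[1]]$state, "elongating")

  # each input body appears exactly once in the output
  s5 <- lapply(c(0.2, 1.4, 2.9), function(y) mk(y, sample.int(1000, 3)))
  s2 <- lapply(c(0.3, 1.5), function(y) mk(y, 1000 + sample.int(1000, 3)))
  stA <- classify_state(s5, s2, 0.5)
  expect_length(stA, 3L)  # 2 paired + 1 unpaired ser5p
  expect_equal(sum(vapply(stA, `[[`, character(1), "state") ==
                     "initiating-elongating"), 2L)

  # greedy matching equals the exhaustive minimum-total-distance
  # assignment on scenes with well-separated pairings (brute-force oracle
  # over all 3! permutations)
  set.seed(7)
  for (rep in 1:20) {
    base <- c(0, 2, 4)
    y5 <- base + stats::runif(3, -0.15, 0.15)
    y2 <- sample(base) + stats::runif(3, -0.15, 0.15)
    d <- abs(outer(y5, y2, `-`))
    got <- txbodies:::greedy_pairs(d, radius = 0.6)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    costs <- vapply(perms, function(p) sum(d[cbind(1:3, p)]), numeric(1))
    best <- perms[[which.min(costs)]]
    expect_equal(nrow(got), 3L)
    got_perm <- got[order(got[, 1]), 2]
    expect_equal(got_perm, best)
  }

  # order-independence: permuting inputs never changes the state labels
  s5 <- lapply(c(0.1, 1.2, 2.4), function(y) mk(y, sample.int(10000, 2)))
  s2 <- lapply(c(0.15, 2.5), function(y) mk(y, 10000 + sample.int(10000, 2)))
  a <- classify_state(s5, s2, 0.5)
  b <- classify_state(rev(s5), rev(s2), 0.5)
  key <- function(l) sort(vapply(l, function(x)
    paste(x$centroid_um[2], x$state), character(1)))
  expect_equal(key(a), key(b))
})

test_that("track_and_time applies the cell-cycle analysis rules", {
  bd <- function(nuc, fr, y, id = "mir430")
    make_body(nuc, fr, c(1, y, 1), identity = id, state = "initiating")
  breakdown <- data.frame(nucleus = 1:3,
                          breakdown_frame = c(NA, NA, 6))

  # nucleus 2 has bodies only at frame 7 -> excluded
  bodies <- c(lapply(2:5, function(f) bd(1, f, 1.0)),
              list(bd(2, 7, 1.0)))
  tt <- track_and_time(bodies, frames_analysed = 0:7,
                       breakdown = breakdown)
  expect_false(2 %in% tt$nucleus)
  expect_equal(attr(tt, "dropped_single_frame"), 2L)

  # first bodies at frame 4 -> t = 0 at frame 4... here nucleus 1 at 2
  expect_equal(tt$t[tt$nucleus == 1 & tt$frame == 2], 0)
  expect_equal(tt$t[tt$nucleus == 1 & tt$frame == 5], 3)

  # frames >= breakdown excluded
  bodies3 <- lapply(2:7, function(f) bd(3, f, 1.0))
  tt3 <- track_and_time(bodies3, 0:7, breakdown)
  expect_equal(max(tt3$frame), 5)

  # fusion: two tracks converge then merge; reported count stays 2
  fuse <- c(
    lapply(0:2, function(f) bd(1, f, 1.0)),
    lapply(0:2, function(f) bd(1, f, 2.0)),
    lapply(3:5, function(f) bd(1, f, 1.5)))
  ttf <- track_and_time(fuse, 0:5,
                        data.frame(nucleus = 1, breakdown_frame = NA),
                        linking_radius = 1.0)
  expect_equal(ttf$n_mir430_raw, c(2, 2, 2, 1, 1, 1))
  expect_equal(ttf$n_mir430, rep(2, 6))
  expect_equal(ttf$fusions, c(0, 0, 0, 1, 1, 1))

  # unordered frames -> input error
  expect_error(track_and_time(fuse, c(2, 1, 0), breakdown),
               "increasing")
})

test_that("summarize_counts reports compositions with NA when empty", {
  bd <- function(nuc, fr, state) {
    b <- make_body(nuc, fr, c(1, 1, 1), identity = "ectopic",
                   state = state)
    b
  }
  bodies <- unlist(lapply(1:10, function(n)
    lapply(0:1, function(f) bd(n, f, "initiating"))), recursive = FALSE)
  tt <- track_and_time(bodies, 0:1,
                       data.frame(nucleus = 1:10, breakdown_frame = NA))
  sm <- summarize_counts(tt)
  expect_equal(sm$pct_initiating, c(100, 100))
  expect_equal(sm$n_nuclei, c(10, 10))

  # zero bodies at a timepoint -> NA percentages, not 0
  tt0 <- tt
  tt0[tt0$t == 1, c("n_initiating", "n_initiating_elongating",
                    "n_elongating")] <- 0
  sm0 <- summarize_counts(tt0)
  expect_true(is.na(sm0$pct_initiating[sm0$t == 1]))
})

test_that("higher ectopic-body rates order conditions by rank-sum test", {
  # per-nucleus ectopic counts under two simulated conditions; the
  # summarized counts must order correctly (one-sided rank-sum p < 0.05)
  set.seed(123)
  n <- 50
  mk_cond <- function(lambda, offset) {
    bodies <- list()
    for (nuc in seq_len(n)) {
      k <- stats::rpois(1, lambda)
      for (f in 0:2) {
        bodies[[length(bodies) + 1L]] <-
          make_body(nuc, f, c(1, 1, 1), identity = "mir430",
                    state = "initiating")
        if (k > 0) for (j in seq_len(k))
          bodies[[length(bodies) + 1L]] <-
            make_body(nuc, f, c(1, 1 + j, 1), identity = "ectopic",
                      state = "elongating")
      }
    }
    track_and_time(bodies, 0:2,
                   data.frame(nucleus = seq_len(n), breakdown_frame = NA))
  }
  a <- mk_cond(0.3)
  b <- mk_cond(1.5)
  per_nuc <- function(tt) tapply(tt$n_ectopic, tt$nucleus, mean)
  p <- stats::wilcox.test(per_nuc(b), per_nuc(a),
                          alternative = "greater", exact = FALSE)$p.value
  expect_lt(p, 0.05)
})
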