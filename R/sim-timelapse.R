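# Synthetic timelapse scenes: transcription bodies appearing during the
# cell cycle, optional fusion of the two locus-nucleated bodies, and
# nuclear-envelope breakdown after which frames are not analysable.

#' Generate a multi-channel timelapse with scheduled body events
#'
#' Renders `n_frames` frames of three channels -- `ser5p` (initiation mark,
#' also carries the nucleoplasmic baseline used for nucleus segmentation),
#' `ser2p` (elongation mark) and `movie` (locus reporter) -- according to a
#' per-nucleus schedule. A body contributes to `ser5p` when its state
#' involves initiation, to `ser2p` when it involves elongation, and to
#' `movie` when its identity is `"mir430"`. At the fusion frame the two
#' locus bodies of a nucleus are replaced by a single body at their
#' midpoint with the combined volume.
#'
#' @param nuclei output of [gen_nuclei()].
#' @param schedule list with one entry per nucleus label:
#'   `bodies` -- list of `list(identity, state, appear, radius_um,
#'   intensity)` (`appear` = first frame, 0-based); `fusion_frame` --
#'   frame at which the first two `"mir430"` bodies fuse (NA = never);
#'   `breakdown_frame` -- first non-analysable frame (NA = never).
#' @param n_frames number of frames.
#' @param seed integer seed (body placement and noise).
#' @param baseline nucleoplasmic baseline intensity (all channels).
#' @param noise_model `"none"`, `"poisson"` or `"poisson+gaussian"`.
#' @param gaussian_sd read-noise sd for `"poisson+gaussian"`.
#' @return List with `frames` (list over frames of named channel
#'   [volume_image()]s), `labels`, and `truth`: per nucleus and frame the
#'   raw and fusion-adjusted ("reported") body counts by identity, state
#'   composition, events, and the analysable flag.
#' @export
gen_timelapse <- function(nuclei, schedule, n_frames, seed = 1L,
                          baseline = 10, noise_model = "none",
                          gaussian_sd = 0) {
  grid <- nuclei$truth$grid
  labels <- nuclei$labels
  set.seed(as.integer(seed))
  coords_um <- voxel_to_um(grid_voxel_coords(grid), grid)

  # validate monotone schedules and place bodies inside their nuclei
  placed <- list()
  for (nl in seq_along(schedule)) {
    sc <- schedule[[nl]]
    nuc <- nuclei$truth$nuclei[[nl]]
    appears <- vapply(sc$bodies, `[[`, numeric(1), "appear")
    if (is.unsorted(appears))
      stop("gen_timelapse: per-nucleus appearance schedule must be monotone")
    bl <- list()
    for (bi in seq_along(sc$bodies)) {
      b <- sc$bodies[[bi]]
      for (try in seq_len(300L)) {
        u <- stats::runif(3, -0.55, 0.55)
        center <- nuc$center_um + u * nuc$semiaxes_um
        vox <- rasterize_blob(grid, matrix(center, 1), b$radius_um,
                              coords_um)
        if (length(vox) == 0L) next
        if (!all(labels[vox] == nl)) next
        # keep bodies clearly separated so rasterized masks never touch
        gap <- 2 * max(grid$spacing)
        clash <- any(vapply(bl, function(o)
          sqrt(sum((o$center_um - center)^2)) <
            o$radius_um + b$radius_um + gap, logical(1)))
        if (!clash) break
        vox <- integer(0)
      }
      if (length(vox) == 0L)
        stop(sprintf("gen_timelapse: cannot place body %d in nucleus %d",
                     bi, nl))
      bl[[bi]] <- c(b, list(center_um = center, vox = vox, nucleus = nl))
    }
    # fused replacement body for the first two mir430 bodies
    fused <- NULL
    if (!is.null(sc$fusion_frame) && !is.na(sc$fusion_frame)) {
      mir <- which(vapply(bl, `[[`, character(1), "identity") == "mir430")
      if (length(mir) < 2L)
        stop("gen_timelapse: fusion requires two mir430 bodies")
      b1 <- bl[[mir[1]]]; b2 <- bl[[mir[2]]]
      mid <- (b1$center_um + b2$center_um) / 2
      r_f <- (b1$radius_um^3 + b2$radius_um^3)^(1 / 3)
      vox <- rasterize_blob(grid, matrix(mid, 1), r_f, coords_um)
      vox <- vox[labels[vox] == nl]
      if (length(vox) == 0L)
        stop("gen_timelapse: fused body fell outside its nucleus")
      fused <- list(identity = "mir430", state = b1$state,
                    appear = sc$fusion_frame, radius_um = r_f,
                    intensity = b1$intensity, center_um = mid, vox = vox,
                    nucleus = nl, parents = mir)
    }
    placed[[nl]] <- list(bodies = bl, fused = fused,
                         fusion_frame = sc$fusion_frame %||% NA,
                         breakdown_frame = sc$breakdown_frame %||% NA)
  }

  state_channels <- function(state) switch(
    state,
    "initiating" = "ser5p",
    "elongating" = "ser2p",
    "initiating-elongating" = c("ser5p", "ser2p"),
    stop("unknown state: ", state))

  frames <- vector("list", n_frames)
  truth_rows <- list()
  events <- list()
  for (f in seq_len(n_frames) - 1L) {
    arrs <- lapply(c(ser5p = 1, ser2p = 2, movie = 3), function(i)
      array(0, dim = grid$shape))
    arrs$ser5p[labels > 0L] <- baseline
    for (nl in seq_along(placed)) {
      pl <- placed[[nl]]
      analysable <- is.na(pl$breakdown_frame) || f < pl$breakdown_frame
      fused_now <- !is.na(pl$fusion_frame) && f >= pl$fusion_frame
      active <- list()
      for (bi in seq_along(pl$bodies)) {
        b <- pl$bodies[[bi]]
        if (f < b$appear) next
        if (fused_now && !is.null(pl$fused) && bi %in% pl$fused$parents)
          next
        active[[length(active) + 1L]] <- b
      }
      if (fused_now && !is.null(pl$fused) &&
          all(vapply(pl$fused$parents, function(p)
            f >= pl$bodies[[p]]$appear, logical(1))))
        active[[length(active) + 1L]] <- pl$fused
      if (analysable || TRUE) {
        # bodies are rendered regardless; analysability only gates analysis
        for (b in active) {
          for (ch in state_channels(b$state))
            arrs[[ch]][b$vox] <- arrs[[ch]][b$vox] + b$intensity
          if (b$identity == "mir430")
            arrs$movie[b$vox] <- arrs$movie[b$vox] + b$intensity
        }
      }
      ids <- vapply(active, `[[`, character(1), "identity")
      sts <- vapply(active, `[[`, character(1), "state")
      n_mir_raw <- sum(ids == "mir430")
      n_mir_rep <- if (fused_now) n_mir_raw + 1L else n_mir_raw
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        nucleus = nl, frame = f, analysable = analysable,
        n_mir430_raw = n_mir_raw, n_mir430 = n_mir_rep,
        n_ectopic = sum(ids == "ectopic"),
        n_initiating = sum(sts == "initiating"),
        n_initiating_elongating = sum(sts == "initiating-elongating"),
        n_elongating = sum(sts == "elongating"))
      if (!is.na(pl$fusion_frame) && f == pl$fusion_frame)
        events[[length(events) + 1L]] <-
          list(type = "fusion", nucleus = nl, frame = f)
      if (!is.na(pl$breakdown_frame) && f == pl$breakdown_frame)
        events[[length(events) + 1L]] <-
          list(type = "envelope_breakdown", nucleus = nl, frame = f)
    }
    imgs <- lapply(names(arrs), function(ch) {
      a <- arrs[[ch]]
      if (noise_model != "none") {
        a[] <- stats::rpois(length(a), pmax(a, 0))
        if (noise_model == "poisson+gaussian" && gaussian_sd > 0)
          a[] <- a + stats::rnorm(length(a), 0, gaussian_sd)
      }
      volume_image(a, grid, channel = ch, frame = f)
    })
    names(imgs) <- names(arrs)
    frames[[f + 1L]] <- imgs
  }

  truth <- list(per_frame = do.call(rbind, truth_rows), events = events,
                schedule = placed, grid = grid, seed = as.integer(seed),
                breakdown = data.frame(
                  nucleus = seq_along(placed),
                  breakdown_frame = vapply(placed, function(p)
                    as.numeric(p$breakdown_frame), numeric(1))))
  list(frames = frames, labels = labels, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
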