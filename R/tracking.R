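# Per-nucleus tracking of classified transcription bodies over the cell
# cycle, with the analysis rules used for timelapse quantification:
# frames after nuclear-envelope breakdown are excluded, t = 0 is the first
# frame in which bodies appear, single-frame nuclei are discarded, and an
# observed fusion of the two locus-nucleated bodies does not reduce the
# reported body count.

#' Track classified bodies and align nuclei in time
#'
#' @param bodies flat list of classified body records (from
#'   [classify_identity()]/[classify_state()]), each carrying `nucleus`,
#'   `frame`, `centroid_um`, `identity`, `state`.
#' @param frames_analysed integer vector of all analysed frame indices
#'   (time-ordered; an error is raised otherwise).
#' @param breakdown data.frame with columns `nucleus`, `breakdown_frame`
#'   (NA = envelope intact throughout); frames `>= breakdown_frame` are
#'   excluded.
#' @param linking_radius maximum centroid displacement (micrometres)
#'   linking the same body across consecutive frames (default 1.0).
#' @return data.frame with one row per nucleus and analysed frame from its
#'   first body onwards: `nucleus`, `frame`, `t` (frames since first
#'   appearance), raw and fusion-adjusted counts by identity, counts by
#'   state, and `fusions` (cumulative fusion events). Nuclei with bodies in
#'   exactly one analysed frame are dropped; their labels are attached as
#'   attribute `dropped_single_frame`.
#' @export
track_and_time <- function(bodies, frames_analysed, breakdown,
                           linking_radius = 1.0) {
  if (is.unsorted(frames_analysed, strictly = TRUE))
    stop("track_and_time: frames_analysed must be strictly increasing")
  nuclei <- sort(unique(vapply(bodies, function(b) as.integer(b$nucleus),
                               integer(1))))
  out <- list(); dropped <- integer(0)
  for (nl in nuclei) {
    bf <- breakdown$breakdown_frame[match(nl, breakdown$nucleus)]
    frames_ok <- frames_analysed
    if (length(bf) == 1L && !is.na(bf)) frames_ok <- frames_ok[frames_ok < bf]
    nb <- Filter(function(b) b$nucleus == nl && b$frame %in% frames_ok,
                 bodies)
    if (length(nb) == 0L) next
    present <- sort(unique(vapply(nb, function(b) as.integer(b$frame),
                                  integer(1))))
    if (length(present) == 1L) { dropped <- c(dropped, nl); next }
    t0 <- present[1L]
    frames_use <- frames_ok[frames_ok >= t0]

    # link mir430 bodies across consecutive frames to observe fusions
    fusion_frames <- integer(0)
    prev <- NULL
    for (f in frames_use) {
      cur <- Filter(function(b) b$frame == f && b$identity == "mir430", nb)
      if (!is.null(prev) && length(prev) > 0L && length(cur) > 0L) {
        d <- matrix(Inf, length(prev), length(cur))
        for (i in seq_along(prev)) for (j in seq_along(cur))
          d[i, j] <- sqrt(sum((prev[[i]]$centroid_um -
                                 cur[[j]]$centroid_um)^2))
        pairs <- greedy_pairs(d, linking_radius)
        # fusion: an unlinked previous track ends next to a body that
        # another track linked to
        if (length(prev) > length(cur)) {
          un <- setdiff(seq_along(prev), pairs[, 1])
          for (i in un) {
            dd <- vapply(cur, function(b)
              sqrt(sum((prev[[i]]$centroid_um - b$centroid_um)^2)),
              numeric(1))
            near <- which(dd <= linking_radius)
            if (length(near) > 0L && any(near %in% pairs[, 2]))
              fusion_frames <- c(fusion_frames, f)
          }
        }
      }
      prev <- cur
    }

    for (f in frames_use) {
      cur <- Filter(function(b) b$frame == f, nb)
      ids <- vapply(cur, `[[`, character(1), "identity")
      sts <- vapply(cur, function(b)
        if (is.null(b$state) || is.na(b$state)) NA_character_ else b$state,
        character(1))
      fus <- sum(fusion_frames <= f)
      n_mir_raw <- sum(ids == "mir430")
      out[[length(out) + 1L]] <- data.frame(
        nucleus = nl, frame = f, t = f - t0,
        n_mir430_raw = n_mir_raw,
        n_mir430 = n_mir_raw + fus,
        n_ectopic = sum(ids == "ectopic"),
        n_initiating = sum(sts == "initiating", na.rm = TRUE),
        n_initiating_elongating = sum(sts == "initiating-elongating",
                                      na.rm = TRUE),
        n_elongating = sum(sts == "elongating", na.rm = TRUE),
        fusions = fus)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(nucleus = integer(), frame = integer(), t = integer(),
               n_mir430_raw = integer(), n_mir430 = integer(),
               n_ectopic = integer(), n_initiating = integer(),
               n_initiating_elongating = integer(),
               n_elongating = integer(), fusions = integer())
  attr(res, "dropped_single_frame") <- dropped
  res
}

#' Summarize tracked series per timepoint
#'
#' Aggregates a [track_and_time()] table by aligned time `t`: number of
#' nuclei, mean body counts per nucleus by identity, and the percentage
#' composition of body states. At timepoints with zero bodies the
#' percentages are `NA` (undefined), not 0.
#'
#' @param series data.frame from [track_and_time()].
#' @return data.frame keyed by `t`.
#' @export
summarize_counts <- function(series) {
  ts <- sort(unique(series$t))
  rows <- lapply(ts, function(tt) {
    s <- series[series$t == tt, , drop = FALSE]
    n_states <- c(initiating = sum(s$n_initiating),
                  initiating_elongating = sum(s$n_initiating_elongating),
                  elongating = sum(s$n_elongating))
    tot <- sum(n_states)
    pct <- if (tot > 0) 100 * n_states / tot else
      stats::setNames(rep(NA_real_, 3), names(n_states))
    data.frame(t = tt, n_nuclei = length(unique(s$nucleus)),
               mean_mir430 = mean(s$n_mir430),
               mean_ectopic = mean(s$n_ectopic),
               n_bodies = tot,
               pct_initiating = pct[["initiating"]],
               pct_initiating_elongating = pct[["initiating_elongating"]],
               pct_elongating = pct[["elongating"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
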