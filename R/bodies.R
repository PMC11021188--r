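# Transcription-body detection and classification in live-imaging channels.
#
# Bodies are detected by fixed intensity thresholding inside segmented
# nuclei (one threshold per channel per experiment). The large locus-
# nucleated bodies are amorphous and can fragment into several connected
# components; fragments overlapping the same reporter (MOVIE) object are
# re-merged and counted as a single body. Identity is assigned by overlap
# with the reporter channel; initiation/elongation state by proximity
# pairing of Ser5P and Ser2P bodies.

# 3D connected-component labeling (6- or 26-connectivity), vectorized BFS.
label_components <- function(mask, connectivity = 6L) {
  dm <- dim(mask)
  labels <- array(0L, dm)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  offsets <- if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    o[rowSums(abs(o)) > 0, , drop = FALSE]
  }
  remaining <- array(FALSE, dm)
  remaining[fg] <- TRUE
  lab <- 0L
  for (start in fg) {
    if (!remaining[start]) next
    lab <- lab + 1L
    frontier <- start
    remaining[start] <- FALSE
    labels[start] <- lab
    while (length(frontier) > 0L) {
      idx <- linear_to_zyx(frontier, dm)
      nxt <- integer(0)
      for (k in seq_len(nrow(offsets))) {
        nb <- idx
        nb[, 1] <- nb[, 1] + offsets[k, 1]
        nb[, 2] <- nb[, 2] + offsets[k, 2]
        nb[, 3] <- nb[, 3] + offsets[k, 3]
        ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
        if (!any(ok)) next
        lin <- zyx_to_linear(nb[ok, , drop = FALSE], dm)
        lin <- lin[remaining[lin]]
        if (length(lin)) {
          remaining[lin] <- FALSE
          labels[lin] <- lab
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

# Otsu threshold on a 256-bin histogram.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(x, br, all.inside = TRUE), nbins = 256L)
  w <- h / sum(h)
  mids <- (br[-1] + br[-257]) / 2
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mt <- cm[256]
  between <- (mt * cw - cm)^2 / (cw * (1 - cw))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Segment nuclei from a nuclear channel
#'
#' Gaussian smoothing, global thresholding (Otsu by default), 3D connected
#' components, and a minimum-volume filter. Manual curation of the original
#' workflow (removal of debris or mis-merged objects) is modeled as an
#' explicit, reproducible exclusion list of labels.
#'
#' @param img a [volume_image()] of a nuclear channel (DAPI or Ser5P).
#' @param smoothing_sigma_um Gaussian sigma in micrometres per axis.
#' @param threshold numeric threshold, or `"otsu"` (default).
#' @param min_volume minimum component size in voxels.
#' @param exclude integer labels to drop after labeling (curation stand-in).
#' @return Integer label array; labels are renumbered 1..n by decreasing
#'   size.
#' @export
segment_nuclei <- function(img, smoothing_sigma_um = c(0.3, 0.2, 0.2),
                           threshold = "otsu", min_volume = 50L,
                           exclude = integer(0)) {
  sm <- gauss_smooth3(img$data, smoothing_sigma_um / img$grid$spacing)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(as.numeric(sm))
  else as.numeric(threshold)
  labels <- label_components(sm > thr, connectivity = 6L)
  tab <- tabulate(labels[labels > 0L])
  keep <- setdiff(which(tab >= min_volume), exclude)
  keep <- keep[order(-tab[keep])]
  out <- array(0L, dim(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

body_record_row <- function(vox, img_list, grid, nucleus, frame) {
  coords <- linear_to_zyx(vox, grid$shape)
  centroid_vox <- colMeans(coords) - 1  # 0-based
  centroid_um <- centroid_vox * grid$spacing
  rec <- list(voxels = vox, n_voxels = length(vox),
              centroid_um = centroid_um, nucleus = nucleus, frame = frame,
              identity = "unassigned", state = NA_character_,
              intensity = lapply(img_list, function(im)
                c(total = sum(im$data[vox]), mean = mean(im$data[vox]))))
  rec
}

#' Detect transcription bodies by thresholding within nuclei
#'
#' Connected components (26-connectivity) of above-threshold voxels that lie
#' inside segmented nuclei, discarding components smaller than `min_size`.
#' The threshold is a fixed per-channel constant for the whole experiment;
#' no default is provided because the appropriate value depends on the
#' acquisition settings.
#'
#' @param img a [volume_image()] of the body channel.
#' @param intensity_threshold fixed intensity threshold (required).
#' @param min_size minimum body size in voxels.
#' @param nuclei integer nucleus label array.
#' @param extra_channels optional named list of [volume_image()]s whose
#'   intensities are also summarized per body.
#' @return A list of body records: `voxels` (linear indices), `n_voxels`,
#'   `centroid_um`, `nucleus`, `frame`, `identity`, `state`, per-channel
#'   `intensity`.
#' @export
detect_bodies <- function(img, intensity_threshold, min_size = 4L, nuclei,
                          extra_channels = list()) {
  if (missing(intensity_threshold) || !is.finite(intensity_threshold))
    stop("detect_bodies: a finite intensity_threshold is required")
  mask <- (img$data > intensity_threshold) & (nuclei > 0L)
  labels <- label_components(mask, connectivity = 26L)
  n <- max(labels)
  img_list <- c(stats::setNames(list(img), img$channel), extra_channels)
  out <- list()
  for (i in seq_len(n)) {
    vox <- which(labels == i)
    if (length(vox) < min_size) next
    nuc <- as.integer(names(which.max(table(nuclei[vox]))))
    out[[length(out) + 1L]] <-
      body_record_row(vox, img_list, img$grid, nuc, img$frame)
  }
  out
}

#' Merge body fragments that overlap the same reference object
#'
#' The amorphous locus-nucleated bodies can be detected as several
#' fragments; fragments overlapping (>= 1 voxel) the same reference object
#' (e.g. a reporter-channel object) are merged into a single record with the
#' union mask and summed intensities. Never increases the body count.
#'
#' @param bodies list of body records from [detect_bodies()].
#' @param reference_objects list of integer voxel-index vectors (masks).
#' @return Merged list of body records.
#' @export
merge_by_reference <- function(bodies, reference_objects) {
  if (length(bodies) == 0L || length(reference_objects) == 0L)
    return(bodies)
  ref_of <- vapply(bodies, function(b) {
    hits <- which(vapply(reference_objects,
                         function(r) length(intersect(b$voxels, r)) > 0L,
                         logical(1)))
    if (length(hits) == 0L) NA_integer_ else hits[1L]
  }, integer(1))
  out <- bodies[is.na(ref_of)]
  for (r in unique(ref_of[!is.na(ref_of)])) {
    grp <- bodies[which(ref_of == r)]
    if (length(grp) == 1L) { out[[length(out) + 1L]] <- grp[[1L]]; next }
    merged <- grp[[1L]]
    merged$voxels <- sort(unique(unlist(lapply(grp, `[[`, "voxels"))))
    merged$n_voxels <- length(merged$voxels)
    w <- vapply(grp, `[[`, numeric(1), "n_voxels")
    cents <- do.call(rbind, lapply(grp, `[[`, "centroid_um"))
    merged$centroid_um <- colSums(cents * w) / sum(w)
    for (ch in names(merged$intensity)) {
      tot <- sum(vapply(grp, function(b) b$intensity[[ch]]["total"],
                        numeric(1)))
      merged$intensity[[ch]] <- c(total = tot,
                                  mean = tot / merged$n_voxels)
    }
    out[[length(out) + 1L]] <- merged
  }
  # deterministic order regardless of input permutation
  out[order(vapply(out, function(b) min(b$voxels), numeric(1)))]
}

#' Classify body identity from reporter-channel overlap
#'
#' A body overlapping (>= 1 voxel) any reporter (MOVIE) object is a
#' locus-nucleated (`"mir430"`) body; a body with no overlap is
#' `"ectopic"`. Call [merge_by_reference()] first so fragmented bodies are
#' counted once.
#'
#' @param bodies list of body records.
#' @param movie_objects list of integer voxel-index vectors from the
#'   reporter channel (may be empty: everything is then ectopic).
#' @return The body list with `identity` filled in.
#' @export
classify_identity <- function(bodies, movie_objects) {
  for (i in seq_along(bodies)) {
    ov <- length(movie_objects) > 0L &&
      any(vapply(movie_objects,
                 function(r) length(intersect(bodies[[i]]$voxels, r)) > 0L,
                 logical(1)))
    bodies[[i]]$identity <- if (ov) "mir430" else "ectopic"
  }
  bodies
}

#' Classify initiation/elongation state by Ser5P-Ser2P pairing
#'
#' Ser5P marks initiating and Ser2P elongating RNA polymerase II. Bodies
#' from the two channels are paired one-to-one, greedily by ascending
#' centroid distance up to `pairing_radius`. A paired Ser5P body becomes one
#' `"initiating-elongating"` record (union of both masks); unpaired Ser5P
#' bodies are `"initiating"`, unpaired Ser2P bodies `"elongating"`. Every
#' input body is represented exactly once in the output.
#'
#' @param ser5p_bodies,ser2p_bodies body lists from the same frame/nucleus.
#' @param pairing_radius centroid-distance pairing radius in micrometres
#'   (default 0.5).
#' @return Combined list of state-classified body records.
#' @export
classify_state <- function(ser5p_bodies, ser2p_bodies, pairing_radius = 0.5) {
  n5 <- length(ser5p_bodies); n2 <- length(ser2p_bodies)
  if (n5 > 0 && n2 > 0) {
    d <- matrix(Inf, n5, n2)
    for (i in seq_len(n5)) for (j in seq_len(n2))
      d[i, j] <- sqrt(sum((ser5p_bodies[[i]]$centroid_um -
                             ser2p_bodies[[j]]$centroid_um)^2))
    pairs <- greedy_pairs(d, pairing_radius)
  } else pairs <- matrix(integer(0), 0, 2)
  out <- list()
  used5 <- pairs[, 1]; used2 <- pairs[, 2]
  for (k in seq_len(nrow(pairs))) {
    b5 <- ser5p_bodies[[pairs[k, 1]]]
    b2 <- ser2p_bodies[[pairs[k, 2]]]
    m <- b5
    m$voxels <- sort(unique(c(b5$voxels, b2$voxels)))
    m$n_voxels <- length(m$voxels)
    m$centroid_um <- (b5$centroid_um * b5$n_voxels +
                        b2$centroid_um * b2$n_voxels) /
      (b5$n_voxels + b2$n_voxels)
    m$intensity <- c(b5$intensity, b2$intensity)
    m$state <- "initiating-elongating"
    out[[length(out) + 1L]] <- m
  }
  for (i in setdiff(seq_len(n5), used5)) {
    b <- ser5p_bodies[[i]]; b$state <- "initiating"
    out[[length(out) + 1L]] <- b
  }
  for (j in setdiff(seq_len(n2), used2)) {
    b <- ser2p_bodies[[j]]; b$state <- "elongating"
    out[[length(out) + 1L]] <- b
  }
  out[order(vapply(out, function(b) min(b$voxels), numeric(1)))]
}

# Greedy one-to-one matching on a distance matrix: repeatedly take the
# globally smallest admissible distance; ties broken by (row, col) order.
greedy_pairs <- function(d, radius) {
  pairs <- matrix(integer(0), 0, 2)
  repeat {
    m <- min(d)
    if (!is.finite(m) || m > radius) break
    hit <- which(d == m, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1L, ]
    pairs <- rbind(pairs, hit)
    d[hit[1], ] <- Inf
    d[, hit[2]] <- Inf
  }
  unname(pairs)
}
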