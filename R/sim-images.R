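# Synthetic 3D fluorescence scenes with machine-readable ground truth.
#
# The generators in this file emulate the imaging inputs the analysis
# pipeline expects: ellipsoidal interphase nuclei rasterized into label
# images, diffraction-limited spots as anisotropic 3D Gaussians, and larger
# amorphous transcription bodies built from overlapping spheres. Ground
# truth carries every parameter used to render, so downstream detection and
# quantification can be checked against exact expected values.

#' Generate non-overlapping ellipsoidal nuclei as a label image
#'
#' Nuclei are axis-aligned ellipsoids placed by rejection sampling so that
#' their voxel masks do not overlap and fit inside the grid. A voxel belongs
#' to a nucleus when its center lies inside the ellipsoid.
#'
#' @param n_nuclei number of nuclei (>= 1).
#' @param grid a [voxel_grid()].
#' @param seed integer random seed; identical seed + parameters give
#'   bit-identical output.
#' @param radius_um mean ellipsoid semi-axis in micrometres (z, y, x);
#'   per-nucleus semi-axes are jittered by +/- 20%.
#' @param max_tries rejection-sampling budget per nucleus.
#' @return A list with `labels` (integer 3D array, 0 = background, 1..n =
#'   nuclei) and `truth` (list with per-nucleus ellipsoid `center_um`,
#'   `semiaxes_um`, `n_voxels`, plus `grid` and `seed`).
#' @export
gen_nuclei <- function(n_nuclei, grid, seed,
                       radius_um = NULL, max_tries = 200L) {
  stopifnot(n_nuclei >= 1)
  if (is.null(radius_um)) {
    # default: nuclei occupy a sensible fraction of the grid
    ext <- grid$shape * grid$spacing
    radius_um <- pmin(ext / (2.5 * ceiling(n_nuclei^(1 / 3)) + 0.5), ext / 3)
  }
  set.seed(as.integer(seed))
  labels <- array(0L, dim = grid$shape)
  coords_um <- voxel_to_um(grid_voxel_coords(grid), grid)
  ext <- (grid$shape - 1L) * grid$spacing
  nuclei <- vector("list", n_nuclei)
  for (i in seq_len(n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      semi <- radius_um * stats::runif(3, 0.8, 1.2)
      if (any(2 * semi > ext)) semi <- pmin(semi, ext / 2 * 0.95)
      center <- semi + stats::runif(3) * (ext - 2 * semi)
      d2 <- ((coords_um[, 1] - center[1]) / semi[1])^2 +
        ((coords_um[, 2] - center[2]) / semi[2])^2 +
        ((coords_um[, 3] - center[3]) / semi[3])^2
      inside <- which(d2 <= 1)
      if (length(inside) == 0L) next
      if (any(labels[inside] != 0L)) next
      labels[inside] <- i
      nuclei[[i]] <- list(label = i, center_um = as.numeric(center),
                          semiaxes_um = as.numeric(semi),
                          n_voxels = length(inside))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf(paste0("gen_nuclei: could not place nucleus %d of %d ",
                          "without overlap after %d tries; grid too small ",
                          "or radius_um too large"), i, n_nuclei, max_tries))
  }
  list(labels = labels,
       truth = list(nuclei = nuclei, grid = grid, seed = as.integer(seed)))
}

# Render one anisotropic 3D Gaussian A*exp(-sum (x-c)^2 / (2 s^2)) into an
# existing array, point-sampled at voxel centers. Evaluation is restricted
# to a +/- 6 sigma bounding box for speed; `full = TRUE` forces the whole
# grid (used when exact totals matter).
add_gaussian_spot <- function(arr, grid, center_um, amplitude, sigma_um,
                              full = FALSE) {
  s <- grid$shape
  sp <- grid$spacing
  if (full) {
    lo <- c(1L, 1L, 1L); hi <- s
  } else {
    cv <- center_um / sp            # 0-based voxel coords
    rad <- 6 * sigma_um / sp
    lo <- pmax(1L, as.integer(floor(cv - rad)) + 1L)
    hi <- pmin(s, as.integer(ceiling(cv + rad)) + 1L)
    if (any(lo > hi)) return(arr)
  }
  ax <- lapply(1:3, function(d) {
    idx <- seq.int(lo[d], hi[d])
    phys <- (idx - 1) * sp[d]
    exp(-(phys - center_um[d])^2 / (2 * sigma_um[d]^2))
  })
  block <- amplitude * (ax[[1]] %o% ax[[2]] %o% ax[[3]])
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + block
  arr
}

#' Render a spot image from ground truth
#'
#' Renders `background + sum of anisotropic 3D Gaussians` (point-sampled at
#' voxel centers), then applies the chosen noise model. The truth object is
#' never modified.
#'
#' @param truth list with `grid` (a [voxel_grid()]) and `spots`, a list of
#'   spots each holding `center_um` (z,y,x), `amplitude`, `sigma_um` (z,y,x)
#'   and optionally `channel`.
#' @param background constant background intensity (photons).
#' @param noise_model one of `"none"`, `"poisson"`, `"poisson+gaussian"`.
#'   Poisson noise is applied to background + signal (shot noise); the
#'   additive Gaussian term models camera read noise.
#' @param seed integer seed used only when noise is drawn.
#' @param gaussian_sd read-noise standard deviation for
#'   `"poisson+gaussian"`.
#' @param channel channel name stamped on the output image.
#' @return A [volume_image()].
#' @export
gen_spot_image <- function(truth, background = 0,
                           noise_model = c("none", "poisson",
                                           "poisson+gaussian"),
                           seed = 1L, gaussian_sd = 0, channel = "spots") {
  noise_model <- match.arg(noise_model)
  grid <- truth$grid
  spots <- truth$spots
  for (sp in spots) {
    sig_vox <- sp$sigma_um / grid$spacing
    if (any(sig_vox < 0.5))
      stop("gen_spot_image: spot sigma must be >= 0.5 voxel on every axis")
  }
  arr <- array(as.numeric(background), dim = grid$shape)
  for (sp in spots)
    arr <- add_gaussian_spot(arr, grid, sp$center_um, sp$amplitude,
                             sp$sigma_um)
  if (noise_model != "none") {
    set.seed(as.integer(seed))
    arr[] <- stats::rpois(length(arr), pmax(arr, 0))
    if (noise_model == "poisson+gaussian" && gaussian_sd > 0)
      arr[] <- arr + stats::rnorm(length(arr), 0, gaussian_sd)
  }
  volume_image(arr, grid, channel = channel)
}

#' Build a spot ground-truth object
#'
#' Convenience constructor used by tests and simulations: draws `n` spot
#' centers uniformly inside the grid margin and fixed amplitude/sigma unless
#' per-spot values are supplied.
#'
#' @param n number of spots.
#' @param grid a [voxel_grid()].
#' @param seed integer seed.
#' @param amplitude peak amplitude (photons) for all spots.
#' @param sigma_um PSF sigma in micrometres (z, y, x).
#' @param margin_um minimum distance of centers from the grid border.
#' @param min_sep_um minimum pairwise center distance (rejection sampling).
#' @return Truth list with `spots`, `grid`, `seed`.
#' @export
gen_spot_truth <- function(n, grid, seed, amplitude = 100,
                           sigma_um = c(0.3, 0.13, 0.13),
                           margin_um = NULL, min_sep_um = 1.0) {
  set.seed(as.integer(seed))
  ext <- (grid$shape - 1L) * grid$spacing
  if (is.null(margin_um)) margin_um <- 4 * max(sigma_um)
  centers <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(centers) < n && tries < 50000L) {
    tries <- tries + 1L
    cand <- margin_um + stats::runif(3) * (ext - 2 * margin_um)
    ok <- TRUE
    if (nrow(centers) > 0) {
      d <- sqrt(colSums((t(centers) - cand)^2))
      ok <- all(d >= min_sep_um)
    }
    if (ok) centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n)
    stop("gen_spot_truth: could not place spots with requested separation")
  spots <- lapply(seq_len(n), function(i)
    list(center_um = as.numeric(centers[i, ]), amplitude = amplitude,
         sigma_um = as.numeric(sigma_um), channel = "spots"))
  list(spots = spots, grid = grid, seed = as.integer(seed))
}

# Rasterize an amorphous body: union of overlapping spheres ("blobs").
# Returns linear voxel indices (1-based) of the body mask.
rasterize_blob <- function(grid, blob_centers_um, blob_radii_um,
                           coords_um = NULL) {
  if (is.null(coords_um))
    coords_um <- voxel_to_um(grid_voxel_coords(grid), grid)
  inside <- rep(FALSE, nrow(coords_um))
  for (b in seq_along(blob_radii_um)) {
    c_um <- blob_centers_um[b, ]
    d2 <- (coords_um[, 1] - c_um[1])^2 + (coords_um[, 2] - c_um[2])^2 +
      (coords_um[, 3] - c_um[3])^2
    inside <- inside | (d2 <= blob_radii_um[b]^2)
  }
  which(inside)
}

#' Generate a multi-channel nuclear body scene with exact enrichment truth
#'
#' Places amorphous transcription bodies strictly inside their nuclei and
#' renders one image per channel: nuclei carry a baseline nucleoplasmic
#' intensity, bodies add a constant increment in the channels they are
#' present in. Because the noiseless rendering is piecewise constant, the
#' per-nucleus area/intensity summaries -- and hence the expected enrichment
#' statistics -- are computed exactly from the masks.
#'
#' @param nuclei output of [gen_nuclei()].
#' @param body_spec list with one entry per body:
#'   `nucleus` (label), `identity` (`"mir430"` or `"ectopic"`), `channels`
#'   (character vector of channels the body is bright in), `radius_um`
#'   (approximate blob radius), `intensity` (added intensity in its
#'   channels), optional `n_blobs` (default 3) for amorphous shape.
#' @param channels all channel names to render.
#' @param nucleus_baseline baseline nucleoplasm intensity per channel
#'   (named numeric, recycled if a single value).
#' @param seed integer seed (body placement).
#' @param noise_model,gaussian_sd as in [gen_spot_image()].
#' @return List with `images` (named list of [volume_image()]), `labels`
#'   (nucleus label array) and `truth`. Truth contains, per nucleus and
#'   channel, the exact `EnrichmentMeasurement` quantities of the noiseless
#'   rendering (body areas/means, nucleus area/mean) plus the expected
#'   `percentage_area`, `percentage_intensity` and `intensity_enrichment`
#'   computed with zero no-primary background.
#' @export
gen_body_scene <- function(nuclei, body_spec, channels = c("cdk9", "ser2p"),
                           nucleus_baseline = 10, seed = 1L,
                           noise_model = "none", gaussian_sd = 0) {
  grid <- nuclei$truth$grid
  labels <- nuclei$labels
  set.seed(as.integer(seed))
  if (length(nucleus_baseline) == 1L)
    nucleus_baseline <- stats::setNames(rep(nucleus_baseline,
                                            length(channels)), channels)
  coords_um <- voxel_to_um(grid_voxel_coords(grid), grid)

  # place bodies: blob union strictly inside the nucleus ellipsoid
  bodies <- vector("list", length(body_spec))
  for (i in seq_along(body_spec)) {
    bs <- body_spec[[i]]
    nuc <- nuclei$truth$nuclei[[bs$nucleus]]
    n_blobs <- if (is.null(bs$n_blobs)) 3L else bs$n_blobs
    r <- bs$radius_um
    for (try in seq_len(200L)) {
      # anchor center well inside the ellipsoid, blobs jittered around it
      u <- stats::runif(3, -0.35, 0.35)
      anchor <- nuc$center_um + u * nuc$semiaxes_um
      jit <- matrix(stats::runif(3 * n_blobs, -r / 3, r / 3), n_blobs, 3)
      bc <- sweep(jit, 2L, anchor, `+`)
      br <- rep(r, n_blobs)
      vox <- rasterize_blob(grid, bc, br, coords_um)
      if (length(vox) == 0L) next
      if (all(labels[vox] == bs$nucleus) &&
          !any(vox %in% unlist(lapply(bodies[seq_len(i - 1)], `[[`, "vox"))))
        break
      vox <- integer(0)
    }
    if (length(vox) == 0L)
      stop(sprintf("gen_body_scene: could not place body %d inside nucleus %d",
                   i, bs$nucleus))
    bodies[[i]] <- c(bs, list(vox = vox, blob_centers_um = bc,
                              blob_radii_um = br,
                              centroid_um = colMeans(coords_um[vox, ,
                                                               drop = FALSE])))
  }

  # noiseless rendering per channel
  imgs0 <- lapply(channels, function(ch) {
    arr <- array(0, dim = grid$shape)
    arr[labels > 0L] <- nucleus_baseline[[ch]]
    for (b in bodies)
      if (ch %in% b$channels) arr[b$vox] <- arr[b$vox] + b$intensity
    arr
  })
  names(imgs0) <- channels

  # exact per-nucleus, per-channel enrichment truth from the noiseless scene
  measurements <- list()
  for (nuc in nuclei$truth$nuclei) {
    nb <- Filter(function(b) b$nucleus == nuc$label, bodies)
    nuc_vox <- which(labels == nuc$label)
    for (ch in channels) {
      arr <- imgs0[[ch]]
      m <- list(nucleus = nuc$label, channel = ch,
                area_nucleus = length(nuc_vox),
                mean_nucleus = mean(arr[nuc_vox]))
      if (length(nb) >= 1L) {
        m$area_body <- vapply(nb, function(b) length(b$vox), numeric(1))
        m$mean_body <- vapply(nb, function(b) mean(arr[b$vox]), numeric(1))
        em <- enrichment_measurement(
          area_body = m$area_body, mean_body = m$mean_body,
          area_nucleus = m$area_nucleus, mean_nucleus = m$mean_nucleus,
          background = 0, channel = ch)
        m$expected <- list(percentage_area = percentage_area(em),
                           percentage_intensity = percentage_intensity(em),
                           intensity_enrichment = intensity_enrichment(em))
      }
      measurements[[length(measurements) + 1L]] <- m
    }
  }

  images <- lapply(channels, function(ch) {
    arr <- imgs0[[ch]]
    if (noise_model != "none") {
      arr[] <- stats::rpois(length(arr), pmax(arr, 0))
      if (noise_model == "poisson+gaussian" && gaussian_sd > 0)
        arr[] <- arr + stats::rnorm(length(arr), 0, gaussian_sd)
    }
    volume_image(arr, grid, channel = ch)
  })
  names(images) <- channels

  truth <- list(bodies = lapply(bodies, function(b)
    b[setdiff(names(b), "vox")]),
    body_voxels = lapply(bodies, `[[`, "vox"),
    measurements = measurements, grid = grid, seed = as.integer(seed),
    nuclei = nuclei$truth$nuclei)
  list(images = images, labels = labels, truth = truth)
}
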