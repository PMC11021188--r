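# DNA-FISH downstream analysis: nucleus assignment, allele-spot selection,
# 3D distances to the locus channel, and colocalization fractions.
#
# Gene probes label ten genes per group in diploid nuclei, so up to 20
# gene spots per channel are informative; the locus itself has two alleles,
# so its two brightest spots are kept.

#' Assign spots to nuclei by center-voxel membership
#'
#' Each spot is labeled with the nucleus whose mask contains its rounded
#' center voxel; spots falling in background are dropped (count attached as
#' attribute `n_dropped`).
#'
#' @param spots a `spot_record` data.frame (see [detect_spots()]).
#' @param masks integer nucleus label array on the same grid.
#' @param grid the [voxel_grid()] shared by spots and masks.
#' @return The labeled subset of `spots`.
#' @export
assign_spots_to_nuclei <- function(spots, masks, grid) {
  if (nrow(spots) == 0L) {
    attr(spots, "n_dropped") <- 0L
    return(spots)
  }
  idx <- cbind(round(spots$z), round(spots$y), round(spots$x)) + 1L
  idx[, 1] <- pmin(pmax(idx[, 1], 1L), grid$shape[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1L), grid$shape[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1L), grid$shape[3])
  labs <- masks[idx]
  keep <- labs > 0L
  out <- spots[keep, , drop = FALSE]
  out$nucleus <- as.integer(labs[keep])
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Select allele spots per nucleus and channel
#'
#' Keeps the brightest spots in each nucleus/channel group: `k_gene` for
#' gene channels (ten genes visualized per group in diploid nuclei) and
#' `k_mir430` for the locus channel (two alleles). Delegates to
#' [top_k_brightest()]; shortfalls (fewer detected spots than requested)
#' are recorded per group.
#'
#' @param spots nucleus-labeled `spot_record` data.frame.
#' @param k_gene spots kept per gene channel (default 20).
#' @param k_mir430 spots kept for the locus channel (default 2).
#' @param mir430_channel channel name of the locus probe (default
#'   `"mir430"`).
#' @return Subset of `spots`, with attribute `shortfalls` (data.frame of
#'   nucleus, channel, missing count).
#' @export
select_allele_spots <- function(spots, k_gene = 20L, k_mir430 = 2L,
                                mir430_channel = "mir430") {
  out <- list(); shortfalls <- list()
  for (nl in sort(unique(spots$nucleus))) {
    for (ch in sort(unique(spots$channel[spots$nucleus == nl]))) {
      grp <- spots[spots$nucleus == nl & spots$channel == ch, ,
                   drop = FALSE]
      k <- if (ch == mir430_channel) k_mir430 else k_gene
      sel <- top_k_brightest(grp, k)
      if (attr(sel, "shortfall") > 0L)
        shortfalls[[length(shortfalls) + 1L]] <- data.frame(
          nucleus = nl, channel = ch, missing = attr(sel, "shortfall"))
      out[[length(out) + 1L]] <- sel
    }
  }
  res <- if (length(out)) do.call(rbind, out) else spots[0, ]
  rownames(res) <- NULL
  attr(res, "shortfalls") <-
    if (length(shortfalls)) do.call(rbind, shortfalls) else NULL
  res
}

#' 3D distances from gene spots to the nearest locus spot
#'
#' For each gene spot the Euclidean distance (micrometres, anisotropy
#' respected through the spot's physical coordinates) to the NEAREST
#' selected locus spot in the same nucleus. Nuclei lacking either spot set
#' are skipped and listed in attribute `skipped_nuclei`. The identity of
#' the nearest allele is also reported so per-allele analyses remain
#' possible.
#'
#' @param gene_spots,mir430_spots nucleus-labeled `spot_record`
#'   data.frames.
#' @return data.frame: `nucleus`, `channel`, gene-spot coordinates (um),
#'   `nearest_allele` (row index within the nucleus's locus spots),
#'   `distance_um`.
#' @export
distances_to_locus <- function(gene_spots, mir430_spots) {
  out <- list(); skipped <- integer(0)
  for (nl in sort(unique(gene_spots$nucleus))) {
    g <- gene_spots[gene_spots$nucleus == nl, , drop = FALSE]
    m <- mir430_spots[mir430_spots$nucleus == nl, , drop = FALSE]
    if (nrow(g) == 0L || nrow(m) == 0L) { skipped <- c(skipped, nl); next }
    for (i in seq_len(nrow(g))) {
      d <- sqrt((m$z_um - g$z_um[i])^2 + (m$y_um - g$y_um[i])^2 +
                  (m$x_um - g$x_um[i])^2)
      j <- which.min(d)
      out[[length(out) + 1L]] <- data.frame(
        nucleus = nl, channel = g$channel[i],
        z_um = g$z_um[i], y_um = g$y_um[i], x_um = g$x_um[i],
        nearest_allele = j, distance_um = d[j])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(nucleus = integer(), channel = character(), z_um = numeric(),
               y_um = numeric(), x_um = numeric(),
               nearest_allele = integer(), distance_um = numeric())
  rownames(res) <- NULL
  attr(res, "skipped_nuclei") <- skipped
  res
}

#' Fraction of spots colocalized with the locus
#'
#' Fraction of distance records strictly below `radius` (default 0.5 um;
#' the boundary itself does not count). Both pooled (all records) and
#' per-nucleus fractions are returned; the pooled value is the headline
#' number.
#'
#' @param records data.frame from [distances_to_locus()].
#' @param radius colocalization radius in micrometres.
#' @return List: `fraction`, `n_colocalized`, `n_total`, `per_nucleus`
#'   (data.frame).
#' @export
colocalized_fraction <- function(records, radius = 0.5) {
  if (nrow(records) == 0L) stop("colocalized_fraction: no distance records")
  hit <- records$distance_um < radius
  per <- do.call(rbind, lapply(sort(unique(records$nucleus)), function(nl) {
    s <- records$nucleus == nl
    data.frame(nucleus = nl, n_colocalized = sum(hit[s]), n_total = sum(s),
               fraction = mean(hit[s]))
  }))
  list(fraction = mean(hit), n_colocalized = sum(hit),
       n_total = length(hit), per_nucleus = per)
}
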