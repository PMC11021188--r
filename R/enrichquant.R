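# Per-nucleus enrichment statistics for the two large transcription bodies,
# and the eGFP/RFP microRNA-activity sensor ratio.
#
# The three body statistics follow the published summary formulas exactly:
# body means enter the numerators uncorrected while the nucleus mean in the
# denominator is corrected by the no-primary-control background. A fully
# background-corrected variant is available behind an explicit flag and is
# clearly non-canonical.

#' Construct an enrichment measurement
#'
#' One record per nucleus and channel: areas and mean intensities of the
#' (usually two) transcription bodies, of the whole nucleus, and the
#' no-primary-control background level. Areas may be voxel counts (default)
#' or physical units, as long as they are consistent -- the statistics are
#' ratios and therefore unit-free.
#'
#' @param area_body numeric vector of body areas (one entry per body).
#' @param mean_body numeric vector of body mean intensities, same length.
#' @param area_nucleus nucleus area.
#' @param mean_nucleus nucleus mean intensity.
#' @param background mean intensity measured in no-primary control nuclei
#'   (see [background_mean()]).
#' @param channel optional channel name.
#' @param nucleus optional nucleus identifier.
#' @return An object of class `enrichment_measurement`.
#' @export
enrichment_measurement <- function(area_body, mean_body, area_nucleus,
                                   mean_nucleus, background = 0,
                                   channel = NA_character_, nucleus = NA) {
  if (length(area_body) != length(mean_body) || length(area_body) < 1L)
    stop("area_body and mean_body must be non-empty and the same length")
  if (any(area_body <= 0) || area_nucleus <= 0)
    stop("areas must be > 0")
  if (sum(area_body) > area_nucleus)
    stop("combined body area exceeds nucleus area")
  structure(list(area_body = as.numeric(area_body),
                 mean_body = as.numeric(mean_body),
                 area_nucleus = as.numeric(area_nucleus),
                 mean_nucleus = as.numeric(mean_nucleus),
                 background = as.numeric(background),
                 channel = channel, nucleus = nucleus),
            class = "enrichment_measurement")
}

corrected_nucleus_mean <- function(m) {
  corr <- m$mean_nucleus - m$background
  if (!is.finite(corr) || corr <= 0)
    stop(sprintf(paste0("corrected nucleus mean <= 0 for nucleus %s ",
                        "(channel %s): background %.4g >= nucleus mean %.4g"),
                 format(m$nucleus), format(m$channel), m$background,
                 m$mean_nucleus))
  corr
}

#' Mean background from no-primary control nuclei
#'
#' @param control_nucleus_means numeric vector of per-nucleus mean
#'   intensities measured in no-primary-antibody control embryos.
#' @return Their arithmetic mean.
#' @export
background_mean <- function(control_nucleus_means) {
  if (length(control_nucleus_means) < 1L)
    stop("at least one control nucleus is required")
  mean(as.numeric(control_nucleus_means))
}

#' Percentage of nuclear area occupied by the bodies
#'
#' `100 * sum(area_body) / area_nucleus`.
#'
#' @param m an [enrichment_measurement()].
#' @return Percentage in (0, 100].
#' @export
percentage_area <- function(m) {
  100 * sum(m$area_body) / m$area_nucleus
}

#' Percentage of nuclear signal present in the bodies
#'
#' `100 * sum(area_body * mean_body) /
#'   (area_nucleus * (mean_nucleus - background))`.
#' Body means are deliberately uncorrected while the nucleus mean is
#' background-corrected, so values above 100 are possible.
#'
#' @inheritParams percentage_area
#' @param correct_bodies if `TRUE`, subtract the background from the body
#'   means as well (non-canonical variant; the default reproduces the
#'   published formula).
#' @return Finite non-negative percentage.
#' @export
percentage_intensity <- function(m, correct_bodies = FALSE) {
  corr <- corrected_nucleus_mean(m)
  mb <- if (correct_bodies) m$mean_body - m$background else m$mean_body
  100 * sum(m$area_body * mb) / (m$area_nucleus * corr)
}

#' Observed-over-expected mean intensity in the bodies
#'
#' Area-weighted body mean divided by the background-corrected nucleus
#' mean. Satisfies the exact identity
#' `intensity_enrichment == percentage_intensity / percentage_area`.
#'
#' @inheritParams percentage_intensity
#' @return Positive ratio (on non-degenerate data).
#' @export
intensity_enrichment <- function(m, correct_bodies = FALSE) {
  corr <- corrected_nucleus_mean(m)
  mb <- if (correct_bodies) m$mean_body - m$background else m$mean_body
  (sum(m$area_body * mb) / sum(m$area_body)) / corr
}

#' Summarize a set of enrichment measurements
#'
#' Computes the three statistics plus `log2(intensity_enrichment)` (the
#' quantity conventionally tested against zero) for each measurement.
#' Nuclei whose corrected nucleus mean is not positive are excluded with a
#' reason, never silently clamped.
#'
#' @param measurements list of [enrichment_measurement()] objects.
#' @return A data.frame with one row per valid measurement and an
#'   `"excluded"` attribute (data.frame of nucleus/channel/reason).
#' @export
summarize_enrichment <- function(measurements) {
  rows <- list(); excl <- list()
  for (m in measurements) {
    res <- tryCatch({
      data.frame(nucleus = format(m$nucleus), channel = format(m$channel),
                 percentage_area = percentage_area(m),
                 percentage_intensity = percentage_intensity(m),
                 intensity_enrichment = intensity_enrichment(m),
                 log2_enrichment = log2(intensity_enrichment(m)),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        nucleus = format(m$nucleus), channel = format(m$channel),
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nucleus = character(), channel = character(),
               percentage_area = numeric(), percentage_intensity = numeric(),
               intensity_enrichment = numeric(), log2_enrichment = numeric())
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else NULL
  out
}

#' eGFP/RFP reporter signal ratio
#'
#' Background-subtracted eGFP divided by background-subtracted RFP:
#' `(eGFP_head - eGFP_background) / (RFP_head - RFP_background)`. The eGFP
#' mRNA carries microRNA target sites; the RFP mRNA does not and serves as
#' the injection/expression normalizer.
#'
#' @param egfp_head,egfp_background,rfp_head,rfp_background mean
#'   fluorescence values (arbitrary units).
#' @return Real-valued ratio; negative if eGFP is below its background.
#' @export
sensor_ratio <- function(egfp_head, egfp_background, rfp_head,
                         rfp_background) {
  den <- rfp_head - rfp_background
  if (!is.finite(den) || den <= 0)
    stop("sensor_ratio: RFP head signal must exceed RFP background")
  (egfp_head - egfp_background) / den
}
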