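## Reporter, cytometry, staining, image and qPCR quantification rules:
## nuclear/cytosolic 2-fold scoring over 20 intestinal cells, TOF-normalized
## flow fluorescence, oil red O inverse-brightness density, micrograph
## black-threshold fractions, delta-delta-Ct, and absorption impairment.

#' Score nuclear localization per animal
#'
#' A cell is scored nuclear-positive when its nuclear fluorescence exceeds
#' the proximal cytosolic signal by at least `fold` ("at least 2-fold" is
#' read as >=). The per-animal percentage divides the positive count by the
#' fixed denominator of 20 intestinal cells, so it is always a multiple of
#' 5. Cells with zero cytosolic intensity are unscorable: they are excluded
#' from the numerator and counted, but the denominator stays 20.
#'
#' @param cells a [CellTable-class].
#' @param fold nuclear/cytosolic ratio threshold; default 2.
#' @return data.frame with columns `animal_id`, `positive_nuclei`,
#'   `unscorable_cells`, `percent_nuclear`.
#' @export
scoreNuclear <- function(cells, fold = 2.0) {
  stopifnot(is(cells, "CellTable"))
  d <- cellData(cells)
  unscorable <- d$cytosol_intensity == 0
  positive <- !unscorable & d$nucleus_intensity / d$cytosol_intensity >= fold
  animals <- unique(d$animal_id)
  af <- factor(d$animal_id, levels = animals)
  pos <- as.integer(tapply(positive, af, sum, default = 0L))
  uns <- as.integer(tapply(unscorable, af, sum, default = 0L))
  data.frame(
    animal_id = animals,
    positive_nuclei = pos,
    unscorable_cells = uns,
    percent_nuclear = 100 * pos / 20,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' TOF-normalized relative fluorescence
#'
#' Normalizes each event's integral fluorescence by its time-of-flight
#' (size proxy), averages the normalized values per group, and standardizes
#' relative to the control group: the control's own relative value is 1 by
#' construction. Normalization is per-event ratio followed by the group
#' mean.
#'
#' @param events sample [EventTable-class].
#' @param control control [EventTable-class]; must be non-empty.
#' @return data.frame with one row per group and columns `group_label`,
#'   `n_events`, `value` (mean TOF-normalized fluorescence),
#'   `relative_to_control`.
#' @export
tofNormalize <- function(events, control) {
  stopifnot(is(events, "EventTable"), is(control, "EventTable"))
  if (nrow(flowEvents(control)) == 0L) stop("control group has no events")
  groupValue <- function(tab) {
    d <- flowEvents(tab)
    mean(d$fluor_integral / d$tof)
  }
  ctrl_val <- groupValue(control)
  smp_val <- groupValue(events)
  out <- data.frame(
    group_label = c(groupLabel(control), groupLabel(events)),
    n_events = c(nrow(flowEvents(control)), nrow(flowEvents(events))),
    value = c(ctrl_val, smp_val),
    relative_to_control = c(1.0, smp_val / ctrl_val),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "normalization") <- "per-event fluor/TOF ratio, then group mean"
  out
}

#' Oil red O relative staining density
#'
#' Brightness is inversely related to staining density (brighter signal =
#' less stain). Each measurement's density is the inverse of its brightness
#' divided by the control summary: by default the mean of the control
#' inverse-brightness values (`control_stat = "mean-of-inverse"`), so the
#' control group's own mean relative density is exactly 1; alternatively
#' the inverse of the mean control brightness
#' (`control_stat = "inverse-of-mean"`).
#'
#' @param sample_brightness,control_brightness positive brightness values.
#' @param control_stat how the control denominator is formed (see above).
#' @return data.frame with columns `group_label`, `brightness`,
#'   `relative_density`, one row per measurement (control rows included).
#' @export
oroDensity <- function(sample_brightness, control_brightness,
                       control_stat = c("mean-of-inverse",
                                        "inverse-of-mean")) {
  control_stat <- match.arg(control_stat)
  s <- as.numeric(sample_brightness)
  ctl <- as.numeric(control_brightness)
  if (length(ctl) == 0L) stop("control brightness values required")
  if (any(is.na(c(s, ctl))) || any(c(s, ctl) <= 0)) {
    stop("brightness values must be positive")
  }
  denom <- switch(control_stat,
    "mean-of-inverse" = mean(1 / ctl),
    "inverse-of-mean" = 1 / mean(ctl))
  data.frame(
    group_label = rep(c("control", "sample"), c(length(ctl), length(s))),
    brightness = c(ctl, s),
    relative_density = (1 / c(ctl, s)) / denom,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Black-threshold fraction of an inverted micrograph
#'
#' Inverts an 8-bit grayscale image (v -> 255 - v), binarizes the inverted
#' image at a global threshold (inverted >= threshold is black), and
#' returns the black-pixel fraction. Dark structures (e.g. lipid droplets)
#' on a bright background therefore count as black. The original
#' "maximum black saturation" conversion is a software setting, modeled
#' here as a plain global threshold with a configurable level.
#'
#' @param image integer/numeric matrix with values in \[0, 255\].
#' @param threshold integer in \[0, 255\]; default 128.
#' @return black-pixel fraction in \[0, 1\].
#' @seealso [temRelativeDensity()] for the control-normalized form.
#' @export
temBlackFraction <- function(image, threshold = 128L) {
  .assertGrayImage(image)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 255) {
    stop("threshold must lie in [0, 255]")
  }
  inverted <- 255 - image
  mean(inverted >= threshold)
}

#' Relative lipid density from black-threshold fractions
#'
#' Computes [temBlackFraction()] for each sample and control image and
#' normalizes the sample fractions to the mean control fraction.
#'
#' @param sample_images,control_images lists of grayscale matrices.
#' @param threshold passed to [temBlackFraction()].
#' @return data.frame with columns `group_label`, `black_fraction`,
#'   `relative_density`.
#' @export
temRelativeDensity <- function(sample_images, control_images,
                               threshold = 128L) {
  if (length(control_images) == 0L) stop("control images required")
  cf <- vapply(control_images, temBlackFraction, numeric(1),
               threshold = threshold)
  sf <- vapply(sample_images, temBlackFraction, numeric(1),
               threshold = threshold)
  if (mean(cf) == 0) stop("control images contain no black pixels")
  data.frame(
    group_label = rep(c("control", "sample"), c(length(cf), length(sf))),
    black_fraction = c(cf, sf),
    relative_density = c(cf, sf) / mean(cf),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Relative transcript abundance by delta-delta-Ct
#'
#' Technical replicates are averaged first. Each target gene's Ct is
#' normalized per sample against the housekeeping genes: geometric-mean
#' normalization on the linear scale is realized exactly as the arithmetic
#' mean of the housekeeping Cts (identical on the log2 scale), giving
#' delta-Ct = Ct(target) - mean Ct(housekeeping). delta-delta-Ct subtracts
#' the control sample's delta-Ct and relative abundance is
#' 2^(-delta-delta-Ct).
#'
#' @param ct a [CtTable-class].
#' @param control_label the sample serving as the reference.
#' @return data.frame with columns `sample_label`, `gene_id`, `delta_ct`,
#'   `delta_delta_ct`, `rel_abundance`, one row per (sample, target gene).
#' @export
deltaDeltaCt <- function(ct, control_label) {
  stopifnot(is(ct, "CtTable"))
  d <- ctData(ct)
  hk <- housekeepingIds(ct)
  if (!control_label %in% d$sample_label) {
    stop(sprintf("control sample '%s' not found", control_label))
  }
  ## replicate-averaged Ct per (sample, gene)
  key <- paste(d$sample_label, d$gene_id, sep = "\r")
  avg <- tapply(d$ct, key, mean)
  meta <- d[!duplicated(key), c("sample_label", "gene_id")]
  meta$ct <- as.numeric(avg[paste(meta$sample_label, meta$gene_id,
                                  sep = "\r")])
  samples <- unique(meta$sample_label)
  hk_mean <- vapply(samples, function(smp) {
    rows <- meta$sample_label == smp & meta$gene_id %in% hk
    if (sum(rows) < length(hk)) {
      stop(sprintf("sample '%s' lacks housekeeping measurements", smp))
    }
    mean(meta$ct[rows])
  }, numeric(1))
  targets <- meta[!meta$gene_id %in% hk, , drop = FALSE]
  targets$delta_ct <- targets$ct - hk_mean[targets$sample_label]
  ctrl <- targets[targets$sample_label == control_label, , drop = FALSE]
  ctrl_dct <- stats::setNames(ctrl$delta_ct, ctrl$gene_id)
  targets$delta_delta_ct <- targets$delta_ct -
    as.numeric(ctrl_dct[targets$gene_id])
  targets$rel_abundance <- 2^(-targets$delta_delta_ct)
  out <- targets[, c("sample_label", "gene_id", "delta_ct",
                     "delta_delta_ct", "rel_abundance")]
  row.names(out) <- NULL
  out
}

#' Percent of animals with impaired absorption
#'
#' Absorption is considered impaired when the absorbed fraction is strictly
#' less than the cutoff ("less than 50%" read as strict <).
#'
#' @param per_animal_fraction_absorbed fractions in \[0, 1\], one per
#'   animal; must be non-empty.
#' @param cutoff impairment cutoff; default 0.5.
#' @return percent of animals impaired, in \[0, 100\].
#' @export
absorptionImpairment <- function(per_animal_fraction_absorbed,
                                 cutoff = 0.5) {
  f <- as.numeric(per_animal_fraction_absorbed)
  if (length(f) == 0L) stop("no animals scored")
  if (any(is.na(f)) || any(f < 0 | f > 1)) {
    stop("absorbed fractions must lie in [0, 1]")
  }
  100 * mean(f < cutoff)
}
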