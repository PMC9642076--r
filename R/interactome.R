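## Bait-normalized relative-binding analysis for co-IP interactomes.
## The treatment condition is rescaled so the bait's mean spectral index
## matches its control level; relative binding (RB) is then the
## treatment/control ratio of per-protein mean spectral indices, with a
## PSM >= 2 detection filter flagged alongside.

## Per-replicate total spectral index (summed over fractions) for one
## protein in one condition, as a named vector over the condition's
## replicate set; replicates without a record count as 0.
.baitConditionMean <- function(rec, bait, cond) {
  sub <- rec[rec$condition == cond, , drop = FALSE]
  reps <- unique(sub$replicate)
  bsub <- sub[sub$protein_id == bait, , drop = FALSE]
  tot <- tapply(bsub$spectral_index, factor(bsub$replicate, levels = reps),
                sum, default = 0)
  mean(as.numeric(tot))
}

#' Bait-normalize a quantification table
#'
#' Rescales every treatment-condition spectral index by the factor
#' (mean bait spectral index in control) / (mean bait spectral index in
#' treatment), leaving control records untouched so control-relative
#' quantities keep their raw scale. After normalization the bait's mean
#' adjusted treatment spectral index equals its control mean, so the bait's
#' relative binding is exactly 1.
#'
#' @param quant a [QuantTable-class]; the bait must have a positive mean
#'   spectral index in every condition.
#' @return The rescaled [QuantTable-class] with the bait-normalized flag
#'   set.
#' @export
baitNormalize <- function(quant) {
  stopifnot(is(quant, "QuantTable"))
  if (isBaitNormalized(quant)) return(quant)
  labs <- conditionLabels(quant)
  rec <- quantRecords(quant)
  bait_means <- vapply(labs, function(cond)
    .baitConditionMean(rec, baitId(quant), cond), numeric(1))
  if (any(is.na(bait_means)) || any(bait_means <= 0)) {
    stop(sprintf("bait '%s' has zero mean spectral index in condition '%s'",
                 baitId(quant), labs[which(bait_means <= 0)[1L]]))
  }
  scale <- bait_means[[1L]] / bait_means[[2L]]
  trt <- rec$condition == labs[2L]
  rec$spectral_index[trt] <- rec$spectral_index[trt] * scale
  quant@records <- rec
  quant@baitNormalized <- TRUE
  validObject(quant)
  quant
}

#' Relative-binding table with PSM detection filter
#'
#' For each protein, takes the mean spectral index across replicates within
#' each condition (after [baitNormalize()], applied automatically if the
#' table is not yet normalized) and reports relative binding
#' RB = mean treatment (bait-adjusted) / mean control. Within a condition,
#' replicates without a record contribute 0 to the mean over the
#' condition's full replicate set. Proteins with a control mean of 0 get
#' `NA` relative binding and the flag `"treatment-only"` rather than an
#' infinite ratio. Proteins failing the PSM filter (maximum PSM count over
#' all runs below `psm_threshold`) are retained but flagged.
#'
#' @param quant a [QuantTable-class].
#' @param psm_threshold minimum peptide-spectrum-match count for a protein
#'   to be considered confidently detected; default 2.
#' @return data.frame with columns `protein_id`, `mean_si_control`,
#'   `mean_si_treatment_adj`, `relative_binding`, `max_psm`,
#'   `passes_psm_filter`, `flag`.
#' @export
relativeBindingTable <- function(quant, psm_threshold = 2L) {
  stopifnot(is(quant, "QuantTable"))
  quant <- baitNormalize(quant)
  labs <- conditionLabels(quant)
  rec <- quantRecords(quant)
  proteins <- sort(unique(rec$protein_id), method = "radix")
  condMeans <- function(cond) {
    sub <- rec[rec$condition == cond, , drop = FALSE]
    reps <- unique(sub$replicate)
    tot <- tapply(sub$spectral_index,
                  list(factor(sub$protein_id, levels = proteins),
                       factor(sub$replicate, levels = reps)),
                  sum, default = 0)
    ## absent (protein, replicate) cells are 0, not NA; a protein with no
    ## records in the condition therefore has mean 0
    tot[is.na(tot)] <- 0
    rowMeans(tot)
  }
  mean_c <- condMeans(labs[1L])
  mean_t <- condMeans(labs[2L])
  max_psm <- tapply(rec$psm_count, factor(rec$protein_id, levels = proteins),
                    max, default = 0L)
  rb <- ifelse(mean_c > 0, mean_t / mean_c, NA_real_)
  flag <- ifelse(mean_c > 0,
                 ifelse(mean_t > 0, "ok", "control-only"),
                 "treatment-only")
  data.frame(
    protein_id = proteins,
    mean_si_control = as.numeric(mean_c),
    mean_si_treatment_adj = as.numeric(mean_t),
    relative_binding = as.numeric(rb),
    max_psm = as.integer(max_psm),
    passes_psm_filter = as.integer(max_psm) >= psm_threshold,
    flag = flag,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Restrict binding results to a functional category
#'
#' Filters a relative-binding table to the proteins in a given identifier
#' set (e.g. a KEGG endocytosis category), preserving row order. Identifier
#' matching is case-sensitive and exact.
#'
#' @param results output of [relativeBindingTable()].
#' @param category character vector of protein identifiers.
#' @return The filtered data.frame; empty (with a warning) when the
#'   category does not intersect the results.
#' @export
subsetByCategory <- function(results, category) {
  stopifnot(is.data.frame(results), "protein_id" %in% names(results))
  out <- results[results$protein_id %in% category, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("category does not intersect the result identifiers")
  }
  out
}
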