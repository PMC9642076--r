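## Solubility-shift indexing: per-protein solubility ratios (SR) in each
## condition, the destabilization index DI = SR(control) - SR(treatment),
## and the top-fraction ranking that feeds over-representation analysis.

#' Solubility ratio
#'
#' SR = soluble / (soluble + insoluble), the fraction of a protein's
#' spectral index found in the soluble fraction; lies in \[0, 1\].
#' Both inputs are replicate-aggregated spectral indices. When both are 0
#' the ratio is undefined and `NA` is returned with a warning; `NA` inputs
#' propagate to `NA`.
#'
#' @param soluble_si,insoluble_si non-negative spectral indices (vectorized,
#'   recycled to common length).
#' @return numeric vector of ratios in \[0, 1\], `NA` where undefined.
#' @examples
#' solubilityRatio(3, 1)  # 0.75
#' solubilityRatio(0, 5)  # 0: fully insoluble
#' @export
solubilityRatio <- function(soluble_si, insoluble_si) {
  n <- max(length(soluble_si), length(insoluble_si))
  s <- rep_len(as.numeric(soluble_si), n)
  i <- rep_len(as.numeric(insoluble_si), n)
  if (any(s < 0, na.rm = TRUE) || any(i < 0, na.rm = TRUE)) {
    stop("spectral indices must be non-negative")
  }
  tot <- s + i
  undef <- !is.na(tot) & tot == 0
  if (any(undef)) {
    warning(sprintf(
      "solubility ratio undefined (0/0) for %d value(s); returning NA",
      sum(undef)))
  }
  out <- s / tot
  out[undef] <- NA_real_
  out
}

#' Destabilization index
#'
#' DI = SR(control) - SR(treatment), in \[-1, 1\]. A value of 1 represents a
#' complete shift from the soluble fraction under control conditions to the
#' insoluble fraction under treatment; -1 is the symmetric resolubilization
#' extreme; 0 means no change in solubility.
#'
#' @param sr_control,sr_treatment solubility ratios in \[0, 1\] (vectorized).
#'   `NA` propagates.
#' @return numeric vector in \[-1, 1\].
#' @examples
#' destabilizationIndex(1, 0)    # complete soluble -> insoluble shift
#' destabilizationIndex(0.5, 0.5)  # no shift
#' @export
destabilizationIndex <- function(sr_control, sr_treatment) {
  bad <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (bad(sr_control) || bad(sr_treatment)) {
    stop("solubility ratios must lie in [0, 1]")
  }
  as.numeric(sr_control) - as.numeric(sr_treatment)
}

## Per-condition SR for every protein detected in that condition.
## Within a condition a protein's missing (fraction, replicate) records are
## taken as measured 0 over the condition's full replicate set; a protein
## with no records at all in the condition gets NA.
.srForCondition <- function(rec, cond, aggregate) {
  sub <- rec[rec$condition == cond, , drop = FALSE]
  reps <- unique(sub$replicate)
  prot <- unique(sub$protein_id)
  pf <- factor(sub$protein_id, levels = prot)
  if (aggregate == "mean-then-ratio") {
    sol <- tapply(sub$spectral_index * (sub$fraction == "soluble"),
                  pf, sum) / length(reps)
    ins <- tapply(sub$spectral_index * (sub$fraction == "insoluble"),
                  pf, sum) / length(reps)
    sr <- suppressWarnings(solubilityRatio(sol, ins))
  } else {
    rf <- factor(sub$replicate, levels = reps)
    sol <- tapply(sub$spectral_index * (sub$fraction == "soluble"),
                  list(pf, rf), sum, default = 0)
    ins <- tapply(sub$spectral_index * (sub$fraction == "insoluble"),
                  list(pf, rf), sum, default = 0)
    srm <- suppressWarnings(solubilityRatio(sol, ins))
    dim(srm) <- dim(sol)
    sr <- rowMeans(srm, na.rm = TRUE)
    sr[is.nan(sr)] <- NA_real_
  }
  stats::setNames(as.numeric(sr), prot)
}

#' Solubility-shift index table
#'
#' Computes, for every protein in a two-fraction quantification table, the
#' solubility ratio under each condition, the destabilization index
#' DI = SR(control) - SR(treatment), a descending-DI rank, and a flag for
#' membership in the top fraction of the DI ranking.
#'
#' Replicates are aggregated by mean spectral index per (protein, condition,
#' fraction) before ratioing (`aggregate = "mean-then-ratio"`, the default);
#' `"ratio-then-mean"` instead computes a per-replicate ratio and averages
#' the defined ratios. Proteins absent from a condition (no records at all)
#' have `NA` SR there, hence `NA` DI, and are excluded from ranking; the
#' "top fraction" denominator is the set of proteins with a defined DI, not
#' the full detected proteome. Ties are broken by `protein_id` (C-locale
#' lexicographic), so ranking is deterministic.
#'
#' @param quant a two-fraction [QuantTable-class] with both conditions
#'   present.
#' @param fraction top fraction of the DI ranking to flag, in (0, 1\];
#'   default 0.10 (the top decile).
#' @param aggregate replicate-aggregation strategy (see Details).
#' @return data.frame with columns `protein_id`, `sr_control`,
#'   `sr_treatment`, `destab_index`, `rank`, `in_top_fraction`, sorted by
#'   rank (NA-DI proteins last, alphabetically).
#' @seealso [topFraction()], [solubilityRatio()], [destabilizationIndex()]
#' @export
solubilityIndexTable <- function(quant, fraction = 0.10,
                                 aggregate = c("mean-then-ratio",
                                               "ratio-then-mean")) {
  stopifnot(is(quant, "QuantTable"))
  aggregate <- match.arg(aggregate)
  if (fractionMode(quant) != "two-fraction") {
    stop("solubility indexing requires a two-fraction table")
  }
  labs <- conditionLabels(quant)
  rec <- quantRecords(quant)
  absent <- setdiff(labs, unique(rec$condition))
  if (length(absent) > 0L) {
    stop(sprintf("condition '%s' has no records", absent[1L]))
  }
  proteins <- sort(unique(rec$protein_id), method = "radix")
  sr_c <- .srForCondition(rec, labs[1L], aggregate)
  sr_t <- .srForCondition(rec, labs[2L], aggregate)
  res <- data.frame(
    protein_id = proteins,
    sr_control = as.numeric(sr_c[proteins]),
    sr_treatment = as.numeric(sr_t[proteins]),
    stringsAsFactors = FALSE
  )
  res$destab_index <- ifelse(
    is.na(res$sr_control) | is.na(res$sr_treatment), NA_real_,
    destabilizationIndex(ifelse(is.na(res$sr_control), 0, res$sr_control),
                         ifelse(is.na(res$sr_treatment), 0,
                                res$sr_treatment)))
  defined <- !is.na(res$destab_index)
  res$rank <- NA_integer_
  if (any(defined)) {
    ord <- order(-res$destab_index[defined],
                 res$protein_id[defined], method = "radix")
    res$rank[defined][ord] <- seq_len(sum(defined))
  }
  k <- sum(defined)
  m <- if (k > 0L) as.integer(ceiling(fraction * k)) else 0L
  res$in_top_fraction <- !is.na(res$rank) & res$rank <= m
  res <- res[order(is.na(res$rank), res$rank, res$protein_id,
                   method = "radix"), , drop = FALSE]
  ## analysis provenance, serialized nowhere but inspectable
  attr(res, "top_fraction") <- fraction
  attr(res, "top_fraction_denominator") <- "defined-DI"
  attr(res, "aggregate") <- aggregate
  res
}

#' Top fraction of the destabilization ranking
#'
#' Returns the `ceiling(fraction * k)` proteins with the highest
#' destabilization indices among the `k` proteins with a defined DI. Ties at
#' the cutoff are broken by `protein_id` (C-locale lexicographic order), so
#' the selection is deterministic.
#'
#' @param results output of [solubilityIndexTable()] (needs columns
#'   `protein_id`, `destab_index`).
#' @param fraction fraction in (0, 1\]; default 0.10.
#' @return character vector of selected protein identifiers, in rank order.
#' @export
topFraction <- function(results, fraction = 0.10) {
  stopifnot(is.data.frame(results),
            all(c("protein_id", "destab_index") %in% names(results)))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  defined <- results[!is.na(results$destab_index), , drop = FALSE]
  k <- nrow(defined)
  if (k == 0L) stop("no protein has a defined destabilization index")
  m <- as.integer(ceiling(fraction * k))
  ord <- order(-defined$destab_index, defined$protein_id, method = "radix")
  defined$protein_id[ord][seq_len(m)]
}
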