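## Threshold-based significance calls on differential-expression tables,
## two-set overlap counts, and the cross-dataset classification of one
## dataset's significant genes as unchanged / inverse / concordant in a
## second dataset.

#' Significant genes by fold-change and p-value thresholds
#'
#' A gene is called significant when |log2FC| is strictly greater than
#' `lfc_min` and its p-value strictly less than `p_max` (the conventional
#' "log2 fold change > +/- 0.5 and p < 0.05" reading, applied with strict
#' inequalities). Rows with missing log2FC or p-value are never called.
#'
#' @param table a [DETable-class].
#' @param lfc_min absolute log2 fold-change threshold (exclusive);
#'   default 0.5.
#' @param p_max p-value threshold (exclusive); default 0.05.
#' @return data.frame with columns `gene_id`, `log2fc`, `sign`
#'   (+1 up, -1 down), one row per significant gene.
#' @export
callSignificant <- function(table, lfc_min = 0.5, p_max = 0.05) {
  stopifnot(is(table, "DETable"))
  d <- deData(table)
  sig <- !is.na(d$log2fc) & !is.na(d$p_value) &
    abs(d$log2fc) > lfc_min & d$p_value < p_max
  out <- d[sig, c("gene_id", "log2fc"), drop = FALSE]
  out$sign <- sign(out$log2fc)
  row.names(out) <- NULL
  out
}

#' Two-set overlap partition
#'
#' Counts the Venn partition of two identifier sets.
#'
#' @param set_a,set_b character vectors (duplicates ignored).
#' @return named integer vector `c(only_a, shared, only_b)`.
#' @export
overlapCounts <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  shared <- sum(a %in% b)
  c(only_a = length(a) - shared, shared = shared,
    only_b = length(b) - shared)
}

#' Cross-dataset classification of significant genes
#'
#' For every gene significant in dataset A, looks the gene up in dataset B
#' and classifies it as:
#' \itemize{
#'   \item `absent_in_B` — not measured in B;
#'   \item `unchanged` — measured in B but not significant there;
#'   \item `inverse` — significant in B with the opposite log2FC sign;
#'   \item `concordant` — significant in B with the same sign.
#' }
#' Significance in B uses the same thresholds as A by default; with
#' `b_p_only = TRUE` only the p-value threshold is applied in B (the looser
#' cross-comparison reading). The summary reports the percentage of each
#' class among A's significant genes, rounded to whole percent.
#'
#' @param sig_a output of [callSignificant()] on dataset A (columns
#'   `gene_id`, `log2fc`, `sign`); must be non-empty.
#' @param table_b a [DETable-class] for dataset B.
#' @param lfc_min,p_max thresholds applied in B; defaults 0.5 and 0.05.
#' @param b_p_only apply only the p-value threshold in B.
#' @return list with `records` (data.frame `gene_id`, `sig_A`, `lfc_A`,
#'   `sig_B`, `lfc_B`, `cls`) and `summary` (named numeric of whole-percent
#'   shares: `unchanged`, `inverse`, `concordant`, `absent_in_B`).
#' @export
crossClassify <- function(sig_a, table_b, lfc_min = 0.5, p_max = 0.05,
                          b_p_only = FALSE) {
  stopifnot(is.data.frame(sig_a),
            all(c("gene_id", "log2fc", "sign") %in% names(sig_a)),
            is(table_b, "DETable"))
  if (nrow(sig_a) == 0L) stop("no significant genes in dataset A")
  b <- deData(table_b)
  idx <- match(sig_a$gene_id, b$gene_id)
  lfc_b <- b$log2fc[idx]
  p_b <- b$p_value[idx]
  sig_b <- !is.na(lfc_b) & !is.na(p_b) & p_b < p_max &
    (b_p_only | abs(lfc_b) > lfc_min)
  cls <- ifelse(is.na(idx), "absent_in_B",
         ifelse(!sig_b, "unchanged",
         ifelse(sign(lfc_b) == -sig_a$sign, "inverse", "concordant")))
  records <- data.frame(
    gene_id = sig_a$gene_id,
    sig_A = TRUE,
    lfc_A = sig_a$log2fc,
    sig_B = ifelse(is.na(idx), NA, sig_b),
    lfc_B = lfc_b,
    cls = cls,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  classes <- c("unchanged", "inverse", "concordant", "absent_in_B")
  counts <- vapply(classes, function(cl) sum(cls == cl), integer(1))
  summary <- round(100 * counts / nrow(records))
  list(records = records, summary = summary)
}
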