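# In-code fixture builders shared across the suite.

# One long-format spectral record per (fraction) with shared metadata.
qrow <- function(pid, cond, frac, rep, si, psm = 5L) {
  data.frame(protein_id = pid, condition = cond, fraction = frac,
             replicate = rep, spectral_index = si, psm_count = psm,
             stringsAsFactors = FALSE)
}

# Two-fraction record block for one protein/condition/replicate.
qblock <- function(pid, cond, rep, sol, ins, psm = 5L) {
  rbind(qrow(pid, cond, "soluble", rep, sol, psm),
        qrow(pid, cond, "insoluble", rep, ins, psm))
}

# Whole-lysate records for one protein: one row per replicate per
# condition, spectral indices given as per-replicate vectors.
qblockWhole <- function(pid, ctrl_si, trt_si, psm = 5L) {
  rbind(
    do.call(rbind, lapply(seq_along(ctrl_si), function(r)
      qrow(pid, "control", "whole", r, ctrl_si[r], psm))),
    do.call(rbind, lapply(seq_along(trt_si), function(r)
      qrow(pid, "treatment", "whole", r, trt_si[r], psm))))
}

# Minimal valid two-condition two-fraction table with a neutral bait
# (equal spectral index everywhere) plus user-supplied protein blocks.
quantWithBait <- function(..., bait_si = 50, bait_reps = 1L,
                          conds = c("control", "treatment")) {
  blocks <- list(...)
  bait <- do.call(rbind, lapply(conds, function(cond)
    do.call(rbind, lapply(seq_len(bait_reps), function(r)
      qblock("BAIT", cond, r, bait_si, bait_si)))))
  QuantTable(rbind(bait, do.call(rbind, blocks)), bait_id = "BAIT",
             condition_labels = conds)
}

# Random two-fraction table: n_prot proteins x 2 conditions x n_rep
# replicates with integer spectral indices, bait included and positive.
randomQuant <- function(n_prot = 3L, n_rep = 2L, max_si = 30L) {
  ids <- sprintf("R%02d", seq_len(n_prot))
  rows <- list()
  for (pid in ids) {
    for (cond in c("control", "treatment")) {
      for (r in seq_len(n_rep)) {
        rows[[length(rows) + 1L]] <- qblock(
          pid, cond, r,
          sample.int(max_si + 1L, 1L) - 1L,
          sample.int(max_si + 1L, 1L) - 1L,
          psm = sample.int(6L, 1L) - 1L)
      }
    }
  }
  for (cond in c("control", "treatment")) {
    for (r in seq_len(n_rep)) {
      rows[[length(rows) + 1L]] <- qblock(
        "BAIT", cond, r, sample.int(max_si, 1L), sample.int(max_si, 1L))
    }
  }
  QuantTable(do.call(rbind, rows), bait_id = "BAIT",
             condition_labels = c("control", "treatment"))
}

# Same records, condition roles exchanged (treatment read as control).
swapConditions <- function(qt) {
  QuantTable(quantRecords(qt), bait_id = baitId(qt),
             condition_labels = rev(conditionLabels(qt)),
             fraction_mode = fractionMode(qt))
}

# Multiply every spectral index in one condition by a constant.
scaleCondition <- function(qt, cond, factor) {
  rec <- quantRecords(qt)
  rec$spectral_index[rec$condition == cond] <-
    rec$spectral_index[rec$condition == cond] * factor
  QuantTable(rec, bait_id = baitId(qt),
             condition_labels = conditionLabels(qt),
             fraction_mode = fractionMode(qt))
}

# Brute-force hypergeometric upper tail by enumerating all draws of n
# from a universe of N whose first K elements are annotated.
enumUpperTail <- function(N, K, n, x) {
  if (n == 0L) return(as.numeric(x == 0L))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= x)
}
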