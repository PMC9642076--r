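## Seeded generators emulating every input the pipeline consumes, each
## returning the generated object(s) plus a ground-truth record (generator
## name, seed, parameters, planted identifier sets, analytically expected
## values where known). Every generator is a pure function of its
## parameters and seed, and leaves the caller's RNG state untouched.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.truthRecord <- function(generator, seed, parameters, planted = list(),
                         expected = list()) {
  list(generator = generator, seed = as.integer(seed),
       parameters = parameters, planted = planted, expected = expected)
}

#' Simulate a two-condition, two-fraction co-IP quantification table
#'
#' Emulates a fractionated co-IP spectral-counting experiment. Each
#' protein's total abundance is drawn log-normally around `mean_depth` and
#' split between soluble and insoluble fractions by a solubility ratio:
#' `sr_base` for every protein under control and for background proteins
#' under treatment, `sr_shifted` for the planted destabilized proteins
#' under treatment. Observed spectral indices are negative-binomial around
#' the fraction means (variance mu + dispersion * mu^2), the counts-like
#' overdispersed model standard for spectral counting. PSM counts are
#' Poisson with mean proportional to the observed abundance. The bait is
#' generated with condition-specific abundance so that bait normalization
#' is exercised.
#'
#' @param n_proteins number of interactor proteins.
#' @param n_planted number of planted destabilized proteins
#'   (`<= n_proteins`).
#' @param sr_base,sr_shifted solubility ratios in (0, 1) for background and
#'   planted-treatment proteins.
#' @param mean_depth median total spectral index per protein.
#' @param dispersion negative-binomial dispersion (0 = Poisson limit).
#' @param n_replicates biological replicates per condition.
#' @param seed RNG seed; fully determines the output.
#' @param bait_id bait identifier.
#' @return list with `quant` (a [QuantTable-class]) and `truth` (the
#'   ground-truth record; `truth$planted$destabilized` holds the planted
#'   protein ids and `truth$expected$mean_di` the large-sample expected
#'   destabilization index `sr_base - sr_shifted` for planted proteins).
#' @export
simCoip <- function(n_proteins = 200L, n_planted = 20L, sr_base = 0.9,
                    sr_shifted = 0.1, mean_depth = 100, dispersion = 0.1,
                    n_replicates = 2L, seed = 1L, bait_id = "BAIT") {
  if (n_planted > n_proteins) stop("n_planted must not exceed n_proteins")
  if (sr_base <= 0 || sr_base >= 1 || sr_shifted <= 0 || sr_shifted >= 1) {
    stop("solubility ratios must lie in (0, 1)")
  }
  if (mean_depth <= 0 || dispersion < 0) {
    stop("mean_depth must be positive and dispersion non-negative")
  }
  .withSeed(seed, {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    planted <- sort(sample(ids, n_planted))
    abundance <- stats::rlnorm(n_proteins, meanlog = log(mean_depth),
                               sdlog = 1)
    names(abundance) <- ids
    conds <- c("control", "treatment")
    draw <- function(mu, n) {
      if (dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
    }
    rows <- vector("list", 0L)
    for (cond in conds) {
      sr <- rep(sr_base, n_proteins)
      if (cond == "treatment") sr[ids %in% planted] <- sr_shifted
      for (rep_i in seq_len(n_replicates)) {
        mu_sol <- abundance * sr
        mu_ins <- abundance * (1 - sr)
        si_sol <- draw(mu_sol, n_proteins)
        si_ins <- draw(mu_ins, n_proteins)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = rep(ids, 2L),
          condition = cond,
          fraction = rep(c("soluble", "insoluble"), each = n_proteins),
          replicate = rep_i,
          spectral_index = c(si_sol, si_ins),
          psm_count = stats::rpois(2L * n_proteins,
                                   c(si_sol, si_ins) / 10),
          stringsAsFactors = FALSE)
        ## bait: abundant, condition-specific level, background solubility
        bait_ab <- mean_depth * if (cond == "control") 20 else 12
        b_sol <- draw(bait_ab * sr_base, 1L)
        b_ins <- draw(bait_ab * (1 - sr_base), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = bait_id,
          condition = cond,
          fraction = c("soluble", "insoluble"),
          replicate = rep_i,
          spectral_index = c(b_sol, b_ins),
          psm_count = stats::rpois(2L, c(b_sol, b_ins) / 10),
          stringsAsFactors = FALSE)
      }
    }
    quant <- QuantTable(do.call(rbind, rows), bait_id = bait_id,
                        condition_labels = conds,
                        fraction_mode = "two-fraction")
    truth <- .truthRecord(
      "coip", seed,
      parameters = list(n_proteins = n_proteins, n_planted = n_planted,
                        sr_base = sr_base, sr_shifted = sr_shifted,
                        mean_depth = mean_depth, dispersion = dispersion,
                        n_replicates = n_replicates, bait_id = bait_id),
      planted = list(destabilized = planted),
      expected = list(mean_di = sr_base - sr_shifted))
    list(quant = quant, truth = truth)
  })
}

#' Simulate a pair of differential-expression tables with a planted
#' cross-dataset composition
#'
#' Dataset A contains exactly `n_sig_A` genes passing the standard
#' (|log2FC| > 0.5, p < 0.05) thresholds by construction. Among those
#' genes, dataset B realizes the requested composition: a fraction
#' `frac_inverse` significant with the opposite sign, `frac_unchanged` not
#' significant in B, and the remainder significant with the same sign
#' (counts are rounded to whole genes). Non-significant genes carry
#' sub-threshold fold changes, so the planted classes are recovered exactly
#' by thresholding under either the symmetric or the p-only reading.
#'
#' @param n_genes genes per table.
#' @param n_sig_A number of genes significant in A.
#' @param frac_inverse,frac_unchanged planted class fractions among A's
#'   significant genes (`frac_inverse + frac_unchanged <= 1`).
#' @param effect_size typical |log2FC| of significant genes.
#' @param seed RNG seed.
#' @return list with `table_a`, `table_b` ([DETable-class]) and `truth`
#'   (planted `inverse`, `unchanged`, `concordant` gene sets).
#' @export
simDEPair <- function(n_genes = 500L, n_sig_A = 37L,
                      frac_inverse = 7 / 37, frac_unchanged = 25 / 37,
                      effect_size = 2, seed = 1L) {
  if (frac_inverse < 0 || frac_unchanged < 0 ||
      frac_inverse + frac_unchanged > 1) {
    stop("class fractions must be non-negative and sum to at most 1")
  }
  if (n_sig_A > n_genes) stop("n_sig_A must not exceed n_genes")
  n_inv <- as.integer(round(frac_inverse * n_sig_A))
  n_unch <- as.integer(round(frac_unchanged * n_sig_A))
  n_conc <- n_sig_A - n_inv - n_unch
  if (n_conc < 0L) stop("infeasible class composition after rounding")
  .withSeed(seed, {
    ids <- sprintf("G%05d", seq_len(n_genes))
    sig_ids <- sort(sample(ids, n_sig_A))
    sigMagnitude <- function(n) {
      pmax(0.6, effect_size * stats::runif(n, 0.75, 1.25))
    }
    sigP <- function(n) stats::runif(n, 1e-8, 0.049)
    nullLfc <- function(n) stats::runif(n, -0.45, 0.45)
    ## dataset A
    lfc_a <- nullLfc(n_genes)
    p_a <- stats::runif(n_genes)
    sig_idx <- match(sig_ids, ids)
    sign_a <- sample(c(-1, 1), n_sig_A, replace = TRUE)
    lfc_a[sig_idx] <- sign_a * sigMagnitude(n_sig_A)
    p_a[sig_idx] <- sigP(n_sig_A)
    ## dataset B: assign classes among A's significant genes
    cls <- sample(rep(c("inverse", "unchanged", "concordant"),
                      c(n_inv, n_unch, n_conc)))
    lfc_b <- nullLfc(n_genes)
    p_b <- stats::runif(n_genes)
    for (j in seq_len(n_sig_A)) {
      i <- sig_idx[j]
      if (cls[j] == "inverse") {
        lfc_b[i] <- -sign_a[j] * sigMagnitude(1L)
        p_b[i] <- sigP(1L)
      } else if (cls[j] == "concordant") {
        lfc_b[i] <- sign_a[j] * sigMagnitude(1L)
        p_b[i] <- sigP(1L)
      } else {
        lfc_b[i] <- nullLfc(1L)
        p_b[i] <- stats::runif(1L, 0.1, 0.95)
      }
    }
    table_a <- DETable(data.frame(gene_id = ids, log2fc = lfc_a,
                                  p_value = p_a,
                                  stringsAsFactors = FALSE), "synthetic-A")
    table_b <- DETable(data.frame(gene_id = ids, log2fc = lfc_b,
                                  p_value = p_b,
                                  stringsAsFactors = FALSE), "synthetic-B")
    truth <- .truthRecord(
      "de_pair", seed,
      parameters = list(n_genes = n_genes, n_sig_A = n_sig_A,
                        frac_inverse = frac_inverse,
                        frac_unchanged = frac_unchanged,
                        effect_size = effect_size),
      planted = list(significant_A = sig_ids,
                     inverse = sort(sig_ids[cls == "inverse"]),
                     unchanged = sort(sig_ids[cls == "unchanged"]),
                     concordant = sort(sig_ids[cls == "concordant"])),
      expected = list(n_inverse = n_inv, n_unchanged = n_unch,
                      n_concordant = n_conc))
    list(table_a = table_a, table_b = table_b, truth = truth)
  })
}

#' Simulate per-cell nuclear/cytosolic intensity tables
#'
#' Twenty intestinal cells per animal. Cytosolic intensities are
#' log-normal around 100 with coefficient of variation `noise_cv`; each
#' cell's nuclear intensity is its cytosolic intensity times a log-normal
#' ratio centred at 1 for background cells and at `fold_shift` for the
#' planted fraction of cells in nuclear-shifted animals.
#'
#' @param n_animals number of animals.
#' @param frac_nuclear_animals fraction of animals planted as
#'   nuclear-shifted.
#' @param fold_shift nuclear/cytosolic ratio centre for shifted cells.
#' @param noise_cv coefficient of variation of the intensity noise.
#' @param frac_positive_cells fraction of cells per shifted animal centred
#'   at `fold_shift`.
#' @param seed RNG seed.
#' @return list with `cells` (a [CellTable-class]) and `truth`
#'   (`truth$planted$nuclear_shifted` holds the shifted animal ids).
#' @export
simCells <- function(n_animals = 20L, frac_nuclear_animals = 0.5,
                     fold_shift = 4, noise_cv = 0.2,
                     frac_positive_cells = 0.6, seed = 1L) {
  if (frac_nuclear_animals < 0 || frac_nuclear_animals > 1 ||
      frac_positive_cells < 0 || frac_positive_cells > 1) {
    stop("fractions must lie in [0, 1]")
  }
  .withSeed(seed, {
    animals <- sprintf("A%03d", seq_len(n_animals))
    shifted <- sort(sample(animals, round(frac_nuclear_animals * n_animals)))
    sdlog <- sqrt(log(1 + noise_cv^2))
    n_pos <- round(frac_positive_cells * 20)
    rows <- lapply(animals, function(a) {
      cyt <- stats::rlnorm(20L, meanlog = log(100), sdlog = sdlog)
      centre <- rep(1, 20L)
      if (a %in% shifted && n_pos > 0L) {
        centre[sample.int(20L, n_pos)] <- fold_shift
      }
      ratio <- stats::rlnorm(20L, meanlog = log(centre), sdlog = sdlog)
      data.frame(animal_id = a, cell_id = sprintf("%s_c%02d", a, 1:20),
                 nucleus_intensity = cyt * ratio, cytosol_intensity = cyt,
                 stringsAsFactors = FALSE)
    })
    cells <- CellTable(do.call(rbind, rows))
    truth <- .truthRecord(
      "cells", seed,
      parameters = list(n_animals = n_animals,
                        frac_nuclear_animals = frac_nuclear_animals,
                        fold_shift = fold_shift, noise_cv = noise_cv,
                        frac_positive_cells = frac_positive_cells),
      planted = list(nuclear_shifted = shifted))
    list(cells = cells, truth = truth)
  })
}

#' Simulate large-particle flow-cytometry event tables
#'
#' Event TOF (size proxy) is normal around `size_mean`; integral
#' fluorescence is proportional to size times a per-group expression level,
#' with log-normal measurement noise. Sample and control expression differ
#' by `expression_ratio`, which is therefore the expected TOF-normalized
#' relative fluorescence.
#'
#' @param n_events events per group.
#' @param size_mean,size_sd TOF distribution parameters.
#' @param expression_ratio sample/control expression ratio.
#' @param noise_cv coefficient of variation of fluorescence noise.
#' @param seed RNG seed.
#' @return list with `control`, `sample` ([EventTable-class]) and `truth`
#'   (`truth$expected$relative_fluorescence = expression_ratio`).
#' @export
simFlow <- function(n_events = 500L, size_mean = 300, size_sd = 50,
                    expression_ratio = 2, noise_cv = 0.1, seed = 1L) {
  if (size_mean <= 0 || size_sd < 0 || expression_ratio <= 0) {
    stop("size parameters and expression_ratio must be positive")
  }
  .withSeed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    makeGroup <- function(label, expr_level) {
      tof <- pmax(stats::rnorm(n_events, size_mean, size_sd), 1)
      ## lognormal noise scaled to mean 1 so E[fluor/tof] = expr_level
      noise <- stats::rlnorm(n_events, meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      EventTable(data.frame(
        event_id = sprintf("%s_e%05d", label, seq_len(n_events)),
        tof = tof,
        fluor_integral = tof * expr_level * noise,
        stringsAsFactors = FALSE), group_label = label)
    }
    base_expr <- 5
    control <- makeGroup("control", base_expr)
    sample_t <- makeGroup("sample", base_expr * expression_ratio)
    truth <- .truthRecord(
      "flow", seed,
      parameters = list(n_events = n_events, size_mean = size_mean,
                        size_sd = size_sd,
                        expression_ratio = expression_ratio,
                        noise_cv = noise_cv),
      expected = list(relative_fluorescence = expression_ratio))
    list(control = control, sample = sample_t, truth = truth)
  })
}

#' Simulate a grayscale micrograph with dark discs of known area
#'
#' Places `n_discs` non-overlapping discs of radius `disc_radius` at seeded
#' positions, painted at `fg_intensity` (dark) on a `bg_intensity`
#' background, optionally with Gaussian pixel noise (clipped to 0..255).
#' The ground truth records the exact painted-pixel fraction counted from
#' the rendered geometry, so threshold-based density estimates can be
#' checked against it analytically.
#'
#' @param width,height image dimensions in pixels.
#' @param n_discs number of discs.
#' @param disc_radius disc radius in pixels.
#' @param fg_intensity,bg_intensity disc and background intensities in
#'   \[0, 255\].
#' @param noise_sd Gaussian noise standard deviation (0 for noise-free).
#' @param seed RNG seed.
#' @return list with `image` (integer matrix) and `truth`
#'   (`truth$expected$dark_fraction` is the exact painted fraction).
#' @export
simImage <- function(width = 128L, height = 128L, n_discs = 5L,
                     disc_radius = 10L, fg_intensity = 0L,
                     bg_intensity = 255L, noise_sd = 0, seed = 1L) {
  r <- disc_radius
  if (n_discs > 0L && (2 * r + 2 > width || 2 * r + 2 > height)) {
    stop("disc_radius too large for the image dimensions")
  }
  for (v in c(fg_intensity, bg_intensity)) {
    if (v < 0 || v > 255) stop("intensities must lie in [0, 255]")
  }
  .withSeed(seed, {
    img <- matrix(as.numeric(bg_intensity), nrow = height, ncol = width)
    centers <- matrix(numeric(0), ncol = 2L)
    attempts <- 0L
    while (nrow(centers) < n_discs) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop("could not place non-overlapping discs; reduce n_discs or radius")
      }
      cx <- stats::runif(1, r + 1, width - r)
      cy <- stats::runif(1, r + 1, height - r)
      if (nrow(centers) == 0L ||
          all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >
              (2 * r + 1)^2)) {
        centers <- rbind(centers, c(cx, cy))
      }
    }
    painted <- 0L
    if (n_discs > 0L) {
      col_idx <- matrix(rep(seq_len(width), each = height), nrow = height)
      row_idx <- matrix(rep(seq_len(height), width), nrow = height)
      for (d in seq_len(nrow(centers))) {
        inside <- (col_idx - centers[d, 1])^2 +
          (row_idx - centers[d, 2])^2 <= r^2
        img[inside] <- fg_intensity
      }
      painted <- sum(img == fg_intensity & fg_intensity != bg_intensity)
    }
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sd)
      img <- pmin(pmax(round(img), 0), 255)
    }
    storage.mode(img) <- "integer"
    truth <- .truthRecord(
      "image", seed,
      parameters = list(width = width, height = height, n_discs = n_discs,
                        disc_radius = disc_radius,
                        fg_intensity = fg_intensity,
                        bg_intensity = bg_intensity, noise_sd = noise_sd),
      expected = list(dark_fraction = painted / (width * height),
                      centers = centers))
    list(image = img, truth = truth)
  })
}
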