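test_that("generators are pure functions of parameters and seed", {
  a <- simCoip(n_proteins = 30L, n_planted = 5L, seed = 3L)
  b <- simCoip(n_proteins = 30L, n_planted = 5L, seed = 3L)
  expect_identical(quantRecords(a$quant), quantRecords(b$quant))
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    quantRecords(simCoip(n_proteins = 30L, n_planted = 5L, seed = 4L)$quant),
    quantRecords(a$quant)))

  d1 <- simDEPair(n_genes = 80L, n_sig_A = 10L, seed = 2L)
  d2 <- simDEPair(n_genes = 80L, n_sig_A = 10L, seed = 2L)
  expect_identical(deData(d1$table_b), deData(d2$table_b))

  expect_identical(cellData(simCells(seed = 5L)$cells),
                   cellData(simCells(seed = 5L)$cells))
  expect_identical(flowEvents(simFlow(seed = 6L)$sample),
                   flowEvents(simFlow(seed = 6L)$sample))
  expect_identical(simImage(seed = 7L)$image, simImage(seed = 7L)$image)

  # the caller's RNG stream is left untouched
  set.seed(123); before <- .Random.seed
  invisible(simCoip(n_proteins = 10L, n_planted = 2L, seed = 99L))
  expect_identical(.Random.seed, before)
})

test_that("planted identifiers always exist in the emitted tables", {
  sim <- simCoip(n_proteins = 40L, n_planted = 8L, seed = 12L)
  expect_true(all(sim$truth$planted$destabilized %in%
                  quantRecords(sim$quant)$protein_id))
  de <- simDEPair(n_genes = 100L, n_sig_A = 20L, seed = 12L)
  expect_true(all(unlist(de$truth$planted) %in% deData(de$table_a)$gene_id))
  cs <- simCells(seed = 12L)
  expect_true(all(cs$truth$planted$nuclear_shifted %in%
                  cellData(cs$cells)$animal_id))
})

test_that("a null co-IP (no planted shift) gives indistinguishable DI groups", {
  n_sig <- 0L
  for (seed in 1:20) {
    sim <- simCoip(n_proteins = 60L, n_planted = 10L, sr_base = 0.5,
                   sr_shifted = 0.5, seed = seed)
    res <- solubilityIndexTable(sim$quant)
    res <- res[res$protein_id != "BAIT" & !is.na(res$destab_index), ]
    planted <- res$protein_id %in% sim$truth$planted$destabilized
    p <- wilcox.test(res$destab_index[planted],
                     res$destab_index[!planted], exact = FALSE)$p.value
    if (p < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})

test_that("a saturated shift recovers the expected mean DI", {
  sim <- simCoip(n_proteins = 150L, n_planted = 150L, sr_base = 0.9,
                 sr_shifted = 0.1, mean_depth = 500, dispersion = 0.01,
                 seed = 21L)
  res <- solubilityIndexTable(sim$quant)
  res <- res[res$protein_id != "BAIT", ]
  expect_lt(abs(mean(res$destab_index, na.rm = TRUE) -
                sim$truth$expected$mean_di), 0.05)
  expect_equal(sim$truth$expected$mean_di, 0.8)
})

test_that("DE-pair classification recovers planted labels at effect size 2", {
  agree <- vapply(1:20, function(seed) {
    sim <- simDEPair(n_genes = 200L, n_sig_A = 40L, frac_inverse = 0.25,
                     frac_unchanged = 0.5, effect_size = 2, seed = seed)
    out <- crossClassify(callSignificant(sim$table_a), sim$table_b)
    truth_cls <- rep(NA_character_, nrow(out$records))
    for (cl in c("inverse", "unchanged", "concordant")) {
      truth_cls[out$records$gene_id %in% sim$truth$planted[[cl]]] <- cl
    }
    mean(out$records$cls == truth_cls)
  }, numeric(1))
  expect_gte(mean(agree), 0.99)

  none <- simDEPair(n_genes = 150L, n_sig_A = 30L, frac_inverse = 0,
                    frac_unchanged = 0.5, seed = 9L)
  out <- crossClassify(callSignificant(none$table_a), none$table_b)
  expect_identical(sum(out$records$cls == "inverse"), 0L)

  expect_error(simDEPair(frac_inverse = 0.8, frac_unchanged = 0.5),
               "at most 1")
})

test_that("nuclear-shifted animals score above background at high fold shift", {
  sim <- simCells(n_animals = 40L, frac_nuclear_animals = 0.5,
                  fold_shift = 4, noise_cv = 0.1, seed = 14L)
  sc <- scoreNuclear(sim$cells)
  planted <- sc$animal_id %in% sim$truth$planted$nuclear_shifted
  expect_gt(median(sc$percent_nuclear[planted]),
            median(sc$percent_nuclear[!planted]))

  # fold_shift 1: positives arise only from noise, so percentages are low
  null <- simCells(n_animals = 40L, frac_nuclear_animals = 0.5,
                   fold_shift = 1, noise_cv = 0.2, seed = 15L)
  scn <- scoreNuclear(null$cells)
  expect_lt(mean(scn$percent_nuclear), 10)
})

test_that("flow generator hits the requested expression ratio", {
  unit <- simFlow(n_events = 2000L, expression_ratio = 1, seed = 16L)
  r1 <- tofNormalize(unit$sample, unit$control)
  expect_lt(abs(r1$relative_to_control[2L] - 1), 0.05)
  dbl <- simFlow(n_events = 2000L, expression_ratio = 2, seed = 17L)
  r2 <- tofNormalize(dbl$sample, dbl$control)
  expect_lt(abs(r2$relative_to_control[2L] - 2), 0.1)
})

test_that("image generator records the exact painted fraction", {
  empty <- simImage(n_discs = 0L, seed = 18L)
  expect_equal(empty$truth$expected$dark_fraction, 0)
  expect_equal(temBlackFraction(empty$image), 0)

  sim <- simImage(width = 96L, height = 80L, n_discs = 4L,
                  disc_radius = 8L, noise_sd = 0, seed = 19L)
  expect_equal(temBlackFraction(sim$image),
               sim$truth$expected$dark_fraction)
  expect_gt(sim$truth$expected$dark_fraction, 0)
  expect_error(simImage(width = 16L, height = 16L, disc_radius = 10L),
               "too large")
})
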