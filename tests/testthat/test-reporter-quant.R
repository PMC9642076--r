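.cells <- function(nuc, cyt, animal = "A1") {
  CellTable(data.frame(animal_id = animal,
                       cell_id = sprintf("c%02d", seq_along(nuc)),
                       nucleus_intensity = nuc, cytosol_intensity = cyt,
                       stringsAsFactors = FALSE))
}

test_that("nuclear scoring applies the >= 2-fold rule over 20 cells", {
  sc <- scoreNuclear(.cells(c(250, 199, 400, 210, 100),
                            c(100, 100, 100, 100, 100)))
  # 250/100 and 400/100 and 210/100 pass; 199/100 = 1.99 fails
  expect_identical(sc$positive_nuclei, 3L)
  expect_equal(sc$percent_nuclear, 15)

  sc4 <- scoreNuclear(.cells(rep(c(300, 100), c(4, 6)), rep(100, 10)))
  expect_equal(sc4$percent_nuclear, 20)  # 4 positives -> 4/20

  # zero cytosol: unscorable, excluded from numerator, denominator fixed
  sc0 <- scoreNuclear(.cells(c(300, 300), c(100, 0)))
  expect_identical(sc0$positive_nuclei, 1L)
  expect_identical(sc0$unscorable_cells, 1L)
  expect_equal(sc0$percent_nuclear, 5)
})

test_that("percent nuclear is always a multiple of 5 in [0, 100]", {
  sim <- simCells(n_animals = 30L, seed = 8L)
  sc <- scoreNuclear(sim$cells)
  expect_true(all(sc$percent_nuclear %in% seq(0, 100, by = 5)))
})

test_that("TOF normalization is per-event ratio, then group mean vs control", {
  ctl <- EventTable(data.frame(event_id = c("c1", "c2"), tof = c(200, 100),
                               fluor_integral = c(1000, 500)), "control")
  smp <- EventTable(data.frame(event_id = c("s1", "s2"), tof = c(100, 100),
                               fluor_integral = c(1200, 800)), "sample")
  out <- tofNormalize(smp, ctl)
  expect_equal(out$value[out$group_label == "control"], 5)   # 1000/200
  expect_equal(out$value[out$group_label == "sample"], 10)
  expect_equal(out$relative_to_control, c(1, 2))

  # doubling fluor and tof together changes nothing
  d <- flowEvents(smp)
  d$tof <- d$tof * 2; d$fluor_integral <- d$fluor_integral * 2
  out2 <- tofNormalize(EventTable(d, "sample"), ctl)
  expect_equal(out2$relative_to_control, out$relative_to_control)

  # control against itself is exactly 1
  self <- tofNormalize(ctl, ctl)
  expect_equal(self$relative_to_control, c(1, 1))
  expect_error(tofNormalize(smp, EventTable(flowEvents(ctl)[0, ], "control")),
               "no events")
})

test_that("oil red O density is inverse brightness over the control mean", {
  eq <- oroDensity(3, c(3, 3, 3))
  expect_equal(eq$relative_density[eq$group_label == "sample"], 1.0)
  half <- oroDensity(2, c(4, 4))
  expect_equal(half$relative_density[half$group_label == "sample"], 2.0)
  # control {2, 4}, sample 2: (1/2) / ((1/2 + 1/4)/2) = 4/3
  mixed <- oroDensity(2, c(2, 4))
  expect_equal(mixed$relative_density[mixed$group_label == "sample"], 4 / 3)
  # the control group's own mean relative density is 1 by construction
  expect_equal(mean(mixed$relative_density[mixed$group_label == "control"]),
               1.0)
  # alternative denominator: inverse of the mean control brightness
  alt <- oroDensity(2, c(2, 4), control_stat = "inverse-of-mean")
  expect_equal(alt$relative_density[alt$group_label == "sample"], 3 / 2)
  expect_error(oroDensity(0, c(2, 4)), "positive")
})

test_that("TEM black fraction inverts then thresholds", {
  white <- matrix(255L, 4, 4)
  black <- matrix(0L, 4, 4)
  expect_equal(temBlackFraction(white), 0)
  expect_equal(temBlackFraction(black), 1)
  # double inversion is the identity on the fraction
  img <- matrix(as.integer(c(0, 60, 200, 255)), 2, 2)
  expect_equal(temBlackFraction(255L - (255L - img)),
               temBlackFraction(img))
  expect_error(temBlackFraction(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(temBlackFraction(img, threshold = 300), "\\[0, 255\\]")

  rel <- temRelativeDensity(list(black), list(img, img))
  expect_equal(rel$relative_density[rel$group_label == "control"], c(1, 1))
  expect_equal(rel$relative_density[rel$group_label == "sample"], 2)
})

test_that("delta-delta-Ct reproduces hand-worked fold changes", {
  mkct <- function(df) CtTable(df, housekeeping_ids = c("hk1", "hk2"))
  base <- expand.grid(sample_label = c("ctrl", "smp"),
                      gene_id = c("tgt", "hk1", "hk2"),
                      replicate = 1:2, stringsAsFactors = FALSE)

  same <- base; same$ct <- 20
  out <- deltaDeltaCt(mkct(same), "ctrl")
  expect_equal(out$rel_abundance, c(1, 1))

  # target one cycle lower in the sample, housekeeping equal -> 2-fold
  one <- base
  one$ct <- ifelse(one$gene_id == "tgt", ifelse(one$sample_label == "smp",
                                                19, 20), 15)
  out1 <- deltaDeltaCt(mkct(one), "ctrl")
  expect_equal(out1$rel_abundance[out1$sample_label == "smp"], 2)

  # target 20 vs 22, housekeeping means 15 vs 16:
  # ddCt = (20-15) - (22-16) = -1 -> 2^1 = 2
  hand <- base
  hand$ct <- ifelse(hand$gene_id == "tgt",
                    ifelse(hand$sample_label == "smp", 20, 22),
                    ifelse(hand$sample_label == "smp", 15, 16))
  outh <- deltaDeltaCt(mkct(hand), "ctrl")
  expect_equal(outh$delta_delta_ct[outh$sample_label == "smp"], -1)
  expect_equal(outh$rel_abundance[outh$sample_label == "smp"], 2)

  # a constant added to every Ct of one sample's run (target and
  # housekeeping alike) cancels in delta-Ct ...
  shift <- hand
  shift$ct[shift$sample_label == "smp"] <-
    shift$ct[shift$sample_label == "smp"] + 3
  expect_equal(deltaDeltaCt(mkct(shift), "ctrl")$rel_abundance,
               outh$rel_abundance)
  # ... but a shift on the target alone does not
  tshift <- hand
  tshift$ct[tshift$sample_label == "smp" & tshift$gene_id == "tgt"] <-
    tshift$ct[tshift$sample_label == "smp" & tshift$gene_id == "tgt"] + 3
  expect_false(isTRUE(all.equal(
    deltaDeltaCt(mkct(tshift), "ctrl")$rel_abundance,
    outh$rel_abundance)))

  expect_error(deltaDeltaCt(mkct(hand), "nope"), "not found")
})

test_that("absorption impairment counts strictly sub-cutoff animals", {
  expect_equal(absorptionImpairment(c(0.9, 0.8, 0.2)), 100 / 3)
  expect_equal(absorptionImpairment(rep(0.5, 6)), 0)  # strict "less than"
  expect_error(absorptionImpairment(numeric(0)), "no animals")
  expect_error(absorptionImpairment(c(0.5, 1.2)), "\\[0, 1\\]")
})
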