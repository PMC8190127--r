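test_that("the 5-PL forward curve anchors its asymptotes", {
  p <- fivepl_params(a = 50, d = 28000, c = 400, b = 1.1, g = 1.3)
  expect_equal(fivepl(0, p), 50)
  expect_lt(fivepl(1e9, p), 28000)
  expect_gt(fivepl(1e9, p), 27990)
  # midpoint dose evaluates to the mid response (forward-evaluation oracle)
  xm <- fivepl_midpoint(p)
  expect_equal(fivepl(xm, p), (50 + 28000) / 2)
  expect_error(fivepl_params(50, 28000, -1, 1, 1), "positive")
  expect_error(fivepl_params(50, 28000, 400, 1, -1), "monotone")
})

test_that("invert_5pl is the closed-form inverse on the open range", {
  set.seed(31)
  for (i in 1:200) {
    p <- fivepl_params(runif(1, 10, 100), runif(1, 5000, 40000),
                       exp(runif(1, log(20), log(2000))),
                       runif(1, 0.5, 2.5), runif(1, 0.3, 3))
    x <- p$c * exp(runif(4, log(1 / 20), log(20)))
    xr <- invert_5pl(p, fivepl(x, p))
    expect_equal(as.numeric(xr), x, tolerance = 1e-6)
    expect_true(all(attr(xr, "range_flag") == "ok"))
  }
})

test_that("out-of-range responses are flagged, not thrown", {
  p <- fivepl_params(a = 50, d = 28000, c = 400, b = 1.1, g = 1.3)
  hi <- invert_5pl(p, 30000)
  expect_true(is.na(as.numeric(hi)))
  expect_equal(attr(hi, "range_flag"), "above")
  lo <- invert_5pl(p, 10)
  expect_equal(attr(lo, "range_flag"), "below")
  at_blank <- invert_5pl(p, 50)
  expect_equal(as.numeric(at_blank), 0)
  expect_equal(attr(at_blank, "range_flag"), "ok")
})

test_that("fit_5pl recovers parameters on noiseless standards", {
  truth <- fivepl_params(a = 50, d = 28000, c = 400, b = 1.1, g = 1.3)
  concs <- c(0, 10000 / 4^(6:0))
  fit <- fit_5pl(concs, fivepl(concs, truth))
  for (nm in c("a", "d", "c", "b", "g")) {
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 0.01)
  }
  expect_error(fit_5pl(concs, rep(100, length(concs))), "constant")
  expect_error(fit_5pl(c(0, 1, 2, 3, 4), 1:5), "at least 6")
})

test_that("fold change against control behaves and propagates flags", {
  expect_equal(fold_change_vs_control(c(2, 2, 2), c(2, 2, 2))$fold, 1)
  expect_equal(fold_change_vs_control(c(290, 310, 300),
                                      c(105, 95, 100))$fold, 3)
  z <- fold_change_vs_control(c(1, 2), c(0, 0))
  expect_equal(z$flag, "zero_control")
  expect_true(is.na(z$fold))
  expect_error(fold_change_vs_control(numeric(0), 1:3), "non-empty")
})

test_that("a planted 4x treatment effect is recovered through the 5-PL
          pipeline within simulation bounds", {
  for (seed in 1:3) {
    mt <- gen_molecular_tables(seed = seed)
    std <- mt$immunoassay[mt$immunoassay$type == "standard" &
                            mt$immunoassay$analyte == "IL-6", ]
    fit <- fit_5pl(std$expected_conc, std$mfi)
    smp <- mt$immunoassay[mt$immunoassay$type == "sample" &
                            mt$immunoassay$analyte == "IL-6" &
                            mt$immunoassay$channel == "top", ]
    conc <- as.numeric(invert_5pl(fit, smp$mfi))
    f <- fold_change_vs_control(conc[smp$condition == "treated"],
                                conc[smp$condition == "control"])
    expect_gt(f$fold, 3)
    expect_lt(f$fold, 5.5)
  }
})

test_that("ddct fold changes: identity, closed form, and shift invariance", {
  rec <- expand.grid(gene = c("X", "GAPDH"), condition = c("ctl", "trt"),
                     replicate = 1:3, stringsAsFactors = FALSE)
  rec$ct <- ifelse(rec$gene == "GAPDH", 18, 25)
  fc <- ddct_fold_changes(rec, reference_condition = "ctl")
  expect_true(all(fc$fold_change == 1))
  # a ddCt of -log2(10) is exactly a 10-fold change
  rec2 <- rec
  rec2$ct[rec2$gene == "X" & rec2$condition == "trt"] <- 25 - log2(10)
  fc2 <- ddct_fold_changes(rec2, reference_condition = "ctl")
  expect_equal(fc2$fold_change[fc2$condition == "trt"], 10,
               tolerance = 1e-12)
  # shifting every Ct by a constant leaves folds unchanged
  rec3 <- rec2
  rec3$ct <- rec3$ct + 3
  fc3 <- ddct_fold_changes(rec3, reference_condition = "ctl")
  expect_equal(fc3$fold_change, fc2$fold_change)
  # per-replicate aggregation agrees on balanced noiseless data
  fc4 <- ddct_fold_changes(rec2, reference_condition = "ctl",
                           method = "per_replicate")
  expect_equal(fc4$fold_change[fc4$condition == "trt"], 10)
})

test_that("ddct validates its inputs", {
  rec <- data.frame(gene = "X", condition = "ctl", replicate = 1, ct = 25)
  expect_error(ddct_fold_changes(rec, "ctl"), "reference-gene")
  bad <- data.frame(gene = c("X", "GAPDH"), condition = "ctl",
                    replicate = 1, ct = c(25, 45))
  expect_error(ddct_fold_changes(bad, "ctl"), "40")
  rec2 <- data.frame(gene = c("X", "GAPDH"), condition = "ctl",
                     replicate = 1, ct = c(25, 18))
  expect_error(ddct_fold_changes(rec2, "other"), "reference condition")
})

test_that("channel-specific enrichment planted at 100x is recovered", {
  mt <- gen_molecular_tables(seed = 5)
  rec <- mt$qpcr[mt$qpcr$condition == "control", ]
  rec$condition <- rec$channel
  rec$channel <- NULL
  fc <- ddct_fold_changes(rec, reference_condition = "bottom")
  ec <- fc[fc$condition == "top" &
             fc$gene %in% c("KLF2", "NOS3", "PECAM1", "CDH5"), ]
  # Ct noise of 0.15 cycles over n = 3 puts the Monte-Carlo spread of a
  # 100-fold change at roughly +/- 30 percent
  expect_true(all(ec$fold_change > 60 & ec$fold_change < 160))
  pc <- fc[fc$condition == "top" & fc$gene %in% c("CSPG4", "PDGFRB"), ]
  expect_true(all(pc$fold_change < 1 / 60))
})
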