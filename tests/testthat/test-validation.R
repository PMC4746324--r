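test_that("amplification efficiency is recovered from clean curves", {
  ## perfect doubling: E = 2 in closed form (slope = log10 2)
  est <- estimateEfficiency(100 * 2^(1:30))
  expect_true(est$ok)
  expect_equal(est$efficiency, 2, tolerance = 1e-4)
  ## known efficiency with a plateau after the exponential phase
  qp <- generateQpcr(seed = 1, noiseSd = 0,
                     genes = data.frame(gene = "G", true_ratio = 2,
                                        efficiency = 1.8))
  cur <- qp$curves[qp$curves$well == "G_low_1", ]
  est2 <- estimateEfficiency(cur$fluorescence, cur$cycle)
  expect_equal(est2$efficiency, 1.8, tolerance = 0.01)
  ## the selected window must sit before the plateau
  expect_lt(est2$window[2], 35)
  ## flat curves are flagged, not forced
  expect_false(estimateEfficiency(rep(100, 40))$ok)
  ## a slope above the physical cap is clipped to 2.2
  expect_equal(estimateEfficiency(10 * 3^(1:20))$efficiency, 2.2)
})

test_that("efficiency recovery tolerates multiplicative read noise", {
  errs <- vapply(1:10, function(s) {
    qp <- generateQpcr(seed = s, noiseSd = 0, curveNoiseCv = 0.02,
                       genes = data.frame(gene = "G", true_ratio = 2,
                                          efficiency = 1.8))
    cur <- qp$curves[qp$curves$well == "G_low_1", ]
    est <- estimateEfficiency(cur$fluorescence, cur$cycle)
    abs(est$efficiency - 1.8)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("Pfaffl ratios reduce to 2^(-ddCt) at perfect efficiency", {
  ## worked example: E_t = 1.8, dCt_t = 2, E_ref = 2, dCt_ref = 1
  rec <- data.frame(
    gene = rep(c("T", "ACT"), each = 2),
    condition = rep(c("low", "high"), 2), replicate = 1,
    ct = c(20, 22, 20, 21),
    efficiency = c(1.8, 1.8, 2, 2), melt_ok = TRUE)
  r <- pfafflRatio(rec, "T")
  expect_equal(r$ratio, 1.8^2 / 2.0, tolerance = 1e-12)
  expect_equal(r$ratio, 1.62, tolerance = 1e-12)
  ## algebraic identity with E = 2 everywhere, randomized Ct tables
  set.seed(5)
  for (i in 1:25) {
    ct <- round(runif(4, 15, 30), 2)
    rec2 <- data.frame(
      gene = rep(c("T", "ACT"), each = 2),
      condition = rep(c("low", "high"), 2), replicate = 1,
      ct = ct, efficiency = 2, melt_ok = TRUE)
    ddct <- (ct[2] - ct[1]) - (ct[4] - ct[3])
    expect_equal(pfafflRatio(rec2, "T")$ratio, 2^ddct, tolerance = 1e-12)
  }
  ## unchanged target and reference -> ratio exactly 1
  recEq <- data.frame(gene = rep(c("T", "ACT"), each = 2),
                      condition = rep(c("low", "high"), 2), replicate = 1,
                      ct = 20, efficiency = 2, melt_ok = TRUE)
  expect_equal(pfafflRatio(recEq, "T")$ratio, 1)
})

test_that("Pfaffl handles references, melt failures and missing data", {
  rec <- data.frame(
    gene = rep(c("T", "ACT", "UBQ"), each = 2),
    condition = rep(c("low", "high"), 3), replicate = 1,
    ct = c(20, 22, 20, 21, 20, 20),
    efficiency = 2, melt_ok = TRUE)
  ## geometric mean of the two reference factors: sqrt(2^1 * 2^0)
  r2 <- pfafflRatio(rec, "T", reference = c("ACT", "UBQ"))
  expect_equal(r2$ratio, 2^2 / sqrt(2), tolerance = 1e-12)
  ## melt-curve failures are excluded with a warning
  recBad <- rbind(rec, data.frame(gene = "T", condition = "low",
                                  replicate = 2, ct = 5, efficiency = 2,
                                  melt_ok = FALSE))
  expect_warning(rBad <- pfafflRatio(recBad, "T"), "melt")
  expect_equal(rBad$ratio, pfafflRatio(rec, "T")$ratio)
  ## a gene missing one condition is an error
  expect_error(pfafflRatio(rec[rec$condition == "low" |
                                 rec$gene != "T", ], "T"), "condition")
  ## generator truth: ratio 4 at E = 2, noise-free
  qp <- generateQpcr(seed = 2, noiseSd = 0)
  expect_equal(pfafflRatio(qp$ct, "CAH1")$ratio, 4, tolerance = 0.02)
  expect_equal(pfafflRatio(qp$ct, "GPM2")$ratio, 0.7, tolerance = 0.02)
})

test_that("cell-count and TIC normalization behaves as constructed", {
  mb <- generateMetabolites(seed = 4)
  norm <- normalizeMetabolites(mb$table)
  analytes <- setdiff(names(norm), c("sample", "condition", "cell_count"))
  ## per-sample sums are exactly 1
  expect_equal(unname(rowSums(norm[analytes])), rep(1, nrow(norm)),
               tolerance = 1e-12)
  ## invariant to rescaling one sample's raw intensities
  scaled <- mb$table
  scaled[2, analytes] <- scaled[2, analytes] * 7.3
  expect_equal(normalizeMetabolites(scaled)[analytes], norm[analytes],
               tolerance = 1e-12)
  ## equal cell counts make the cell-count step a no-op
  mbEq <- generateMetabolites(seed = 4, equalCellCounts = TRUE)
  normEq <- normalizeMetabolites(mbEq$table)
  noCounts <- mbEq$table
  noCounts$cell_count <- 1
  expect_equal(normalizeMetabolites(noCounts)[analytes], normEq[analytes],
               tolerance = 1e-12)
  ## degenerate inputs are refused
  bad <- mb$table; bad$cell_count[1] <- 0
  expect_error(normalizeMetabolites(bad), "cell count")
  bad2 <- mb$table; bad2[1, analytes] <- 0
  expect_error(normalizeMetabolites(bad2), "total ion")
})

test_that("fold changes recover planted effects and flag absences", {
  mb <- generateMetabolites(seed = 10, cv = 0.1)
  fc <- log2FoldChange(normalizeMetabolites(mb$table))
  expect_gte(fc$log2fc[fc$analyte == "xylose"], 2)     # > 5-fold planted
  expect_lt(fc$log2fc[fc$analyte == "sucrose"], -0.5)  # planted decrease
  nulls <- fc$log2fc[!fc$analyte %in% c("xylose", "sucrose", "glycerate")]
  expect_lt(stats::median(abs(nulls)), 0.3)
  ## equal means give exactly zero
  tab <- data.frame(sample = paste0("s", 1:4),
                    condition = rep(c("low", "high"), each = 2),
                    cell_count = 1, a = c(5, 5, 5, 5), b = c(1, 3, 1, 3))
  fc0 <- log2FoldChange(normalizeMetabolites(tab))
  expect_equal(fc0$log2fc[fc0$analyte == "a"], 0)
  ## analyte absent in one condition is flagged, not dropped
  tab$b <- c(0, 0, 2, 2)
  fcAbs <- log2FoldChange(normalizeMetabolites(
    within(tab, b[1:2] <- 1e-12)))
  expect_equal(nrow(fcAbs), 2)
  expect_error(log2FoldChange(normalizeMetabolites(tab)[1:2, ]),
               "two replicates")
})

test_that("concordance compares predicted and measured directions", {
  nf <- data.frame(metabolite_id = c("up[c]", "down[c]", "undef[c]"),
                   net_flux_low = c(1, 2, 1),
                   net_flux_high = c(2, 1, 0))
  fc <- data.frame(analyte = c("up", "down", "undef"),
                   log2fc = c(0.8, 0.5, 1))
  rep <- concordance(nf, fc)
  tab <- rep$table
  expect_equal(tab$status[tab$analyte == "up"], "concordant")
  expect_equal(tab$status[tab$analyte == "down"], "discordant")
  expect_equal(tab$status[tab$analyte == "undef"], "unevaluable")
  expect_warning(concordance(nf, data.frame(analyte = "zz", log2fc = 1)),
                 "no shared")
  ## generator scenario: 13 evaluable, 10 planted concordant
  sc <- synthConcordanceScenario(seed = 11)
  fc2 <- log2FoldChange(normalizeMetabolites(sc$measurements))
  rep2 <- concordance(sc$netflux, fc2)
  expect_equal(unname(rep2$counts["concordant"]), sc$truth$concordant)
  expect_equal(unname(rep2$counts["discordant"]), sc$truth$discordant)
  expect_equal(sum(rep2$counts[c("concordant", "discordant")]), 13L)
})
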