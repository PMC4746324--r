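#' Estimate qPCR amplification efficiency from a fluorescence curve
#'
#' Fits log10(fluorescence) against cycle number over sliding windows of
#' 4-6 cycles restricted to the exponential phase (readings clearly above
#' the baseline estimated from the earliest cycles) and converts the best
#' window's slope into the per-cycle amplification factor E = 10^slope.
#' Among windows reaching the R-squared threshold the widest is taken
#' (ties by R-squared, then by earliest start), which stabilizes the
#' estimate against read noise; E is capped at `eMax` and estimates at or
#' below 1 are failures. A curve with no window of sufficient linear
#' quality (e.g. a flat well) is flagged rather than forced.
#'
#' @param fluorescence numeric readings, one per cycle (arbitrary units,
#'   non-negative).
#' @param cycles cycle numbers (default `seq_along(fluorescence)`);
#'   strictly increasing.
#' @param windowWidths candidate window widths in cycles.
#' @param r2Threshold minimal R-squared for an acceptable window.
#' @param baselineCycles indices used to estimate the baseline.
#' @param eMax upper cap on E (default 2.2).
#' @return list with `efficiency` (NA on failure), `ok`, `r2`, `window`
#'   (first and last cycle used) and `reason` for failures.
#' @examples
#' est <- estimateEfficiency(100 * 2^(1:30))
#' est$efficiency  # 2
#' @export
estimateEfficiency <- function(fluorescence, cycles = seq_along(fluorescence),
                               windowWidths = 4:6, r2Threshold = 0.99,
                               baselineCycles = 1:5, eMax = 2.2) {
  stopifnot(length(fluorescence) == length(cycles),
            all(diff(cycles) > 0), all(fluorescence >= 0))
  fail <- function(reason) list(efficiency = NA_real_, ok = FALSE,
                                r2 = NA_real_, window = c(NA, NA),
                                reason = reason)
  bl <- fluorescence[baselineCycles[baselineCycles <= length(fluorescence)]]
  baseline <- stats::median(bl)
  noise <- stats::mad(bl)
  corrected <- fluorescence - baseline
  ## exponential-phase gate: well clear of the baseline (so additive
  ## baseline noise cannot dominate the log signal) and clear of
  ## saturation, whose smooth bend depresses window slopes while leaving
  ## R-squared high
  eligible <- corrected > max(10 * noise, baseline, 1e-9) &
    corrected < 0.05 * max(corrected)
  if (sum(eligible) < min(windowWidths)) return(fail("no exponential phase"))
  ## when the curve demonstrably plateaus, invert the saturation
  ## (signal -> signal / (1 - signal/plateau)) so the fitted phase is
  ## exactly log-linear; curves still rising at the last cycle are left
  ## untouched
  n <- length(corrected)
  peak <- max(corrected)
  signal <- corrected
  if (n >= 2L && corrected[n - 1L] > 0 &&
      corrected[n] / corrected[n - 1L] < 1.1) {
    signal <- corrected / (1 - pmin(corrected / peak, 0.99))
  }

  best <- NULL
  idx <- which(eligible)
  for (w in sort(windowWidths, decreasing = TRUE)) {
    for (s in idx) {
      win <- s:(s + w - 1L)
      if (max(win) > length(cycles) || !all(eligible[win])) next
      y <- log10(signal[win])
      x <- cycles[win]
      fit <- stats::lm.fit(cbind(1, x), y)
      slope <- fit$coefficients[2]
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (!is.finite(r2) || !is.finite(slope)) next
      if (r2 >= r2Threshold && slope > 0 &&
          (is.null(best) || r2 > best$r2)) {
        best <- list(slope = slope, r2 = r2, window = c(x[1], x[w]))
      }
    }
    if (!is.null(best)) break  # widest acceptable width wins
  }
  if (is.null(best))
    return(fail("no window with sufficient linearity"))
  E <- min(10^unname(best$slope), eMax)
  if (E <= 1) return(fail("non-amplifying slope"))
  list(efficiency = E, ok = TRUE, r2 = best$r2, window = best$window,
       reason = NA_character_)
}

#' Efficiency-corrected relative expression (Pfaffl) ratio
#'
#' Computes the relative expression of a target gene between two CO2
#' conditions, corrected by one or more reference genes:
#' `ratio = E_t^dCt_t / E_ref^dCt_ref` with `dCt = Ct(high) - Ct(low)`, so
#' a ratio above 1 means higher expression at low CO2. With several
#' reference genes the geometric mean of their correction factors is used.
#' Records failing the melt-curve check are excluded (with a warning)
#' before Ct values are averaged over replicates; with all efficiencies
#' equal to 2 the ratio reduces to the classical 2^(-ddCt).
#'
#' @param records data.frame with columns `gene`, `condition` (`"low"` /
#'   `"high"`), `replicate`, `ct`, `efficiency`, `melt_ok` (logical).
#' @param target target gene name.
#' @param reference reference gene name(s); default `"ACT"` (actin), the
#'   housekeeping normalizer.
#' @param contrast which condition is the numerator of the underlying
#'   template comparison; `"low_vs_high"` (default) gives ratios > 1 for
#'   genes more expressed at low CO2.
#' @return list with `gene`, `ratio`, `reference_genes`, `dct_target`,
#'   `dct_reference`.
#' @examples
#' rec <- data.frame(
#'   gene = rep(c("CAH1", "ACT"), each = 2),
#'   condition = rep(c("low", "high"), 2), replicate = 1,
#'   ct = c(20, 21, 25, 25), efficiency = 2, melt_ok = TRUE)
#' pfafflRatio(rec, "CAH1")$ratio  # 2
#' @export
pfafflRatio <- function(records, target, reference = "ACT",
                        contrast = c("low_vs_high", "high_vs_low")) {
  contrast <- match.arg(contrast)
  need <- c("gene", "condition", "replicate", "ct", "efficiency", "melt_ok")
  stopifnot(all(need %in% names(records)))
  if (any(!records$melt_ok)) {
    warning(sum(!records$melt_ok),
            " record(s) discarded for failed melt curves")
    records <- records[records$melt_ok, , drop = FALSE]
  }
  if (any(records$ct <= 0)) stop("Ct values must be positive")
  if (any(records$efficiency <= 1 | records$efficiency > 2.2))
    stop("efficiencies must be in (1, 2.2]")
  factorOf <- function(gene) {
    sub <- records[records$gene == gene, , drop = FALSE]
    ctLow <- sub$ct[sub$condition == "low"]
    ctHigh <- sub$ct[sub$condition == "high"]
    if (length(ctLow) == 0L || length(ctHigh) == 0L)
      stop("gene '", gene, "' lacks measurements in one condition")
    dct <- mean(ctHigh) - mean(ctLow)
    if (contrast == "high_vs_low") dct <- -dct
    list(E = mean(sub$efficiency), dct = dct,
         value = mean(sub$efficiency)^dct)
  }
  ft <- factorOf(target)
  fr <- lapply(reference, factorOf)
  refFactor <- exp(mean(log(vapply(fr, `[[`, numeric(1), "value"))))
  list(gene = target, ratio = ft$value / refFactor,
       reference_genes = reference, dct_target = ft$dct,
       dct_reference = vapply(fr, `[[`, numeric(1), "dct"))
}

#' Normalize metabolite intensities by cell count and total ion content
#'
#' Each sample's analyte intensities are divided by the sample's cell
#' count and then by the sample's total ion content (the sum over analytes
#' after the cell-count step), so every sample's analyte values sum to 1.
#' The result is invariant to rescaling the raw intensities of any single
#' sample.
#'
#' @param table data.frame with columns `sample`, `condition`,
#'   `cell_count` and one numeric column per analyte.
#' @return the table with analyte columns normalized.
#' @export
normalizeMetabolites <- function(table) {
  meta <- c("sample", "condition", "cell_count")
  stopifnot(all(meta %in% names(table)))
  analytes <- setdiff(names(table), meta)
  if (length(analytes) == 0L) stop("no analyte columns")
  X <- as.matrix(table[analytes])
  if (any(X < 0)) stop("intensities must be non-negative")
  if (any(table$cell_count <= 0)) stop("zero or negative cell count")
  X <- X / table$cell_count
  tic <- rowSums(X)
  if (any(tic <= 0)) stop("zero total ion content in sample(s): ",
                          paste(table$sample[tic <= 0], collapse = ", "))
  table[analytes] <- X / tic
  table
}

#' Per-analyte log2 fold changes with Welch tests
#'
#' For each analyte, computes the log2 ratio of condition means
#' (`high` over `low` by default), a Welch two-sample t-test on the
#' log2-scale replicate values, and Benjamini-Hochberg adjustment across
#' analytes. Analytes with no positive value in one of the conditions are
#' flagged and their test skipped rather than silently dropped.
#'
#' @param normTable normalized table from [normalizeMetabolites()].
#' @param numerator,denominator condition labels contrasted (default
#'   high over low CO2).
#' @return data.frame with columns `analyte`, `log2fc`, `p_value`,
#'   `p_adj`, `n_num`, `n_den`, `flag`.
#' @export
log2FoldChange <- function(normTable, numerator = "high",
                           denominator = "low") {
  analytes <- setdiff(names(normTable),
                      c("sample", "condition", "cell_count"))
  isNum <- normTable$condition == numerator
  isDen <- normTable$condition == denominator
  if (sum(isNum) < 2L || sum(isDen) < 2L)
    stop("need at least two replicates per condition")
  rows <- lapply(analytes, function(a) {
    xn <- normTable[[a]][isNum]
    xd <- normTable[[a]][isDen]
    flag <- NA_character_
    if (all(xn <= 0) || all(xd <= 0)) {
      return(data.frame(analyte = a, log2fc = NA_real_, p_value = NA_real_,
                        n_num = sum(isNum), n_den = sum(isDen),
                        flag = "absent in one condition",
                        stringsAsFactors = FALSE))
    }
    l2 <- log2(mean(xn) / mean(xd))
    p <- tryCatch(
      stats::t.test(log2(xn[xn > 0]), log2(xd[xd > 0]))$p.value,
      error = function(e) NA_real_)
    data.frame(analyte = a, log2fc = l2, p_value = p,
               n_num = sum(isNum), n_den = sum(isDen), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out[c("analyte", "log2fc", "p_value", "p_adj", "n_num", "n_den", "flag")]
}

#' Concordance between predicted net fluxes and measured fold changes
#'
#' Compares, per metabolite, the direction the model predicts between high
#' and low CO2 (the sign of log2 of net flux at high over net flux at low
#' CO2, from the CO2-sensitive reactions) with the measured direction (the
#' sign of the high-vs-low log2 fold change). Metabolites whose net-flux
#' ratio is undefined, non-positive (a sign change between conditions,
#' where a log-ratio direction is meaningless) or zero are reported as
#' unevaluable rather than forced into either class.
#'
#' @param netflux data.frame from [netFluxTable()].
#' @param foldChanges data.frame from [log2FoldChange()]; metabolite
#'   matching is by `analyte` against `metabolite_id` after stripping
#'   compartment tags, or via `mapping`.
#' @param mapping optional data.frame with columns `metabolite_id`,
#'   `analyte` linking model metabolites to measured analytes.
#' @param eps tolerance for treating fluxes or fold changes as zero.
#' @return list of class `concordanceReport`: `table` (one row per shared
#'   metabolite with `predicted_sign`, `measured_sign`, `status`) and
#'   `counts` (`concordant`, `discordant`, `unevaluable`).
#' @export
concordance <- function(netflux, foldChanges, mapping = NULL, eps = 1e-9) {
  if (is.null(mapping)) {
    mapping <- data.frame(metabolite_id = netflux$metabolite_id,
                          analyte = speciesName(netflux$metabolite_id),
                          stringsAsFactors = FALSE)
  }
  mapping <- mapping[mapping$analyte %in% foldChanges$analyte &
                       mapping$metabolite_id %in% netflux$metabolite_id, ,
                     drop = FALSE]
  if (nrow(mapping) == 0L) {
    warning("no shared metabolites between predictions and measurements")
    return(structure(list(table = data.frame(),
                          counts = c(concordant = 0L, discordant = 0L,
                                     unevaluable = 0L)),
                     class = "concordanceReport"))
  }
  rows <- lapply(seq_len(nrow(mapping)), function(k) {
    nf <- netflux[netflux$metabolite_id == mapping$metabolite_id[k], ][1, ]
    fc <- foldChanges[foldChanges$analyte == mapping$analyte[k], ][1, ]
    lo <- nf$net_flux_low; hi <- nf$net_flux_high
    status <- "unevaluable"; predSign <- NA_real_
    measSign <- if (is.na(fc$log2fc)) NA_real_ else sign(fc$log2fc)
    if (abs(lo) > eps && hi / lo > 0) {
      predSign <- sign(log2(hi / lo))
      if (predSign != 0 && !is.na(measSign) && abs(fc$log2fc) > eps)
        status <- if (predSign == measSign) "concordant" else "discordant"
    }
    data.frame(metabolite_id = mapping$metabolite_id[k],
               analyte = mapping$analyte[k],
               net_flux_low = lo, net_flux_high = hi,
               predicted_sign = predSign, measured_log2fc = fc$log2fc,
               measured_sign = measSign, status = status,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts <- c(concordant = sum(tab$status == "concordant"),
              discordant = sum(tab$status == "discordant"),
              unevaluable = sum(tab$status == "unevaluable"))
  structure(list(table = tab, counts = counts), class = "concordanceReport")
}

#' @export
print.concordanceReport <- function(x, ...) {
  cat("Concordance of FBA net fluxes with measured fold changes\n")
  cat(sprintf("  concordant %d / discordant %d / unevaluable %d\n",
              x$counts["concordant"], x$counts["discordant"],
              x$counts["unevaluable"]))
  invisible(x)
}
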