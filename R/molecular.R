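# Channel-specific molecular readout processing: five-parameter logistic
# (5-PL) immunoassay calibration and inversion with fold-change
# normalisation, and comparative-CT qPCR fold changes.

#' Evaluate the five-parameter logistic curve
#'
#' `F(x) = d + (a - d) / (1 + (x/c)^b)^g` with `a` the response at zero
#' dose, `d` the response at infinite dose, `c` the inflection-scale
#' concentration, `b` the slope factor and `g` the asymmetry factor. The
#' curve is strictly monotone between the asymptotes when `b * g > 0`.
#'
#' @param x Concentrations (>= 0).
#' @param params A `fivepl_params` object or a named list with elements
#'   `a`, `d`, `c`, `b`, `g`.
#' @return Predicted responses (MFI).
#' @export
fivepl <- function(x, params) {
  p <- unclass(params)
  ifelse(x <= 0, p$a, p$d + (p$a - p$d) / (1 + (x / p$c)^p$b)^p$g)
}

#' Construct 5-PL parameters
#'
#' @param a,d Asymptotes at zero and infinite dose (MFI).
#' @param c Inflection-scale concentration (> 0), pg/mL.
#' @param b Slope factor.
#' @param g Asymmetry factor (`b * g > 0` for monotonicity).
#' @return An object of class `fivepl_params`.
#' @export
fivepl_params <- function(a, d, c, b, g) {
  if (!is.finite(c) || c <= 0) stop("c must be positive", call. = FALSE)
  if (!is.finite(b) || !is.finite(g) || b * g <= 0) {
    stop("b * g must be positive for a monotone curve", call. = FALSE)
  }
  structure(list(a = a, d = d, c = c, b = b, g = g),
            class = "fivepl_params")
}

#' @export
print.fivepl_params <- function(x, ...) {
  cat(sprintf(
    "5-PL: a = %.4g, d = %.4g, c = %.4g, b = %.4g, g = %.4g\n",
    x$a, x$d, x$c, x$b, x$g))
  invisible(x)
}

#' Fit a five-parameter logistic standard curve
#'
#' Levenberg-Marquardt least squares of the 5-PL model to immunoassay
#' standards. Initial guesses come from the data extremes (asymptotes), the
#' log-midpoint response (for `c`) and a unit slope/asymmetry; `c` and the
#' asymmetry `g` are fitted on the log scale to keep them positive. A blank
#' (`x = 0`) standard anchors the lower asymptote, since `F(0) = a`
#' exactly in this parameterisation.
#'
#' Bead-based immunoassay reads have multiplicative (constant-CV) noise,
#' so residuals are weighted by the predicted response by default
#' (`weighting = "cv"`); set `weighting = "none"` for ordinary least
#' squares. The asymmetry `g` is constrained to `[0.25, 4]`: outside that
#' range `g` trades off against `c` along a near-flat likelihood ridge (a
#' structural non-identifiability of the 5-PL family), and the fitted
#' scale parameter loses meaning while the fitted curve is unchanged. The
#' returned object carries the identifiable midpoint concentration (dose
#' at the response halfway between the asymptotes) in its `midpoint`
#' attribute.
#'
#' @param standard_concs Standard concentrations, pg/mL (>= 6 distinct
#'   points spanning the sigmoid; may include 0; duplicates welcome).
#' @param standard_mfis Measured responses at those concentrations.
#' @param weighting `"cv"` (default) or `"none"`.
#' @return A `fivepl_params` object with attributes `residual_sd`,
#'   `fitted` and `midpoint`.
#' @export
fit_5pl <- function(standard_concs, standard_mfis,
                    weighting = c("cv", "none")) {
  weighting <- match.arg(weighting)
  x <- as.numeric(standard_concs)
  y <- as.numeric(standard_mfis)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 6) {
    stop("need at least 6 distinct standard concentrations", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("constant responses: no curve to fit", call. = FALSE)
  }
  ord <- order(x)
  increasing <- stats::cor(x[ord], y[ord], method = "spearman") > 0
  a0 <- if (increasing) min(y) else max(y)
  d0 <- if (increasing) max(y) else min(y)
  mid <- (a0 + d0) / 2
  pos <- x[x > 0]
  c0 <- tryCatch({
    stats::approx(y[x > 0], pos, xout = mid, ties = mean)$y
  }, error = function(e) NA_real_)
  if (!is.finite(c0) || c0 <= 0) c0 <- exp(mean(log(pos)))
  start <- c(a = a0, d = d0, logc = log(c0), b = 1, logg = 0)
  fn <- function(par) {
    p <- list(a = par[["a"]], d = par[["d"]], c = exp(par[["logc"]]),
              b = par[["b"]], g = exp(par[["logg"]]))
    r <- fivepl(x, p) - y
    if (weighting == "cv") r / pmax(abs(fivepl(x, p)), 1e-6) else r
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = fn,
                       lower = c(a = -Inf, d = -Inf, logc = -Inf,
                                 b = 1e-3, logg = log(0.25)),
                       upper = c(a = Inf, d = Inf, logc = Inf,
                                 b = Inf, logg = log(4)),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) {
    stop("5-PL fit did not converge: ",
         if (is.null(fit)) "optimizer error" else fit$message,
         call. = FALSE)
  }
  par <- fit$par
  out <- fivepl_params(a = par[["a"]], d = par[["d"]],
                       c = exp(par[["logc"]]), b = par[["b"]],
                       g = exp(par[["logg"]]))
  attr(out, "residual_sd") <- sqrt(sum((fivepl(x, out) - y)^2) /
                                     max(1, length(y) - 5))
  attr(out, "fitted") <- fivepl(x, out)
  attr(out, "midpoint") <- fivepl_midpoint(out)
  out
}

#' Midpoint concentration of a 5-PL curve
#'
#' Dose at which the response is halfway between the asymptotes,
#' `c * (2^(1/g) - 1)^(1/b)`. Unlike the raw scale parameter `c`, the
#' midpoint is well identified by standard-curve data (it is a functional
#' of the fitted curve, not of the degenerate `c`/`g` pair).
#'
#' @param params A `fivepl_params`.
#' @return Midpoint concentration, pg/mL.
#' @export
fivepl_midpoint <- function(params) {
  p <- unclass(params)
  p$c * (2^(1 / p$g) - 1)^(1 / p$b)
}

#' Invert the 5-PL curve to recover concentrations
#'
#' Closed-form inverse
#' `x = c * (((a - d)/(y - d))^(1/g) - 1)^(1/b)` for responses strictly
#' between the asymptotes. Out-of-range responses are not an error: they
#' return `NA` with a `range_flag` attribute of `"below"` or `"above"`
#' (relative to the dose axis).
#'
#' @param params A `fivepl_params`.
#' @param mfi Measured responses.
#' @return Concentrations (pg/mL) with attribute `range_flag` (character:
#'   `"ok"`, `"below"` or `"above"`).
#' @export
invert_5pl <- function(params, mfi) {
  p <- unclass(params)
  lo <- min(p$a, p$d)
  hi <- max(p$a, p$d)
  increasing <- (p$a < p$d)
  flag <- rep("ok", length(mfi))
  flag[mfi <= lo] <- if (increasing) "below" else "above"
  flag[mfi >= hi] <- if (increasing) "above" else "below"
  x <- rep(NA_real_, length(mfi))
  ok <- flag == "ok"
  if (any(ok)) {
    ratio <- (p$a - p$d) / (mfi[ok] - p$d)
    x[ok] <- p$c * (ratio^(1 / p$g) - 1)^(1 / p$b)
  }
  # a response exactly at the zero-dose asymptote is dose 0, not missing
  x[mfi == p$a] <- 0
  flag[mfi == p$a] <- "ok"
  attr(x, "range_flag") <- flag
  x
}

#' Fold change of treated over control measurements
#'
#' `mean(treated) / mean(control)` with an optional delta-method standard
#' error. Used to express analyte concentrations after a stimulus relative
#' to untreated controls.
#'
#' @param treated,control Numeric vectors of concentrations (same analyte
#'   and channel).
#' @return A list with `fold`, `se` (delta-method; `NA` for n < 2) and the
#'   group sizes.
#' @export
fold_change_vs_control <- function(treated, control) {
  treated <- treated[!is.na(treated)]
  control <- control[!is.na(control)]
  if (!length(treated) || !length(control)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  mc <- mean(control)
  if (mc == 0) {
    return(list(fold = NA_real_, se = NA_real_, flag = "zero_control",
                n_treated = length(treated), n_control = length(control)))
  }
  f <- mean(treated) / mc
  se <- if (length(treated) > 1 && length(control) > 1) {
    abs(f) * sqrt(stats::var(treated) / (length(treated) * mean(treated)^2) +
                    stats::var(control) / (length(control) * mc^2))
  } else NA_real_
  list(fold = f, se = se, flag = "ok",
       n_treated = length(treated), n_control = length(control))
}

#' Comparative-CT (delta-delta-Ct) fold changes
#'
#' Implements the comparative-CT method: per sample,
#' `dCt = Ct(gene) - Ct(reference gene)`; per gene and condition,
#' `ddCt = mean dCt(condition) - mean dCt(reference condition)`; the fold
#' change is `2^-ddCt`. The default aggregation averages `dCt` within a
#' condition before differencing (the condition-mean form); the
#' per-replicate variant computes a `ddCt` for every replicate against the
#' reference-condition mean, which yields the same fold but a usable
#' replicate spread.
#'
#' @param records Data frame with columns `gene`, `condition`, `replicate`,
#'   `ct` and optionally `channel` (readouts are then grouped per channel).
#' @param reference_condition Condition label used as the calibrator.
#' @param reference_gene Housekeeping gene, default `"GAPDH"`.
#' @param method `"condition_mean"` (default) or `"per_replicate"`.
#' @return A tibble with one row per gene x channel x condition:
#'   `n`, `delta_ct_mean`, `delta_ct_sd`, `ddct`, `fold_change`, and
#'   `fold_lo`/`fold_hi` (fold at `ddct +/- delta_ct_sd`).
#' @export
ddct_fold_changes <- function(records, reference_condition,
                              reference_gene = "GAPDH",
                              method = c("condition_mean", "per_replicate")) {
  method <- match.arg(method)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "replicate", "ct")
  if (!all(need %in% names(records))) {
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$channel)) records$channel <- "all"
  if (any(records$ct <= 0 | records$ct > 40)) {
    stop("Ct values must lie in (0, 40]", call. = FALSE)
  }
  if (!reference_condition %in% records$condition) {
    stop("reference condition not present in records", call. = FALSE)
  }
  samp_key <- interaction(records$channel, records$condition,
                          records$replicate, drop = TRUE)
  ref_rows <- records$gene == reference_gene
  ref_ct <- tapply(records$ct[ref_rows], samp_key[ref_rows], mean)
  if (!length(ref_ct) || anyNA(ref_ct) ||
      any(!levels(samp_key) %in% names(ref_ct))) {
    stop("every sample needs a reference-gene (", reference_gene,
         ") measurement", call. = FALSE)
  }
  tab <- records[!ref_rows, ]
  tab$dct <- tab$ct - as.numeric(ref_ct[as.character(
    interaction(tab$channel, tab$condition, tab$replicate, drop = FALSE))])
  key <- interaction(tab$gene, tab$channel, drop = TRUE)
  out <- lapply(split(tab, key), function(g) {
    ref <- g$dct[g$condition == reference_condition]
    if (!length(ref)) return(NULL)
    per_cond <- split(g, g$condition)
    do.call(rbind, lapply(per_cond, function(cc) {
      if (method == "condition_mean") {
        ddct <- mean(cc$dct) - mean(ref)
        spread <- stats::sd(cc$dct)
      } else {
        dd <- cc$dct - mean(ref)
        ddct <- mean(dd)
        spread <- stats::sd(dd)
      }
      data.frame(gene = cc$gene[1], channel = cc$channel[1],
                 condition = cc$condition[1], n = nrow(cc),
                 delta_ct_mean = mean(cc$dct), delta_ct_sd = spread,
                 ddct = ddct, fold_change = 2^(-ddct),
                 fold_lo = 2^(-(ddct + spread)),
                 fold_hi = 2^(-(ddct - spread)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  tibble::as_tibble(out)
}
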