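# Macromolecular (FITC-dextran) permeability assay analysis: linear
# standard curves, the apparent permeability-coefficient estimator, a
# two-compartment forward simulator and plate-level replicate summaries.

#' Timestamped donor/receiver tracer series for one device
#'
#' Concentration time course of a fluorescent tracer in the donor (top) and
#' receiver (bottom) channel loops of a single bilayer device. Times are in
#' minutes from tracer load; concentrations in ug/mL; loop volumes in ul.
#'
#' @param times_min Sampling times, minutes, strictly increasing from 0.
#' @param donor_conc Donor-channel concentrations, ug/mL.
#' @param receiver_conc Receiver-channel concentrations, ug/mL.
#' @param c0 Initial donor concentration applied, ug/mL.
#' @param donor_volume_ul,receiver_volume_ul Recirculating loop volumes, ul.
#'   The default 100 ul lies in the tunable 60-150 ul recirculating range.
#' @param tracer_mw_kda Tracer molecular weight, kDa (tag only).
#' @param device Optional device address string.
#' @return An object of class `tracer_series`.
#' @export
tracer_series <- function(times_min, donor_conc, receiver_conc, c0,
                          donor_volume_ul = 100, receiver_volume_ul = 100,
                          tracer_mw_kda = NA_real_, device = NA_character_) {
  times_min <- as.numeric(times_min)
  if (length(times_min) < 2 || times_min[1] != 0 ||
      any(diff(times_min) <= 0)) {
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  if (length(donor_conc) != length(times_min) ||
      length(receiver_conc) != length(times_min)) {
    stop("donor and receiver series must match the time vector",
         call. = FALSE)
  }
  if (any(donor_conc < 0) || any(receiver_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (!is.finite(c0) || c0 < 0) stop("c0 must be >= 0", call. = FALSE)
  if (donor_volume_ul <= 0 || receiver_volume_ul <= 0) {
    stop("loop volumes must be positive", call. = FALSE)
  }
  structure(list(times_min = times_min,
                 donor_conc = as.numeric(donor_conc),
                 receiver_conc = as.numeric(receiver_conc),
                 c0 = c0,
                 donor_volume_ul = donor_volume_ul,
                 receiver_volume_ul = receiver_volume_ul,
                 tracer_mw_kda = tracer_mw_kda,
                 device = device),
            class = "tracer_series")
}

#' @export
print.tracer_series <- function(x, ...) {
  cat(sprintf("Tracer series (%s kDa, device %s): %d timepoints over %g min\n",
              format(x$tracer_mw_kda), x$device, length(x$times_min),
              max(x$times_min)))
  print(tibble::tibble(time_min = x$times_min, donor = x$donor_conc,
                       receiver = x$receiver_conc))
  invisible(x)
}

# ---- standard curves ----------------------------------------------------

#' Fit a linear fluorescence standard curve
#'
#' Ordinary least-squares line `fluorescence = slope * conc + intercept`,
#' fitted per plate and per tracer molecular weight. FITC-dextran plate
#' reads are linear over the assay range, so a straight line (rather than a
#' logistic) is the appropriate calibration model here.
#'
#' @param known_concs Standard concentrations, ug/mL (>= 3 distinct values).
#' @param readings Fluorescence readings at those concentrations.
#' @return An object of class `standard_curve` with `slope`, `intercept`
#'   and `r_squared`.
#' @export
fit_standard_curve <- function(known_concs, readings) {
  stopifnot(length(known_concs) == length(readings))
  if (length(unique(known_concs)) < 3) {
    stop("need at least 3 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(readings ~ known_concs)
  # direct r2 (summary.lm warns on exact standards, which are legitimate)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((readings - mean(readings))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = length(readings)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: F = %.4g * C + %.4g (r2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Convert plate-reader readings to concentrations
#'
#' Inverts a fitted [fit_standard_curve()]: `(reading - intercept)/slope`.
#' Readings below the blank (fitted intercept) are clipped to 0 and flagged
#' in the `below_blank` attribute. Set `clip = FALSE` to keep signed
#' values - the permeability estimator differences concentrations between
#' timepoints, and clipping the time-zero blank would break the exact
#' cancellation of the fitted intercept in `C(t) - C(t0)`.
#'
#' @param curve A `standard_curve`.
#' @param readings Fluorescence readings.
#' @param clip Clip negative (below-blank) concentrations to 0 (default
#'   TRUE).
#' @return Concentrations in ug/mL, with a logical attribute `below_blank`.
#' @export
readings_to_concentration <- function(curve, readings, clip = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  conc <- (readings - curve$intercept) / curve$slope
  below <- conc < 0
  if (clip) conc[below] <- 0
  attr(conc, "below_blank") <- below
  conc
}

# ---- permeability coefficient ------------------------------------------

#' Apparent permeability coefficient of the barrier
#'
#' Estimates the apparent permeability coefficient from receiver-channel
#' tracer accumulation:
#'
#'   P = (C(t) - C(t0)) * V / (A * t * C0)        (cm/s)
#'
#' where `C(t)` is the receiver concentration at the chosen endpoint
#' (conventionally the final, 260 min sample), `C(t0)` the receiver
#' concentration at time 0, `V` the receiver-loop volume (cm3), `A` the
#' exchange area (cm2), `t` the elapsed time (s) and `C0` the initial donor
#' concentration. The default area is the channel-overlap area (3.7 mm2),
#' the only region where both cell layers separate the compartments; pass
#' the top-channel membrane area (8.5 mm2) to normalise to the full
#' membrane instead.
#'
#' @param series A [tracer_series()].
#' @param area_mm2 Exchange area used for normalisation, mm2.
#' @param t_index Index into `series$times_min` for the endpoint (default:
#'   the final sample).
#' @param culture_mode,treatment Optional condition tags carried through.
#' @return An object of class `permeability_result` with elements
#'   `p_cm_s`, `t_end_s`, `area_cm2`, `device` and the condition tags.
#' @export
permeability_coefficient <- function(series, area_mm2 = 3.7,
                                     t_index = length(series$times_min),
                                     culture_mode = NA_character_,
                                     treatment = NA_character_) {
  stopifnot(inherits(series, "tracer_series"))
  if (t_index < 2 || t_index > length(series$times_min)) {
    stop("t_index must select a sampled time > 0", call. = FALSE)
  }
  t_s <- series$times_min[t_index] * 60
  if (t_s <= 0) stop("endpoint time must be > 0", call. = FALSE)
  if (series$c0 <= 0) {
    stop("initial donor concentration C0 must be > 0", call. = FALSE)
  }
  if (area_mm2 <= 0) stop("area must be positive", call. = FALSE)
  v_cm3 <- series$receiver_volume_ul * 1e-3
  a_cm2 <- area_mm2 * 1e-2
  dC <- series$receiver_conc[t_index] - series$receiver_conc[1]
  p <- dC * v_cm3 / (a_cm2 * t_s * series$c0)
  structure(list(p_cm_s = p, t_end_s = t_s, area_cm2 = a_cm2,
                 device = series$device,
                 tracer_mw_kda = series$tracer_mw_kda,
                 culture_mode = culture_mode, treatment = treatment),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("P = %.3g cm/s (device %s, %s kDa, t = %g min, A = %.3g cm2)\n",
              x$p_cm_s, x$device, format(x$tracer_mw_kda), x$t_end_s / 60,
              x$area_cm2))
  invisible(x)
}

# ---- forward simulator --------------------------------------------------

#' Simulate two-compartment tracer transport across the barrier
#'
#' Forward model for the permeability assay under the well-mixed assumption
#' (feeder flow recirculates both loops during the assay):
#'
#'   dCb/dt = (P A / Vb) (Ct - Cb),   dCt/dt = -(P A / Vt) (Ct - Cb)
#'
#' Integrated exactly (the system is linear): the concentration difference
#' decays as `exp(-P A (1/Vt + 1/Vb) t)` while total mass is conserved, so
#' with equal loop volumes both compartments approach `C0 / 2` - e.g.
#' 25 ug/mL for a 50 ug/mL load. Optional sampling events remove
#' `sampling_volume_ul` of mixed fluid from each loop at every sampled time
#' after 0 and replace it with blank medium (concentrations scale by
#' `(V - s)/V`; removed mass is tracked in the `sampled_mass_ug` attribute).
#' Optional multiplicative Gaussian reading noise is applied to the
#' reported (not the state) concentrations.
#'
#' @param p_cm_s True permeability coefficient, cm/s.
#' @param area_mm2 Exchange area, mm2.
#' @param v_top_ul,v_bottom_ul Donor and receiver loop volumes, ul.
#' @param c0 Initial donor concentration, ug/mL.
#' @param times_min Sampling times, minutes, starting at 0.
#' @param sampling_volume_ul Volume withdrawn from each loop per sampling
#'   event, ul (0 disables sampling corrections).
#' @param noise_cv Coefficient of variation of reading noise (0 = noiseless).
#' @param seed Optional seed for the reading noise.
#' @param tracer_mw_kda,device Tags carried into the returned series.
#' @return A [tracer_series()] of sampled concentrations.
#' @export
simulate_two_compartment <- function(p_cm_s, area_mm2 = 3.7,
                                     v_top_ul = 100, v_bottom_ul = 100,
                                     c0 = 50,
                                     times_min = c(0, 20, 40, 60, 120, 260),
                                     sampling_volume_ul = 0,
                                     noise_cv = 0, seed = NULL,
                                     tracer_mw_kda = NA_real_,
                                     device = NA_character_) {
  if (p_cm_s < 0 || area_mm2 <= 0 || v_top_ul <= 0 || v_bottom_ul <= 0 ||
      c0 < 0 || sampling_volume_ul < 0 || noise_cv < 0) {
    stop("simulation parameters must be non-negative (volumes/area positive)",
         call. = FALSE)
  }
  if (sampling_volume_ul >= min(v_top_ul, v_bottom_ul)) {
    stop("sampling volume must be smaller than the loop volume",
         call. = FALSE)
  }
  times_min <- as.numeric(times_min)
  a_cm2 <- area_mm2 * 1e-2
  vt <- v_top_ul * 1e-3  # cm3
  vb <- v_bottom_ul * 1e-3
  k <- p_cm_s * a_cm2 * (1 / vt + 1 / vb)  # 1/s
  ct <- c0
  cb <- 0
  sampled_mass <- 0
  out_t <- out_b <- numeric(length(times_min))
  for (i in seq_along(times_min)) {
    if (i > 1) {
      dt_s <- (times_min[i] - times_min[i - 1]) * 60
      ceq <- (vt * ct + vb * cb) / (vt + vb)
      d <- (ct - cb) * exp(-k * dt_s)
      ct <- ceq + d * vb / (vt + vb)
      cb <- ceq - d * vt / (vt + vb)
    }
    out_t[i] <- ct
    out_b[i] <- cb
    if (sampling_volume_ul > 0) {
      s <- sampling_volume_ul * 1e-3
      sampled_mass <- sampled_mass + s * (ct + cb)
      ct <- ct * (vt - s) / vt
      cb <- cb * (vb - s) / vb
    }
  }
  if (noise_cv > 0) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    out_t <- pmax(0, out_t * (1 + stats::rnorm(length(out_t), 0, noise_cv)))
    out_b <- pmax(0, out_b * (1 + stats::rnorm(length(out_b), 0, noise_cv)))
  }
  ser <- tracer_series(times_min, out_t, out_b, c0,
                       donor_volume_ul = v_top_ul,
                       receiver_volume_ul = v_bottom_ul,
                       tracer_mw_kda = tracer_mw_kda, device = device)
  attr(ser, "sampled_mass_ug") <- sampled_mass
  ser
}

# save/restore the RNG state so seeded helpers do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- plate-level report -------------------------------------------------

#' Summarise permeability results per condition and as a plate table
#'
#' Groups `permeability_result`s by condition (from the plate map if
#' given, else from the result tags), reports mean +/- SD and the max/min
#' replicate ratio with a consistency flag (replicates within one order of
#' magnitude pass), and lays the coefficients out as an 8x12 plate matrix
#' for export.
#'
#' @param results List of [permeability_coefficient()] results.
#' @param pm Optional `plate_map`; conditions are then taken from it by
#'   device address.
#' @param max_ratio Replicate max/min ratio above which a condition is
#'   flagged (default 10, i.e. one order of magnitude).
#' @return A list with `summary` (tibble: condition, n, mean, sd, ratio,
#'   consistent) and `plate` (8x12 matrix of P in cm/s, NA where absent).
#' @export
plate_permeability_report <- function(results, pm = NULL, max_ratio = 10) {
  stopifnot(length(results) >= 1)
  dev <- vapply(results, function(r) as.character(r$device), character(1))
  p <- vapply(results, function(r) r$p_cm_s, numeric(1))
  mw <- vapply(results, function(r) as.numeric(r$tracer_mw_kda), numeric(1))
  if (!is.null(pm)) {
    stopifnot(inherits(pm, "plate_map"))
    idx <- match(dev, pm$device)
    cond <- condition_label(pm[idx, ])
  } else {
    cond <- vapply(results, function(r) {
      paste(stats::na.omit(c(r$culture_mode, r$treatment)), collapse = "+")
    }, character(1))
    cond[cond == ""] <- "unlabelled"
  }
  cond <- paste0(cond, ifelse(is.na(mw), "", paste0("/", mw, "kDa")))
  keep <- !is.na(p)
  if (!all(keep)) warning("dropping results with missing coefficients")
  tab <- tibble::tibble(condition = cond[keep], p_cm_s = p[keep])
  groups <- split(tab$p_cm_s, tab$condition)
  summary <- tibble::tibble(
    condition = names(groups),
    n = unname(vapply(groups, length, integer(1))),
    mean_p_cm_s = unname(vapply(groups, mean, numeric(1))),
    sd_p_cm_s = unname(vapply(groups, function(g)
      if (length(g) > 1) stats::sd(g) else NA_real_, numeric(1))),
    replicate_ratio = unname(vapply(groups, function(g) {
      if (min(g) <= 0) Inf else max(g) / min(g)
    }, numeric(1)))
  )
  summary$consistent <- summary$replicate_ratio <= max_ratio
  plate <- matrix(NA_real_, nrow = 8, ncol = 12,
                  dimnames = list(DEVICE_ROWS, 1:12))
  for (i in seq_along(results)) {
    d <- dev[i]
    if (!is.na(d) && d %in% device_addresses()) {
      a <- device_address(d)
      plate[a$row, a$col] <- p[i]
    }
  }
  list(summary = summary, plate = plate)
}
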