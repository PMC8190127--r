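# Seeded generators for plate-reader, immunoassay and qPCR tables with
# exact ground truth, plus the table-driven permeability pipeline that
# closes the loop from raw fluorescence exports to coefficients.

#' One-way (linear-flux) receiver accumulation series
#'
#' Generates the donor/receiver series implied by the permeability
#' estimator's own model: a constant donor at `C0` and linear receiver
#' accumulation `C_b(t) = P A t C0 / V`. The estimator re-recovers `P`
#' exactly from such a series for every `P`, `A`, `V`, `C0` and endpoint.
#'
#' @inheritParams simulate_two_compartment
#' @param receiver_volume_ul Receiver loop volume, ul.
#' @return A [tracer_series()].
#' @export
linear_flux_series <- function(p_cm_s, area_mm2 = 3.7,
                               receiver_volume_ul = 100, c0 = 50,
                               times_min = c(0, 20, 40, 60, 120, 260),
                               tracer_mw_kda = NA_real_,
                               device = NA_character_) {
  a_cm2 <- area_mm2 * 1e-2
  v_cm3 <- receiver_volume_ul * 1e-3
  t_s <- times_min * 60
  cb <- p_cm_s * a_cm2 * t_s * c0 / v_cm3
  tracer_series(times_min, rep(c0, length(times_min)), cb, c0,
                donor_volume_ul = receiver_volume_ul,
                receiver_volume_ul = receiver_volume_ul,
                tracer_mw_kda = tracer_mw_kda, device = device)
}

#' Describe a synthetic permeability-assay scenario
#'
#' Defaults reproduce the study design: 50 ug/mL tracer load, sampling at
#' 0/20/40/60/120/260 min, 9 technical replicates per condition (within
#' the 8-10 used on plate), 2 percent reading noise, and true
#' coefficients matching the reported condition means for 20 and 70 kDa
#' tracer in mono- and co-culture plus the barrier-disrupted co-culture.
#'
#' @param conditions Data frame with columns `condition`, `tracer_mw_kda`,
#'   `p_cm_s` (true coefficient).
#' @param n_replicates Technical replicates per condition.
#' @param c0 Tracer load, ug/mL.
#' @param times_min Sampling times, minutes.
#' @param area_mm2 Exchange area used by the forward model, mm2.
#' @param volume_ul Recirculating loop volume per channel, ul.
#' @param noise_cv Reading noise CV.
#' @param curve_slope,curve_intercept Truth for the linear fluorescence
#'   standard curve (AFU per ug/mL; AFU).
#' @param standard_concs Standard concentrations, ug/mL.
#' @param transport_model `"one_way"` (matches the estimator's model;
#'   default) or `"two_compartment"` (bidirectional simulator).
#' @return An object of class `tracer_assay_scenario`.
#' @export
tracer_assay_scenario <- function(
    conditions = data.frame(
      condition = c("co", "mono", "co", "mono", "co+CB"),
      tracer_mw_kda = c(20, 20, 70, 70, 20),
      p_cm_s = c(3.9e-6, 1.0e-5, 1.5e-6, 6.8e-6, 1.3e-5)),
    n_replicates = 9, c0 = 50,
    times_min = c(0, 20, 40, 60, 120, 260),
    area_mm2 = 3.7, volume_ul = 100, noise_cv = 0.02,
    curve_slope = 180, curve_intercept = 60,
    standard_concs = c(0, 0.78125, 1.5625, 3.125, 6.25, 12.5, 25, 50),
    transport_model = c("one_way", "two_compartment")) {
  transport_model <- match.arg(transport_model)
  stopifnot(all(c("condition", "tracer_mw_kda", "p_cm_s") %in%
                  names(conditions)))
  structure(list(conditions = conditions, n_replicates = n_replicates,
                 c0 = c0, times_min = times_min, area_mm2 = area_mm2,
                 volume_ul = volume_ul, noise_cv = noise_cv,
                 curve_slope = curve_slope,
                 curve_intercept = curve_intercept,
                 standard_concs = standard_concs,
                 transport_model = transport_model),
            class = "tracer_assay_scenario")
}

#' Generate plate-reader and standards tables for a permeability assay
#'
#' Forward-simulates every replicate of every condition, converts
#' concentrations to fluorescence through the true linear standard curve,
#' applies seeded multiplicative reading noise, and emits tidy tables plus
#' the exact ground truth.
#'
#' @param scenario A [tracer_assay_scenario()].
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `reads.csv` and
#'   `standards.csv` are written there.
#' @return A list with `readings` (tibble: device, condition,
#'   tracer_mw_kda, channel, time_min, fluorescence), `standards` (tibble:
#'   tracer_mw_kda, conc_ug_ml, fluorescence) and `truth` (true
#'   coefficients per device and curve parameters).
#' @export
gen_tracer_readings <- function(scenario = tracer_assay_scenario(),
                                seed = 1L, dir = NULL) {
  stopifnot(inherits(scenario, "tracer_assay_scenario"))
  s <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  devices <- device_addresses()
  rows <- list()
  truth_rows <- list()
  di <- 0L
  for (i in seq_len(nrow(s$conditions))) {
    for (rep_i in seq_len(s$n_replicates)) {
      di <- di + 1L
      if (di > length(devices)) stop("more replicates than devices",
                                     call. = FALSE)
      dev <- devices[di]
      p <- s$conditions$p_cm_s[i]
      ser <- if (s$transport_model == "one_way") {
        linear_flux_series(p, s$area_mm2, s$volume_ul, s$c0, s$times_min,
                           tracer_mw_kda = s$conditions$tracer_mw_kda[i],
                           device = dev)
      } else {
        simulate_two_compartment(p, s$area_mm2, s$volume_ul, s$volume_ul,
                                 s$c0, s$times_min,
                                 tracer_mw_kda =
                                   s$conditions$tracer_mw_kda[i],
                                 device = dev)
      }
      for (ch in c("top", "bottom")) {
        conc <- if (ch == "top") ser$donor_conc else ser$receiver_conc
        f <- s$curve_intercept + s$curve_slope * conc
        if (s$noise_cv > 0) {
          f <- f * (1 + stats::rnorm(length(f), 0, s$noise_cv))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          device = dev, condition = s$conditions$condition[i],
          tracer_mw_kda = s$conditions$tracer_mw_kda[i], channel = ch,
          time_min = s$times_min, fluorescence = f)
      }
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        device = dev, condition = s$conditions$condition[i],
        tracer_mw_kda = s$conditions$tracer_mw_kda[i], p_cm_s = p)
    }
  }
  standards <- do.call(rbind, lapply(unique(s$conditions$tracer_mw_kda),
                                     function(mw) {
    f <- s$curve_intercept + s$curve_slope * s$standard_concs
    if (s$noise_cv > 0) {
      f <- f * (1 + stats::rnorm(length(f), 0, s$noise_cv))
    }
    tibble::tibble(tracer_mw_kda = mw, conc_ug_ml = s$standard_concs,
                   fluorescence = f)
  }))
  readings <- do.call(rbind, rows)
  out <- list(readings = readings, standards = standards,
              truth = list(devices = do.call(rbind, truth_rows),
                           curve_slope = s$curve_slope,
                           curve_intercept = s$curve_intercept,
                           scenario = s))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(readings, file.path(dir, "reads.csv"),
                     row.names = FALSE)
    utils::write.csv(standards, file.path(dir, "standards.csv"),
                     row.names = FALSE)
  }
  out
}

#' Estimate permeability coefficients from plate-reader tables
#'
#' The full analysis path from raw fluorescence exports: fit a linear
#' standard curve per tracer molecular weight, convert readings to
#' concentrations, assemble each device's receiver time course and apply
#' the endpoint permeability estimator.
#'
#' @param readings Tibble as produced by [gen_tracer_readings()] (columns
#'   `device`, `condition`, `tracer_mw_kda`, `channel`, `time_min`,
#'   `fluorescence`).
#' @param standards Tibble with `tracer_mw_kda`, `conc_ug_ml`,
#'   `fluorescence`.
#' @param area_mm2 Exchange area for the estimator, mm2.
#' @param volume_ul Receiver loop volume, ul.
#' @param c0 Initial donor concentration, ug/mL.
#' @return Tibble: `device`, `condition`, `tracer_mw_kda`, `p_cm_s`.
#' @export
permeability_from_readings <- function(readings, standards,
                                       area_mm2 = 3.7, volume_ul = 100,
                                       c0 = 50) {
  curves <- lapply(split(standards, standards$tracer_mw_kda), function(st)
    fit_standard_curve(st$conc_ug_ml, st$fluorescence))
  keys <- unique(readings[, c("device", "condition", "tracer_mw_kda")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- readings[readings$device == keys$device[i] &
                      readings$tracer_mw_kda == keys$tracer_mw_kda[i], ]
    curve <- curves[[as.character(keys$tracer_mw_kda[i])]]
    bot <- sub[sub$channel == "bottom", ]
    top <- sub[sub$channel == "top", ]
    bot <- bot[order(bot$time_min), ]
    top <- top[order(top$time_min), ]
    # keep signed concentrations so the fitted-intercept error cancels in
    # the C(t) - C(t0) difference; shift the series origin to zero only to
    # satisfy the non-negativity contract of the container
    top_conc <- readings_to_concentration(curve, top$fluorescence,
                                          clip = FALSE)
    bot_conc <- readings_to_concentration(curve, bot$fluorescence,
                                          clip = FALSE)
    shift <- min(0, top_conc, bot_conc)
    ser <- tracer_series(
      bot$time_min,
      as.numeric(top_conc - shift),
      as.numeric(bot_conc - shift),
      c0 = c0, donor_volume_ul = volume_ul,
      receiver_volume_ul = volume_ul,
      tracer_mw_kda = keys$tracer_mw_kda[i], device = keys$device[i])
    permeability_coefficient(ser, area_mm2 = area_mm2)$p_cm_s
  })
  tibble::tibble(device = keys$device, condition = keys$condition,
                 tracer_mw_kda = keys$tracer_mw_kda,
                 p_cm_s = unlist(res))
}

# ---- molecular tables ---------------------------------------------------

#' Describe a synthetic molecular-readout scenario
#'
#' Emulates channel-specific molecular designs: a 12-plex immunoassay
#' panel read against 5-PL standard curves, and a qPCR panel with a
#' housekeeping reference gene, channel-specific enrichment of endothelial
#' vs mural-cell transcripts, and condition effects.
#'
#' @param analytes Analyte names for the immunoassay panel.
#' @param fivepl_truth A `fivepl_params` shared shape for the standards
#'   (the scale `c` is jittered per analyte, seeded).
#' @param standard_concs Immunoassay standard concentrations, pg/mL
#'   (0 = blank).
#' @param base_conc_pg_ml Baseline analyte concentration in samples.
#' @param treatment_effects Named fold changes applied to treated samples
#'   (analyte -> fold).
#' @param mfi_cv Immunoassay reading CV (default 0.05).
#' @param genes qPCR panel (excluding the reference gene).
#' @param ec_genes,pc_genes Genes enriched in the top (endothelial) or
#'   bottom (mural) channel.
#' @param channel_enrichment Fold enrichment of cell-type transcripts in
#'   their own channel (default 100).
#' @param condition_effects Named fold changes on expression in the
#'   treated condition (gene -> fold, applied in the top channel).
#' @param base_ct Baseline target-gene Ct; `reference_ct` for the
#'   housekeeping gene.
#' @param reference_gene,reference_ct Housekeeping gene and its Ct.
#' @param ct_sd Replicate SD of Ct values, cycles.
#' @param n_replicates Biological replicates per condition (default 3).
#' @return An object of class `molecular_scenario`.
#' @export
molecular_scenario <- function(
    analytes = c("CCL2", "CX3CL1", "G-CSF", "GM-CSF", "IL-6", "IL-8",
                 "IL-10", "IL-13", "IL-33", "PDGF-AA", "PDGF-BB", "VEGF"),
    fivepl_truth = fivepl_params(a = 50, d = 28000, c = 400, b = 1.1,
                                 g = 1.3),
    standard_concs = c(0, 10000 / 4^(6:0)),
    base_conc_pg_ml = 150,
    treatment_effects = c("IL-6" = 4, "G-CSF" = 3, "CX3CL1" = 2.5),
    mfi_cv = 0.05,
    genes = c("KLF2", "NOS3", "PECAM1", "CDH5", "IL6", "CSPG4", "PDGFRB"),
    ec_genes = c("KLF2", "NOS3", "PECAM1", "CDH5"),
    pc_genes = c("CSPG4", "PDGFRB"),
    channel_enrichment = 100,
    condition_effects = c("IL6" = 2.5, "CDH5" = 0.5),
    base_ct = 26, reference_gene = "GAPDH", reference_ct = 18,
    ct_sd = 0.15, n_replicates = 3) {
  structure(list(analytes = analytes, fivepl_truth = fivepl_truth,
                 standard_concs = standard_concs,
                 base_conc_pg_ml = base_conc_pg_ml,
                 treatment_effects = treatment_effects, mfi_cv = mfi_cv,
                 genes = genes, ec_genes = ec_genes, pc_genes = pc_genes,
                 channel_enrichment = channel_enrichment,
                 condition_effects = condition_effects, base_ct = base_ct,
                 reference_gene = reference_gene,
                 reference_ct = reference_ct, ct_sd = ct_sd,
                 n_replicates = n_replicates),
            class = "molecular_scenario")
}

#' Generate immunoassay and qPCR tables with ground truth
#'
#' Immunoassay MFIs are drawn from per-analyte 5-PL truth curves with CV
#' noise for both standards and samples (conditions `control` and
#' `treated`, channels `top` and `bottom`). Ct tables carry the
#' housekeeping reference, channel-specific enrichment of cell-type
#' transcripts and condition effects, with Gaussian replicate noise.
#'
#' @param scenario A [molecular_scenario()].
#' @param seed Integer seed.
#' @param dir Optional directory; writes `immunoassay.csv` and `qpcr.csv`.
#' @return A list with `immunoassay` (tibble: analyte, type, channel,
#'   condition, replicate, expected_conc, mfi), `qpcr` (tibble: gene,
#'   channel, condition, replicate, ct) and `truth` (per-analyte curve
#'   params and true concentrations/folds, per-gene true enrichment and
#'   condition folds).
#' @export
gen_molecular_tables <- function(scenario = molecular_scenario(),
                                 seed = 1L, dir = NULL) {
  stopifnot(inherits(scenario, "molecular_scenario"))
  s <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # per-analyte truth curves: shared shape, seeded scale jitter
  curves <- lapply(seq_along(s$analytes), function(i) {
    p <- unclass(s$fivepl_truth)
    p$c <- p$c * exp(stats::runif(1, -0.7, 0.7))
    do.call(fivepl_params, p)
  })
  names(curves) <- s$analytes

  imm <- list()
  true_conc <- list()
  for (an in s$analytes) {
    cur <- curves[[an]]
    mfi_std <- fivepl(s$standard_concs, cur)
    mfi_std <- mfi_std * (1 + stats::rnorm(length(mfi_std), 0, s$mfi_cv))
    imm[[length(imm) + 1L]] <- tibble::tibble(
      analyte = an, type = "standard", channel = NA_character_,
      condition = NA_character_, replicate = NA_integer_,
      expected_conc = s$standard_concs, mfi = mfi_std)
    for (ch in c("top", "bottom")) {
      for (cond in c("control", "treated")) {
        eff <- if (cond == "treated" && an %in% names(s$treatment_effects))
          s$treatment_effects[[an]] else 1
        # treatment acts on the stimulated (top, endothelial) channel
        if (ch == "bottom") eff <- 1 + (eff - 1) * 0.25
        conc <- s$base_conc_pg_ml * eff
        mfi <- fivepl(rep(conc, s$n_replicates), cur) *
          (1 + stats::rnorm(s$n_replicates, 0, s$mfi_cv))
        imm[[length(imm) + 1L]] <- tibble::tibble(
          analyte = an, type = "sample", channel = ch, condition = cond,
          replicate = seq_len(s$n_replicates),
          expected_conc = NA_real_, mfi = mfi)
        true_conc[[length(true_conc) + 1L]] <- tibble::tibble(
          analyte = an, channel = ch, condition = cond, conc_pg_ml = conc)
      }
    }
  }
  immunoassay <- do.call(rbind, imm)
  true_conc <- do.call(rbind, true_conc)

  qp <- list()
  enr_truth <- list()
  half_log2_enr <- log2(s$channel_enrichment) / 2
  for (gene in c(s$genes, s$reference_gene)) {
    is_ref <- gene == s$reference_gene
    base <- if (is_ref) s$reference_ct else s$base_ct
    for (ch in c("top", "bottom")) {
      delta <- 0
      if (!is_ref) {
        if (gene %in% s$ec_genes) {
          delta <- if (ch == "top") -half_log2_enr else half_log2_enr
        } else if (gene %in% s$pc_genes) {
          delta <- if (ch == "bottom") -half_log2_enr else half_log2_enr
        }
      }
      for (cond in c("control", "treated")) {
        cond_fold <- if (!is_ref && cond == "treated" && ch == "top" &&
                         gene %in% names(s$condition_effects))
          s$condition_effects[[gene]] else 1
        ct_mean <- base + delta - log2(cond_fold)
        qp[[length(qp) + 1L]] <- tibble::tibble(
          gene = gene, channel = ch, condition = cond,
          replicate = seq_len(s$n_replicates),
          ct = ct_mean + stats::rnorm(s$n_replicates, 0, s$ct_sd))
      }
      if (!is_ref) {
        enr_truth[[length(enr_truth) + 1L]] <- tibble::tibble(
          gene = gene, channel = ch,
          enrichment_fold = 2^(-2 * (if (gene %in% s$ec_genes &&
                                         ch == "top") -half_log2_enr
                                     else if (gene %in% s$pc_genes &&
                                              ch == "bottom") -half_log2_enr
                                     else if (gene %in% c(s$ec_genes,
                                                          s$pc_genes))
                                       half_log2_enr else 0)) / 1)
      }
    }
  }
  qpcr <- do.call(rbind, qp)
  out <- list(immunoassay = immunoassay, qpcr = qpcr,
              truth = list(curves = curves, concentrations = true_conc,
                           treatment_effects = s$treatment_effects,
                           channel_enrichment = s$channel_enrichment,
                           condition_effects = s$condition_effects))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(immunoassay, file.path(dir, "immunoassay.csv"),
                     row.names = FALSE)
    utils::write.csv(qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE)
  }
  out
}
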