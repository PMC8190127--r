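# Image pipeline for device tiles: clean channel-edge artifacts, isolate
# the channel-overlap region by connected components, and quantify EC
# coverage, nucleus counts and viability inside it.

#' Multi-channel fluorescence image of one device tile
#'
#' Named single-precision rasters (values in `[0, 1]`) for the stains of
#' one device's channel-overlap tile. Channels are named roles, not
#' colours: `nuclei` (DNA stain), `ec_marker` (endothelial junction stain),
#' and optionally `actin`, `live`, `dead`.
#'
#' @param channels Named list of numeric matrices, all the same dimension.
#' @param pixel_size_um Physical pixel size, um/px.
#' @param device Optional device address string.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, pixel_size_um, device = NA_character_) {
  if (!length(channels) || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("channels must be a named list of matrices", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  if (any(!vapply(channels, is.matrix, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must be matrices of identical dimensions",
         call. = FALSE)
  }
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be positive", call. = FALSE)
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 device = device),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Device tile %s: %d x %d px at %.3g um/px; channels: %s\n",
              x$device, d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# histogram Otsu threshold on a vector of intensities in [0, 1]
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (!length(v) || max(v) == min(v)) return(Inf)
  h <- tabulate(pmin(levels, 1L + floor(v * levels)), nbins = levels)
  w <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# robust scale of a vector (median absolute deviation, normal-consistent)
robust_spread <- function(v) stats::mad(v, constant = 1.4826)

# Decide whether an automatic (Otsu) threshold of `v` reflects a genuine
# foreground/background split. Returns the threshold plus a status:
#   "none"      - the two classes are separated by less than `min_ratio`
#                 times their internal spreads (pure background/noise);
#   "split"     - a clean bimodal split (the histogram valley at the
#                 threshold is nearly empty relative to the class peaks);
#   "saturated" - real structure but no empty valley, i.e. the region is
#                 uniformly foreground and the split divides foreground
#                 texture, not foreground from background.
.auto_threshold_state <- function(v, min_ratio = 3, valley_frac = 0.25,
                                  bins = 64L) {
  # pixels zeroed by edge cleaning are invalid, not dark: drop them so
  # they cannot fabricate a background class
  v <- v[v > 0]
  if (length(v) < 2 || max(v) == min(v)) {
    return(list(threshold = Inf, status = "none"))
  }
  thr <- otsu_threshold(v)
  lo <- v[v <= thr]
  hi <- v[v > thr]
  if (!length(lo) || !length(hi)) {
    return(list(threshold = thr, status = "none"))
  }
  gap <- mean(hi) - mean(lo)
  spread <- robust_spread(lo) + robust_spread(hi)
  if (spread == 0) spread <- stats::sd(v)
  if (!is.finite(gap / spread) || gap / spread < min_ratio) {
    return(list(threshold = thr, status = "none"))
  }
  rng <- range(v)
  h <- tabulate(pmin(bins, 1L + floor((v - rng[1]) / diff(rng) * bins)),
                nbins = bins)
  tb <- min(bins, 1L + floor((thr - rng[1]) / diff(rng) * bins))
  valley <- mean(h[max(1L, tb - 1L):min(bins, tb + 1L)])
  peak_lo <- max(h[seq_len(max(1L, tb - 2L))])
  peak_hi <- max(h[min(bins, tb + 2L):bins])
  status <- if (valley <= valley_frac * min(peak_lo, peak_hi)) "split" else
    "saturated"
  list(threshold = thr, status = status)
}

#' Suppress bright channel-edge artifacts
#'
#' The laser-cut channel walls leave bright ridge artifacts along every
#' channel boundary in the junction-stain (green) channel. They are
#' detected from the brightness difference between the `ec_marker` and
#' `nuclei` channels: a pixel is an edge artifact when
#' `ec_marker - nuclei` is anomalously large. Candidate pixels exceed `k`
#' times the robust spread (MAD) of that difference over the tile; the
#' candidates are then split into two brightness classes (automatic
#' histogram threshold) and the upper class is suppressed only when the
#' two classes are well separated relative to the tile's dynamic range -
#' wall ridges saturate the junction channel far above any junctional
#' staining, whereas on artifact-free tiles the candidate set is just the
#' brightest cellular signal, the separation test fails, and the tile
#' passes through untouched. The whole decision is scale-free: rescaling
#' the intensities leaves the suppressed set unchanged. Flagged pixels are zeroed in every channel, which also severs
#' the thin bright seams that would otherwise connect the overlap region
#' to the flanking channel segments during component analysis.
#'
#' @param img A [multichannel_image()] with `nuclei` and `ec_marker`
#'   channels.
#' @param k Multiple of the robust background spread defining candidate
#'   pixels (default 6).
#' @param min_rel_gap Minimum separation between the two candidate
#'   classes, as a fraction of the tile's brightness-difference range,
#'   for the upper class to count as wall ridge (default 0.4).
#' @return The cleaned `multichannel_image`; the number of suppressed
#'   pixels is in the `n_suppressed` attribute.
#' @export
clean_channel_edges <- function(img, k = 6, min_rel_gap = 0.4) {
  stopifnot(inherits(img, "multichannel_image"))
  if (!all(c("nuclei", "ec_marker") %in% names(img$channels))) {
    stop("clean_channel_edges needs 'nuclei' and 'ec_marker' channels",
         call. = FALSE)
  }
  g <- img$channels$ec_marker
  b <- img$channels$nuclei
  d <- g - b
  med <- stats::median(d)
  cand <- d > med + k * robust_spread(d)
  edge <- FALSE & cand
  if (any(cand)) {
    v <- d[cand]
    rng <- range(v)
    if (diff(rng) > .Machine$double.eps^0.5) {
      vn <- (v - rng[1]) / diff(rng)
      cut <- otsu_threshold(vn)
      upper <- vn > cut
      if (any(upper) && !all(upper)) {
        gap <- mean(v[upper]) - mean(v[!upper])
        if (gap / (max(d) - med) >= min_rel_gap) {
          edge <- cand & (d > rng[1] + cut * diff(rng))
        }
      }
    }
  }
  if (any(edge)) {
    img$channels <- lapply(img$channels, function(ch) {
      ch[edge] <- 0
      ch
    })
  }
  attr(img, "n_suppressed") <- sum(edge)
  img
}

#' Binary mask of the channel-overlap region
#'
#' Thresholds the combined (`nuclei` + `ec_marker`) brightness of a
#' cleaned tile, labels connected components, and applies a series of
#' decisions to discard everything but the channel overlap: components
#' hugging the tile border (more than `border_frac` of their pixels within
#' `border_margin_px` of an edge) are dropped, as are components whose
#' area falls outside `expected_area_mm2 * (1 +/- area_tol)`; among the
#' survivors the component nearest the image centre is kept, morphologically
#' closed and hole-filled. If the Otsu threshold lands above the in-channel
#' background (it then selects only the cells), a half-threshold retry
#' recovers the full region. Finally the mask must contain detectable cell
#' signal (upper-quantile contrast above `min_cell_contrast`), otherwise a
#' "no cells detected" error is raised - this is what marks blank devices
#' ND in plate reports.
#'
#' @param img A cleaned [multichannel_image()].
#' @param expected_area_mm2 Expected overlap area (default 3.7 mm2).
#' @param area_tol Relative half-width of the accepted area band
#'   (default 0.4, i.e. +/- 40 percent).
#' @param border_frac Maximum fraction of component pixels allowed near the
#'   tile border (default 0.3).
#' @param border_margin_px Width of the border zone, px.
#' @param closing_um Radius of the morphological closing, um.
#' @param min_cell_contrast Minimum (99th percentile - median) combined
#'   brightness within the mask for the region to count as cell-bearing.
#' @return An object of class `overlap_mask`: list with `mask` (logical
#'   matrix), `area_px`, `area_mm2`, `threshold`.
#' @export
extract_overlap_mask <- function(img, expected_area_mm2 = 3.7,
                                 area_tol = 0.4, border_frac = 0.3,
                                 border_margin_px = 3, closing_um = 40,
                                 min_cell_contrast = 0.12) {
  stopifnot(inherits(img, "multichannel_image"))
  if (!all(c("nuclei", "ec_marker") %in% names(img$channels))) {
    stop("mask extraction needs 'nuclei' and 'ec_marker' channels",
         call. = FALSE)
  }
  combined <- img$channels$nuclei + img$channels$ec_marker
  combined <- pmin(combined, 1)
  px_mm2 <- (img$pixel_size_um / 1000)^2
  band <- expected_area_mm2 * c(1 - area_tol, 1 + area_tol)
  t0 <- otsu_threshold(combined)
  chosen <- NULL
  for (thr in c(t0, t0 / 2)) {
    cand <- .select_overlap_component(combined > thr, band / px_mm2,
                                      border_frac, border_margin_px)
    if (!is.null(cand)) {
      chosen <- cand
      threshold <- thr
      break
    }
  }
  if (is.null(chosen)) {
    stop("no cells detected: no component matches the expected overlap area",
         call. = FALSE)
  }
  r_px <- max(1L, round(closing_um / img$pixel_size_um))
  kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  m <- EBImage::closing(chosen * 1, kern)
  m <- EBImage::fillHull(m)
  mask <- m > 0
  # cell-content check: a blank (cell-free) device still shows the channel
  # autofluorescence rectangle, but no punctate cell signal above it.
  # Evaluated on the eroded interior so residual wall brightness at the
  # mask rim cannot masquerade as cells.
  er <- EBImage::makeBrush(21L, shape = "disc")
  interior <- EBImage::erode(mask * 1, er) > 0
  if (!any(interior)) interior <- mask
  vals <- combined[interior]
  contrast <- stats::quantile(vals, 0.99, names = FALSE) -
    stats::median(vals)
  if (contrast < min_cell_contrast) {
    stop("no cells detected: overlap region lacks cell signal",
         call. = FALSE)
  }
  structure(list(mask = mask, area_px = sum(mask),
                 area_mm2 = sum(mask) * px_mm2,
                 threshold = threshold, cell_contrast = contrast),
            class = "overlap_mask")
}

# label a binary image and pick the component passing the overlap decisions
.select_overlap_component <- function(bw, area_band_px, border_frac,
                                      border_margin_px) {
  lab <- EBImage::bwlabel(bw * 1)
  nlab <- max(lab)
  if (nlab == 0) return(NULL)
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  nr <- nrow(bw); nc <- ncol(bw)
  m <- border_margin_px
  border_zone <- matrix(FALSE, nr, nc)
  border_zone[c(seq_len(m), nr - seq_len(m) + 1L), ] <- TRUE
  border_zone[, c(seq_len(m), nc - seq_len(m) + 1L)] <- TRUE
  border_counts <- tabulate(lab[border_zone & lab > 0], nbins = nlab)
  ok <- areas >= area_band_px[1] & areas <= area_band_px[2] &
    (border_counts / areas) <= border_frac
  if (!any(ok)) return(NULL)
  if (sum(ok) > 1) {
    # keep the survivor nearest the image centroid
    ctr <- c(nr, nc) / 2
    d2 <- vapply(which(ok), function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      sum((colMeans(idx) - ctr)^2)
    }, numeric(1))
    keep <- which(ok)[which.min(d2)]
  } else {
    keep <- which(ok)
  }
  lab == keep
}

#' @export
print.overlap_mask <- function(x, ...) {
  cat(sprintf("Overlap mask: %d px (%.3g mm2), threshold %.3g\n",
              x$area_px, x$area_mm2, x$threshold))
  invisible(x)
}

#' Endothelial coverage fraction within the overlap region
#'
#' Thresholds the junction-stain channel within the overlap mask
#' (automatic histogram threshold by default) and reports the positive
#' fraction of mask pixels. The threshold is computed differently for
#' mono- and co-cultures: in mono-culture the junctional stain is weaker,
#' so nuclear objects are segmented, dilated (to bridge the gap between
#' each nucleus and the cell-border stain) and unioned with the thresholded
#' junction channel before counting positive pixels.
#'
#' @param img A cleaned [multichannel_image()].
#' @param mask An [extract_overlap_mask()] result (or a logical matrix).
#' @param culture_mode `"co"` or `"mono"`.
#' @param threshold_method `"otsu"` (default) or `"quantile"`.
#' @param threshold_quantile Quantile used when `threshold_method =
#'   "quantile"`.
#' @param dilation_um Nuclear dilation radius for mono-culture bridging,
#'   um (default 5).
#' @return A list of class `coverage_result`: `coverage` (fraction),
#'   `threshold`, `positive` (logical overlay matrix), `flag`.
#' @export
ec_coverage <- function(img, mask, culture_mode = c("co", "mono"),
                        threshold_method = c("otsu", "quantile"),
                        threshold_quantile = 0.5, dilation_um = 5) {
  stopifnot(inherits(img, "multichannel_image"))
  culture_mode <- match.arg(culture_mode)
  threshold_method <- match.arg(threshold_method)
  m <- if (inherits(mask, "overlap_mask")) mask$mask else mask
  if (!is.matrix(m) || !any(m)) stop("empty overlap mask", call. = FALSE)
  g <- img$channels$ec_marker
  if (is.null(g)) stop("ec_marker channel required", call. = FALSE)
  if (threshold_method == "quantile") {
    thr <- stats::quantile(g[m], threshold_quantile, names = FALSE)
    positive <- g > thr & m
    flag <- "ok"
  } else {
    st <- .auto_threshold_state(g[m])
    thr <- st$threshold
    if (st$status == "none") {
      # The junction channel is uniform within the mask: either the region
      # is cell-free or it is fully covered with uniform stain, and the
      # two are indistinguishable from one channel alone. The DNA stain
      # arbitrates: nuclei present means a confluent stained layer.
      b <- img$channels$nuclei
      if (!is.null(b) &&
          .auto_threshold_state(b[m])$status == "split") {
        st$status <- "saturated"
      }
    }
    if (st$status == "none") {
      positive <- m & FALSE
      flag <- "no_signal"
    } else if (st$status == "saturated") {
      # uniformly covered: the split separates stain texture, not cells
      # from background
      positive <- m
      flag <- "saturated"
    } else {
      positive <- g > thr & m
      flag <- "ok"
    }
  }
  if (culture_mode == "mono" && flag != "no_signal") {
    b <- img$channels$nuclei
    if (is.null(b)) {
      stop("mono-culture coverage needs the nuclei channel", call. = FALSE)
    }
    stb <- .auto_threshold_state(b[m])
    if (stb$status == "split") {
      nuc <- (b > stb$threshold) & m
      r_px <- max(1L, round(dilation_um / img$pixel_size_um))
      nuc <- EBImage::dilate(nuc * 1,
                             EBImage::makeBrush(2L * r_px + 1L,
                                                "disc")) > 0
      positive <- positive | (nuc & m)
    }
  }
  cov <- sum(positive) / sum(m)
  structure(list(coverage = cov, threshold = thr, positive = positive,
                 culture_mode = culture_mode, flag = flag),
            class = "coverage_result")
}

# segment blob-like objects in one channel within the mask and count them,
# splitting touching clusters by their area relative to a singleton
.count_objects <- function(ch, m, pixel_size_um, min_area_um2) {
  st <- .auto_threshold_state(ch[m])
  thr <- st$threshold
  if (st$status != "split") {
    # background-only or uniform channels hold no countable objects
    return(list(count = 0L, labels = matrix(0L, nrow(ch), ncol(ch)),
                threshold = thr))
  }
  bw <- (ch > thr) & m
  if (!any(bw)) {
    return(list(count = 0L, labels = matrix(0L, nrow(ch), ncol(ch)),
                threshold = thr))
  }
  lab <- EBImage::bwlabel(bw * 1)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  floor_px <- min_area_um2 / pixel_size_um^2
  keep <- areas >= floor_px
  if (!any(keep)) {
    return(list(count = 0L, labels = matrix(0L, nrow(ch), ncol(ch)),
                threshold = thr))
  }
  singleton <- stats::median(areas[keep])
  counts <- pmax(1, round(areas[keep] / singleton))
  list(count = as.integer(sum(counts)), labels = lab, threshold = thr,
       singleton_area_px = singleton)
}

#' Count nuclei within the overlap region
#'
#' Thresholds the DNA-stain channel within the mask, labels connected
#' components, discards debris below `min_area_um2`, and counts each
#' component as `round(area / median singleton area)` (minimum 1) so that
#' touching clusters of nuclei are counted by their aggregate area.
#'
#' @inheritParams ec_coverage
#' @param min_area_um2 Debris floor, um2 (default 20).
#' @return A list of class `nucleus_count`: `count`, `labels` (label
#'   overlay matrix), `threshold`, `singleton_area_px`.
#' @export
count_nuclei <- function(img, mask, min_area_um2 = 20) {
  stopifnot(inherits(img, "multichannel_image"))
  m <- if (inherits(mask, "overlap_mask")) mask$mask else mask
  if (!is.matrix(m) || !any(m)) stop("empty overlap mask", call. = FALSE)
  b <- img$channels$nuclei
  if (is.null(b)) stop("nuclei channel required", call. = FALSE)
  res <- .count_objects(b, m, img$pixel_size_um, min_area_um2)
  structure(res, class = "nucleus_count")
}

#' Live/dead viability fraction within the overlap region
#'
#' Counts objects in the `live` and `dead` channels with the same
#' segmentation used by [count_nuclei()] and reports
#' `live / (live + dead)`.
#'
#' @inheritParams count_nuclei
#' @return A list of class `viability_result`: `viability` (fraction, `NA`
#'   when no object is found in either channel), `live_count`,
#'   `dead_count`, `flag`.
#' @export
viability <- function(img, mask, min_area_um2 = 20) {
  stopifnot(inherits(img, "multichannel_image"))
  m <- if (inherits(mask, "overlap_mask")) mask$mask else mask
  if (!is.matrix(m) || !any(m)) stop("empty overlap mask", call. = FALSE)
  if (!all(c("live", "dead") %in% names(img$channels))) {
    stop("viability needs 'live' and 'dead' channels", call. = FALSE)
  }
  live <- .count_objects(img$channels$live, m, img$pixel_size_um,
                         min_area_um2)$count
  dead <- .count_objects(img$channels$dead, m, img$pixel_size_um,
                         min_area_um2)$count
  total <- live + dead
  structure(list(viability = if (total == 0) NA_real_ else live / total,
                 live_count = live, dead_count = dead,
                 flag = if (total == 0) "undefined" else "ok"),
            class = "viability_result")
}

#' Quantify one device tile end to end
#'
#' Convenience wrapper: clean edges, extract the overlap mask, and compute
#' coverage, nucleus count and (when live/dead channels are present)
#' viability. Devices where no overlap/cells are detected return an ND
#' record instead of an error.
#'
#' @param img A raw [multichannel_image()].
#' @param culture_mode `"co"` or `"mono"`.
#' @param ... Passed to [extract_overlap_mask()].
#' @return A list of class `quant_result` with `device`, `status`
#'   (`"ok"`/`"ND"`), `coverage`, `nucleus_count`, `viability`,
#'   `mask_area_mm2`.
#' @export
quantify_device_tile <- function(img, culture_mode = c("co", "mono"), ...) {
  culture_mode <- match.arg(culture_mode)
  cleaned <- clean_channel_edges(img)
  msk <- tryCatch(extract_overlap_mask(cleaned, ...), error = function(e) e)
  if (inherits(msk, "error")) {
    return(structure(list(device = img$device, status = "ND",
                          coverage = NA_real_, nucleus_count = NA_integer_,
                          viability = NA_real_, mask_area_mm2 = NA_real_,
                          message = conditionMessage(msk)),
                     class = "quant_result"))
  }
  cov <- ec_coverage(cleaned, msk, culture_mode)
  nuc <- count_nuclei(cleaned, msk)
  via <- if (all(c("live", "dead") %in% names(img$channels))) {
    viability(cleaned, msk)$viability
  } else NA_real_
  structure(list(device = img$device, status = "ok",
                 coverage = cov$coverage, nucleus_count = nuc$count,
                 viability = via, mask_area_mm2 = msk$area_mm2,
                 flag = if (nuc$count == 0) "no_nuclei" else "ok"),
            class = "quant_result")
}

#' Plate-formatted image-quantification report
#'
#' Lays per-device coverage and nucleus counts out as 8x12 plate tables
#' (ND for blank or failed devices) and aggregates per condition.
#'
#' @param results List of `quant_result`s (from [quantify_device_tile()]).
#' @param pm Optional `plate_map` used to label conditions.
#' @return A list with `coverage` and `counts` (8x12 character matrices,
#'   `"ND"` where not detected) and `by_condition` (tibble of mean +/- SD).
#' @export
plate_image_report <- function(results, pm = NULL) {
  stopifnot(length(results) >= 1)
  cov_tab <- matrix("ND", 8, 12, dimnames = list(DEVICE_ROWS, 1:12))
  cnt_tab <- cov_tab
  dev <- vapply(results, function(r) as.character(r$device), character(1))
  covs <- vapply(results, function(r) r$coverage, numeric(1))
  cnts <- vapply(results, function(r) as.numeric(r$nucleus_count),
                 numeric(1))
  ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
  for (i in seq_along(results)) {
    if (is.na(dev[i]) || !dev[i] %in% device_addresses()) next
    a <- device_address(dev[i])
    if (ok[i]) {
      cov_tab[a$row, a$col] <- sprintf("%.3f", covs[i])
      cnt_tab[a$row, a$col] <- sprintf("%d", as.integer(cnts[i]))
    }
  }
  by_condition <- NULL
  if (!is.null(pm)) {
    stopifnot(inherits(pm, "plate_map"))
    idx <- match(dev, pm$device)
    cond <- condition_label(pm[idx, ])
    keep <- ok & !is.na(cond) & pm$culture_mode[idx] != "blank"
    groups <- split(seq_along(results)[keep], cond[keep])
    by_condition <- tibble::tibble(
      condition = names(groups),
      n = unname(vapply(groups, length, integer(1))),
      coverage_mean = unname(vapply(groups, function(i) mean(covs[i]),
                                    numeric(1))),
      coverage_sd = unname(vapply(groups, function(i)
        if (length(i) > 1) stats::sd(covs[i]) else NA_real_, numeric(1))),
      count_mean = unname(vapply(groups, function(i) mean(cnts[i]),
                                 numeric(1))),
      count_sd = unname(vapply(groups, function(i)
        if (length(i) > 1) stats::sd(cnts[i]) else NA_real_, numeric(1)))
    )
  }
  list(coverage = cov_tab, counts = cnt_tab, by_condition = by_condition)
}
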