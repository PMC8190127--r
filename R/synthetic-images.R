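# Synthetic device-tile renderer with exact ground truth. Emulates a tile
# scan of one bilayer device: two overlapping channel bands whose
# intersection is the 3.7 mm2 overlap region, nucleus blobs (with touching
# clusters), a junctional EC border stain over the covered fraction,
# optional live/dead channels, channel autofluorescence, a background
# gradient, bright channel-edge ridge artifacts and sensor noise.

#' Describe a synthetic device-tile scenario
#'
#' The default geometry reproduces the production device as seen in a
#' low-magnification tile scan: 1 mm wide channels whose straight segments
#' coincide over a 3.7 mm stretch, giving the 3.7 mm2 channel-overlap
#' region, flanked by channel arms that leave the field of view. The
#' default raster is 896 x 1792 px at 2.6 um/px (a 2x-binned 10x tile
#' scan, 2.33 x 4.66 mm field).
#'
#' @param tile_px Integer c(rows, cols) of the raster.
#' @param pixel_size_um Physical pixel size, um/px.
#' @param channel_width_mm Channel width, mm (vertical extent of the band).
#' @param overlap_length_mm Length of the coincident channel segment, mm
#'   (overlap area = width x length, default 1 x 3.7 = 3.7 mm2).
#' @param coverage Target EC coverage fraction of the overlap in `[0, 1]`.
#' @param n_nuclei Number of nuclei to render (exact ground-truth count).
#' @param cluster_prob Probability that a placement event is a touching
#'   pair rather than a single nucleus (default 0.15).
#' @param nucleus_radius_um Mean nucleus radius, um.
#' @param viability Live fraction in `[0, 1]`, or `NA` to skip live/dead
#'   channels.
#' @param background Optical background level outside the channels.
#' @param autofluorescence Added brightness per fluidic layer (the overlap
#'   region carries two layers).
#' @param gradient_amplitude Peak-to-peak amplitude of a linear
#'   illumination gradient across the tile.
#' @param noise_sd Gaussian sensor noise SD per pixel.
#' @param edge_artifact Render bright channel-wall ridges in the
#'   `ec_marker` channel (default TRUE).
#' @param edge_brightness Ridge brightness (near saturation).
#' @return An object of class `image_scenario`.
#' @export
image_scenario <- function(tile_px = c(896L, 1792L), pixel_size_um = 2.6,
                           channel_width_mm = 1, overlap_length_mm = 3.7,
                           coverage = 0.9, n_nuclei = 2000,
                           cluster_prob = 0.15, nucleus_radius_um = 5.5,
                           viability = NA_real_, background = 0.01,
                           autofluorescence = 0.08,
                           gradient_amplitude = 0.03, noise_sd = 0.015,
                           edge_artifact = TRUE, edge_brightness = 0.92) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0,1]",
                                         call. = FALSE)
  if (!is.na(viability) && (viability < 0 || viability > 1)) {
    stop("viability must be in [0,1]", call. = FALSE)
  }
  mm2px <- 1000 / pixel_size_um
  if (overlap_length_mm * mm2px >= tile_px[2] ||
      channel_width_mm * mm2px >= tile_px[1]) {
    stop("overlap region does not fit in the tile at this pixel size",
         call. = FALSE)
  }
  structure(list(tile_px = as.integer(tile_px),
                 pixel_size_um = pixel_size_um,
                 channel_width_mm = channel_width_mm,
                 overlap_length_mm = overlap_length_mm,
                 coverage = coverage, n_nuclei = as.integer(n_nuclei),
                 cluster_prob = cluster_prob,
                 nucleus_radius_um = nucleus_radius_um,
                 viability = viability, background = background,
                 autofluorescence = autofluorescence,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, edge_artifact = edge_artifact,
                 edge_brightness = edge_brightness),
            class = "image_scenario")
}

# weights of an elliptical blob (soft-edged) or ring within its local
# window, as linear indices into an (nr x nc) raster plus weights; the
# caller accumulates them into a flat buffer to avoid full-matrix copies
.blob_weights <- function(r0, c0, radius_px, nr, nc, axis_ratio = 1,
                          angle = 0, ring = FALSE) {
  a <- radius_px * sqrt(axis_ratio)
  b <- radius_px / sqrt(axis_ratio)
  ext <- ceiling(max(a, b) * 1.4) + 1L
  rr <- max(1L, round(r0) - ext):min(nr, round(r0) + ext)
  cc <- max(1L, round(c0) - ext):min(nc, round(c0) + ext)
  dy <- rr - r0
  dx <- cc - c0
  cs <- cos(angle); sn <- sin(angle)
  u <- outer(dy, dx, function(y, x) x * cs + y * sn)
  v <- outer(dy, dx, function(y, x) -x * sn + y * cs)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  w <- if (ring) pmax(0, 1 - abs(rho - 1) / 0.22) else
    pmin(1, pmax(0, (1.15 - rho) / 0.3))
  keep <- which(w > 0)
  idx <- outer(rr, (cc - 1L) * nr, `+`)[keep]
  list(idx = idx, w = w[keep])
}

# rejection-sample blob centres inside `allowed` (logical matrix) with a
# minimum pairwise separation, using a bucket grid for neighbour lookup
.place_points <- function(n, allowed, min_sep_px) {
  idx <- which(allowed)
  if (!length(idx)) stop("no room to place objects", call. = FALSE)
  nr <- nrow(allowed)
  cell <- max(1, min_sep_px)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    i <- idx[sample.int(length(idx), 1L)]
    r <- ((i - 1L) %% nr) + 1L + stats::runif(1, -0.5, 0.5)
    c <- ((i - 1L) %/% nr) + 1L + stats::runif(1, -0.5, 0.5)
    br <- floor(r / cell); bc <- floor(c / cell)
    clash <- FALSE
    for (dr in -1:1) {
      for (dc in -1:1) {
        key <- paste(br + dr, bc + dc)
        nb <- buckets[[key]]
        if (!is.null(nb)) {
          for (j in seq_len(nrow(nb))) {
            if ((nb[j, 1] - r)^2 + (nb[j, 2] - c)^2 < min_sep_px^2) {
              clash <- TRUE
              break
            }
          }
        }
        if (clash) break
      }
      if (clash) break
    }
    if (clash) next
    placed <- placed + 1L
    pts[placed, ] <- c(r, c)
    key <- paste(br, bc)
    buckets[[key]] <- rbind(buckets[[key]], c(r, c))
  }
  if (placed < n) {
    stop("could not place all objects at the requested density",
         call. = FALSE)
  }
  pts
}

# smooth random field over a (nr x nc) window: coarse white noise,
# bilinearly upsampled
.smooth_field <- function(nr, nc, scale_px = 64) {
  gr <- max(2L, ceiling(nr / scale_px) + 1L)
  gc <- max(2L, ceiling(nc / scale_px) + 1L)
  coarse <- matrix(stats::rnorm(gr * gc), gr, gc)
  ry <- seq(1, gr, length.out = nr)
  rx <- seq(1, gc, length.out = nc)
  y0 <- pmin(floor(ry), gr - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gc - 1L); fx <- rx - x0
  a <- coarse[y0, x0, drop = FALSE]
  b <- coarse[y0 + 1L, x0, drop = FALSE]
  cc <- coarse[y0, x0 + 1L, drop = FALSE]
  d <- coarse[y0 + 1L, x0 + 1L, drop = FALSE]
  a * outer(1 - fy, 1 - fx) + b * outer(fy, 1 - fx) +
    cc * outer(1 - fy, fx) + d * outer(fy, fx)
}

#' Render a synthetic device tile with exact ground truth
#'
#' Deterministic function of (scenario, seed). Returns the multi-channel
#' raster together with the exact ground truth used to benchmark the
#' quantification pipeline: the true overlap mask, the realised coverage
#' fraction (pixel-exact within the overlap), the rendered nucleus count
#' and the live fraction.
#'
#' @param scenario An [image_scenario()].
#' @param seed Integer seed.
#' @return A list with `image` (a [multichannel_image()]) and `truth`
#'   (list: `mask`, `coverage`, `nucleus_count`, `viability`,
#'   `overlap_area_mm2`).
#' @export
render_device_tile <- function(scenario = image_scenario(), seed = 1L) {
  stopifnot(inherits(scenario, "image_scenario"))
  s <- scenario
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  nr <- s$tile_px[1]; nc <- s$tile_px[2]
  px <- s$pixel_size_um
  mm2px <- 1000 / px
  band_h <- round(s$channel_width_mm * mm2px)
  r0 <- floor((nr - band_h) / 2) + 1L
  r1 <- r0 + band_h - 1L
  ov_len <- round(s$overlap_length_mm * mm2px)
  c0 <- floor((nc - ov_len) / 2) + 1L
  c1 <- c0 + ov_len - 1L
  arm_w <- band_h

  # region masks
  top_band <- matrix(FALSE, nr, nc); top_band[r0:r1, ] <- TRUE
  bottom_chan <- matrix(FALSE, nr, nc)
  bottom_chan[r0:r1, c0:c1] <- TRUE                      # coincident segment
  if (r1 < nr) {
    bottom_chan[(r1 + 1L):nr, c0:(c0 + arm_w - 1L)] <- TRUE   # left arm
    bottom_chan[(r1 + 1L):nr, (c1 - arm_w + 1L):c1] <- TRUE   # right arm
  }
  overlap <- top_band & bottom_chan

  # shared optical base: background + per-layer autofluorescence + gradient
  grad <- s$gradient_amplitude *
    (outer(seq_len(nr) / nr, rep(0.35, nc)) +
       outer(rep(0.65, nr), seq_len(nc) / nc) - 0.5)
  base <- s$background + s$autofluorescence * (top_band + bottom_chan) + grad

  green <- base
  blue <- base

  # covered region: thresholded smooth field, pixel-exact target fraction
  ov_rows <- r0:r1; ov_cols <- c0:c1
  n_ov <- length(ov_rows) * length(ov_cols)
  covered_local <- matrix(FALSE, length(ov_rows), length(ov_cols))
  n_cov <- round(s$coverage * n_ov)
  if (n_cov > 0) {
    field <- .smooth_field(length(ov_rows), length(ov_cols))
    cut <- sort(field, decreasing = TRUE)[n_cov]
    covered_local <- field >= cut
  }
  covered <- matrix(FALSE, nr, nc)
  covered[ov_rows, ov_cols] <- covered_local
  true_cov <- sum(covered_local) / n_ov

  # diffuse junctional stain over the covered area
  green <- green + 0.22 * covered

  r_nuc <- s$nucleus_radius_um / px
  standoff <- ceiling(3 * r_nuc)
  allowed <- matrix(FALSE, nr, nc)
  core_rows <- (r0 + standoff):(r1 - standoff)
  core_cols <- (c0 + standoff):(c1 - standoff)
  allowed[core_rows, core_cols] <- covered[core_rows, core_cols]

  n <- s$n_nuclei
  if (n > 0) {
    # decide singles vs touching pairs up front so the total is exact
    sizes <- integer(0)
    left <- n
    while (left > 0) {
      if (left >= 2 && stats::runif(1) < s$cluster_prob) {
        sizes <- c(sizes, 2L); left <- left - 2L
      } else {
        sizes <- c(sizes, 1L); left <- left - 1L
      }
    }
    centres <- .place_points(length(sizes), allowed,
                             min_sep_px = 3.2 * r_nuc)
    ring_r <- 1.65 * r_nuc
    blue_add <- numeric(nr * nc)
    green_add <- numeric(nr * nc)
    for (i in seq_along(sizes)) {
      rc <- centres[i, ]
      members <- if (sizes[i] == 2L) {
        ang <- stats::runif(1, 0, 2 * pi)
        off <- 1.9 * r_nuc / 2
        rbind(rc + off * c(sin(ang), cos(ang)),
              rc - off * c(sin(ang), cos(ang)))
      } else {
        rbind(rc)
      }
      for (j in seq_len(nrow(members))) {
        bw <- .blob_weights(members[j, 1], members[j, 2],
                            r_nuc * stats::runif(1, 0.9, 1.1), nr, nc,
                            axis_ratio = stats::runif(1, 1, 1.3),
                            angle = stats::runif(1, 0, pi))
        blue_add[bw$idx] <- blue_add[bw$idx] + 0.5 * bw$w
        rw <- .blob_weights(members[j, 1], members[j, 2], ring_r, nr, nc,
                            ring = TRUE)
        green_add[rw$idx] <- green_add[rw$idx] +
          0.12 * rw$w * covered[rw$idx]
      }
    }
    blue <- blue + blue_add
    green <- green + green_add
  }

  channels <- list(nuclei = blue, ec_marker = green)

  if (!is.na(s$viability)) {
    n_live <- round(s$n_nuclei * s$viability)
    n_dead <- s$n_nuclei - n_live
    for (side in c("live", "dead")) {
      n_side <- if (side == "live") n_live else n_dead
      add <- numeric(nr * nc)
      if (n_side > 0) {
        pts <- .place_points(n_side, allowed, min_sep_px = 3.2 * r_nuc)
        for (j in seq_len(n_side)) {
          bw <- .blob_weights(pts[j, 1], pts[j, 2],
                              r_nuc * stats::runif(1, 0.9, 1.1), nr, nc)
          add[bw$idx] <- add[bw$idx] + 0.5 * bw$w
        }
      }
      channels[[side]] <- base + add
    }
  }

  # bright channel-wall ridges (junction-stain channel only)
  if (s$edge_artifact) {
    e <- 1L  # half-width -> 3 px ridge
    ridge <- matrix(FALSE, nr, nc)
    for (rr in c(r0, r1)) {
      ridge[max(1, rr - e):min(nr, rr + e), ] <- TRUE       # band walls
    }
    for (ccx in c(c0, c1)) {                                 # segment ends
      ridge[r0:r1, max(1, ccx - e):min(nc, ccx + e)] <- TRUE
    }
    if (r1 < nr) {
      for (ccx in c(c0, c0 + arm_w - 1L, c1 - arm_w + 1L, c1)) {
        ridge[(r1 + 1L):nr, max(1, ccx - e):min(nc, ccx + e)] <- TRUE
      }
    }
    g <- channels$ec_marker
    g[ridge] <- pmax(g[ridge], s$edge_brightness)
    channels$ec_marker <- g
  }

  # sensor noise, clipped to the dynamic range
  channels <- lapply(channels, function(ch) {
    ch <- ch + stats::rnorm(length(ch), 0, s$noise_sd)
    ch[ch < 0] <- 0
    ch[ch > 1] <- 1
    ch
  })

  mask_truth <- overlap
  img <- multichannel_image(channels, pixel_size_um = px)
  list(image = img,
       truth = list(mask = mask_truth,
                    coverage = true_cov,
                    nucleus_count = if (is.na(s$viability)) s$n_nuclei else
                      s$n_nuclei,
                    viability = if (is.na(s$viability)) NA_real_ else
                      round(s$n_nuclei * s$viability) / s$n_nuclei,
                    overlap_area_mm2 = sum(overlap) * (px / 1000)^2))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b Logical matrices of equal dimension.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "overlap_mask")) a <- a$mask
  if (inherits(b, "overlap_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  sum(a & b) / sum(a | b)
}
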