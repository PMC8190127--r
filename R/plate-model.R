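# Data model for the 96-device bilayer plate, its 384-well interface,
# device geometry and plate-map conditions.

#' Physical geometry of one bilayer microfluidic device
#'
#' Bundles the physical constants of a single bilayer device: two stacked
#' U-shaped microchannels separated by a track-etched microporous membrane.
#' Cells cultured on opposite membrane faces interact only in the region
#' where the two channels overlap.
#'
#' Defaults describe the production device: 1 mm wide, 250 um tall channels;
#' membrane surface areas of 8.5 mm2 (top channel) and 6.9 mm2 (bottom
#' channel) with a 3.7 mm2 channel-overlap region; a 10 um thick membrane
#' with 3 um pores at 2e6 pores/cm2.
#'
#' @param channel_width_mm Channel width, mm.
#' @param channel_height_um Channel height, um.
#' @param membrane_area_top_mm2 Membrane surface area of the top channel, mm2.
#' @param membrane_area_bottom_mm2 Membrane surface area of the bottom
#'   channel, mm2.
#' @param overlap_area_mm2 Channel-overlap area (the imaging and co-culture
#'   region of interest), mm2.
#' @param membrane_thickness_um Membrane thickness, um.
#' @param pore_diameter_um Nominal membrane pore diameter, um.
#' @param pore_density_per_cm2 Membrane pore density, pores/cm2.
#'
#' @return An object of class `device_geometry`.
#' @examples
#' geom <- device_geometry()
#' channel_volume(geom, "top")
#' membrane_porosity(geom)
#' @export
device_geometry <- function(channel_width_mm = 1,
                            channel_height_um = 250,
                            membrane_area_top_mm2 = 8.5,
                            membrane_area_bottom_mm2 = 6.9,
                            overlap_area_mm2 = 3.7,
                            membrane_thickness_um = 10,
                            pore_diameter_um = 3,
                            pore_density_per_cm2 = 2e6) {
  vals <- c(channel_width_mm = channel_width_mm,
            channel_height_um = channel_height_um,
            membrane_area_top_mm2 = membrane_area_top_mm2,
            membrane_area_bottom_mm2 = membrane_area_bottom_mm2,
            overlap_area_mm2 = overlap_area_mm2,
            membrane_thickness_um = membrane_thickness_um,
            pore_diameter_um = pore_diameter_um)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all device dimensions must be positive and finite", call. = FALSE)
  }
  if (pore_density_per_cm2 < 0) {
    stop("pore density must be non-negative", call. = FALSE)
  }
  if (overlap_area_mm2 > min(membrane_area_top_mm2, membrane_area_bottom_mm2)) {
    stop("overlap area cannot exceed either membrane area", call. = FALSE)
  }
  geom <- structure(as.list(c(vals,
                              pore_density_per_cm2 = pore_density_per_cm2)),
                    class = "device_geometry")
  # fail early on physically impossible pore packing
  membrane_porosity(geom)
  geom
}

#' @export
print.device_geometry <- function(x, ...) {
  cat("Bilayer device geometry\n")
  cat(sprintf("  channel: %.3g mm wide x %.4g um tall\n",
              x$channel_width_mm, x$channel_height_um))
  cat(sprintf("  membrane areas (mm2): top %.3g, bottom %.3g, overlap %.3g\n",
              x$membrane_area_top_mm2, x$membrane_area_bottom_mm2,
              x$overlap_area_mm2))
  cat(sprintf("  membrane: %.3g um thick, %.3g um pores at %.3g /cm2 (porosity %.3f)\n",
              x$membrane_thickness_um, x$pore_diameter_um,
              x$pore_density_per_cm2, membrane_porosity(x)))
  invisible(x)
}

#' Geometric volume of one device channel
#'
#' The fluid volume of the channel lumen, computed as the channel's membrane
#' surface area times the channel height. For the default geometry the top
#' channel holds 8.5 mm2 x 250 um = 2.125 ul, i.e. roughly 2.1 ul per
#' channel.
#'
#' @param geom A [device_geometry()].
#' @param side `"top"` or `"bottom"`.
#' @return Channel volume in microlitres.
#' @export
channel_volume <- function(geom, side = c("top", "bottom")) {
  stopifnot(inherits(geom, "device_geometry"))
  side <- match.arg(side)
  area_mm2 <- if (side == "top") geom$membrane_area_top_mm2 else
    geom$membrane_area_bottom_mm2
  # mm2 * um = mm2 * 1e-3 mm = 1e-3 mm3 = 1e-3 ul... (1 mm3 == 1 ul)
  area_mm2 * geom$channel_height_um * 1e-3
}

#' Membrane porosity fraction
#'
#' Open-area fraction of the track-etched membrane,
#' `pi * (d/2)^2 * density`, dimensionless. The default pore specification
#' (3 um pores, 2e6 pores/cm2) gives a porosity of about 0.141.
#'
#' @param geom A [device_geometry()].
#' @return Porosity as a fraction in `[0, 1)`.
#' @export
membrane_porosity <- function(geom) {
  stopifnot(inherits(geom, "device_geometry"))
  d_cm <- geom$pore_diameter_um * 1e-4
  frac <- pi * (d_cm / 2)^2 * geom$pore_density_per_cm2
  if (frac >= 1) {
    stop(sprintf(
      "pore specification implies porosity %.3f >= 1 (overlapping pores)",
      frac), call. = FALSE)
  }
  frac
}

# ---- device / well addressing ------------------------------------------

DEVICE_ROWS <- LETTERS[1:8]
WELL_ROWS <- LETTERS[1:16]

#' Device address on the 96-device plate
#'
#' Devices are addressed like a 96-well plate: rows A-H, columns 1-12.
#'
#' @param row Row letter `"A"`-`"H"` (or a string like `"B7"` in which case
#'   `col` is ignored).
#' @param col Column number 1-12.
#' @return An object of class `device_address`.
#' @examples
#' device_address("A", 1)
#' device_address("H12")
#' @export
device_address <- function(row, col = NULL) {
  if (is.null(col)) {
    m <- regmatches(row, regexec("^([A-H])([0-9]{1,2})$", row))[[1]]
    if (length(m) != 3) {
      stop("device address must look like 'A1' .. 'H12'", call. = FALSE)
    }
    col <- as.integer(m[3])
    row <- m[2]
  }
  col <- as.integer(col)
  if (!(row %in% DEVICE_ROWS) || is.na(col) || col < 1 || col > 12) {
    stop(sprintf("invalid device address %s%s (rows A-H, columns 1-12)",
                 row, col), call. = FALSE)
  }
  structure(list(row = row, col = col), class = "device_address")
}

#' @export
format.device_address <- function(x, ...) paste0(x$row, x$col)

#' @export
print.device_address <- function(x, ...) {
  cat("<device ", format(x), ">\n", sep = "")
  invisible(x)
}

#' All 96 device addresses in row-major order
#' @return Character vector `"A1" ... "H12"`.
#' @export
device_addresses <- function() {
  as.vector(t(outer(DEVICE_ROWS, 1:12, paste0)))
}

#' Map a device to its four wells on the 384-well interface
#'
#' Each bilayer device is served by a 2x2 block of wells on the 384-well
#' plate top: one well for each inlet and outlet port of the top and bottom
#' channels. The mapping is a bijection: the 96 devices x 4 roles cover all
#' 384 wells exactly once.
#'
#' The quadrant convention assigns roles within the 2x2 block. The default
#' (`"top-row-top-channel"`) puts the top channel on the upper row of the
#' block with inlets on the left; `"left-col-top-channel"` puts the top
#' channel on the left column with inlets on the upper row.
#'
#' @param addr A [device_address()] or a string like `"A1"`.
#' @param convention Quadrant convention tag (see Details).
#' @return A tibble with columns `well`, `row`, `col`, `role` (one of
#'   `top_inlet`, `top_outlet`, `bottom_inlet`, `bottom_outlet`).
#' @examples
#' device_wells("A1")
#' device_wells("H12")
#' @export
device_wells <- function(addr,
                         convention = c("top-row-top-channel",
                                        "left-col-top-channel")) {
  if (is.character(addr)) addr <- device_address(addr)
  stopifnot(inherits(addr, "device_address"))
  convention <- match.arg(convention)
  ri <- match(addr$row, DEVICE_ROWS)
  rows <- WELL_ROWS[c(2L * ri - 1L, 2L * ri)]
  cols <- c(2L * addr$col - 1L, 2L * addr$col)
  # four wells of the 2x2 block in (row, col) order
  grid <- expand.grid(row = rows, col = cols,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$row, grid$col), ]
  roles <- if (convention == "top-row-top-channel") {
    # upper row = top channel, left = inlet
    c("top_inlet", "top_outlet", "bottom_inlet", "bottom_outlet")
  } else {
    # left column = top channel, upper = inlet
    c("top_inlet", "bottom_inlet", "top_outlet", "bottom_outlet")
  }
  tibble::tibble(well = paste0(grid$row, grid$col),
                 row = grid$row, col = grid$col, role = roles)
}

# ---- plate map ----------------------------------------------------------

CULTURE_MODES <- c("mono_EC", "mono_PC", "co", "blank")

#' Build a plate map of culture conditions
#'
#' A plate map assigns each device a culture mode (`mono_EC`, `mono_PC`,
#' `co`, or `blank`), a media identifier, a treatment and a replicate
#' group. Devices absent from `assignments` are treated as blank.
#'
#' @param assignments Data frame with columns `device`, `culture_mode` and
#'   optionally `media_id`, `treatment`, `replicate_group`.
#' @return A tibble of class `plate_map` with one row per device (96 rows).
#' @export
plate_map <- function(assignments) {
  assignments <- as.data.frame(assignments, stringsAsFactors = FALSE)
  if (!all(c("device", "culture_mode") %in% names(assignments))) {
    stop("plate map needs at least 'device' and 'culture_mode' columns",
         call. = FALSE)
  }
  dev <- as.character(assignments$device)
  if (anyDuplicated(dev)) {
    stop(sprintf("duplicated device row(s): %s",
                 paste(unique(dev[duplicated(dev)]), collapse = ", ")),
         call. = FALSE)
  }
  lapply(dev, device_address)  # validates addresses
  bad <- setdiff(unique(assignments$culture_mode), CULTURE_MODES)
  if (length(bad)) {
    stop(sprintf("unknown culture_mode: %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(CULTURE_MODES, collapse = ", ")), call. = FALSE)
  }
  for (f in c("media_id", "treatment", "replicate_group")) {
    if (is.null(assignments[[f]])) assignments[[f]] <- NA_character_
    assignments[[f]] <- as.character(assignments[[f]])
  }
  full <- tibble::tibble(device = device_addresses())
  out <- merge(full, assignments, by = "device", all.x = TRUE, sort = FALSE)
  out$culture_mode[is.na(out$culture_mode)] <- "blank"
  out <- out[match(full$device, out$device),
             c("device", "culture_mode", "media_id", "treatment",
               "replicate_group")]
  out <- tibble::as_tibble(out)
  class(out) <- c("plate_map", class(out))
  out
}

#' Read a plate map from CSV
#'
#' One device per row; columns `device,culture_mode[,media_id,treatment,
#' replicate_group]`, UTF-8, comma-separated, with a header. Rows whose
#' `culture_mode` is `blank` (or devices missing from the file) are kept as
#' blanks, mirroring plates where e.g. an entire column is left cell-free
#' as permeability control.
#'
#' @param file Path to the CSV file.
#' @return A `plate_map` tibble.
#' @export
parse_plate_map <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  plate_map(df)
}

#' Write a plate map to CSV in canonical form
#'
#' Canonical form is all 96 devices in row-major order (A1..H12) with the
#' full five-column header, so `write_plate_map(parse_plate_map(f))`
#' reproduces a canonical file byte-for-byte.
#'
#' @param pm A `plate_map`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_plate_map <- function(pm, file) {
  stopifnot(inherits(pm, "plate_map"))
  utils::write.csv(as.data.frame(pm), file, row.names = FALSE, na = "")
  invisible(file)
}

# internal: condition label used to group replicates in reports
condition_label <- function(pm_rows) {
  lab <- pm_rows$culture_mode
  extra <- !is.na(pm_rows$treatment) & pm_rows$treatment != ""
  lab[extra] <- paste(lab[extra], pm_rows$treatment[extra], sep = "+")
  has_media <- !is.na(pm_rows$media_id) & pm_rows$media_id != ""
  lab[has_media] <- paste(lab[has_media], pm_rows$media_id[has_media],
                          sep = ":")
  lab
}
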