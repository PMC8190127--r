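test_that("channel volumes follow area x height and match the device", {
  geom <- device_geometry()
  expect_equal(channel_volume(geom, "top"), 2.125)      # 8.5 mm2 x 250 um
  expect_equal(channel_volume(geom, "bottom"), 1.725)   # 6.9 mm2 x 250 um
  expect_equal(round(channel_volume(geom, "top"), 1), 2.1)
  # homogeneous of degree 1 in the linear (height) dimension
  geom2 <- device_geometry(channel_height_um = 500)
  expect_equal(channel_volume(geom2, "top"), 2 * channel_volume(geom, "top"))
})

test_that("membrane porosity is pi (d/2)^2 rho and scales quadratically", {
  geom <- device_geometry()
  expect_equal(membrane_porosity(geom), pi * (1.5e-4)^2 * 2e6)
  expect_equal(round(membrane_porosity(geom), 4), 0.1414)
  expect_equal(membrane_porosity(device_geometry(pore_density_per_cm2 = 0)),
               0)
  d2 <- device_geometry(pore_diameter_um = 6, pore_density_per_cm2 = 5e5)
  expect_equal(membrane_porosity(d2),
               membrane_porosity(device_geometry(pore_density_per_cm2 = 5e5)) * 4)
})

test_that("impossible geometries are rejected", {
  expect_error(device_geometry(channel_width_mm = -1), "positive")
  expect_error(device_geometry(overlap_area_mm2 = 9), "overlap")
  # 10 um pores at 2e6 /cm2 would imply porosity > 1
  expect_error(device_geometry(pore_diameter_um = 10), "porosity")
  expect_error(channel_volume(list(), "top"))
})

test_that("device-to-well mapping follows the 2x2 block convention", {
  w <- device_wells("A1")
  expect_equal(w$well, c("A1", "A2", "B1", "B2"))
  expect_equal(w$role[w$well == "A1"], "top_inlet")
  expect_equal(w$role[w$well == "A2"], "top_outlet")
  expect_equal(w$role[w$well == "B1"], "bottom_inlet")
  w2 <- device_wells("H12")
  expect_setequal(w2$well, c("O23", "O24", "P23", "P24"))
  # alternative quadrant convention keeps the same block, different roles
  w3 <- device_wells("A1", convention = "left-col-top-channel")
  expect_equal(w3$role[w3$well == "B1"], "top_outlet")
  expect_error(device_wells("I3"), "address")
  expect_error(device_address("A13"), "address|columns")
})

test_that("the 96 x 4 device-well mapping is a bijection onto 384 wells", {
  wells <- unlist(lapply(device_addresses(), function(d)
    device_wells(d)$well))
  expect_length(wells, 384)
  expect_false(anyDuplicated(wells) > 0)
  expect_setequal(wells,
                  as.vector(outer(LETTERS[1:16], 1:24, paste0)))
})

test_that("plate maps parse, preserve blanks, and round-trip canonically", {
  df <- expand.grid(row = LETTERS[1:8], col = 1:12,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$device <- paste0(df$row, df$col)
  df$culture_mode <- ifelse(df$col == 12, "blank",
                            ifelse(df$row %in% LETTERS[1:4], "co",
                                   "mono_EC"))
  df$media_id <- paste0("M", (df$col - 1) %% 10 + 1)
  df$treatment <- ""
  df$replicate_group <- df$media_id
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df[c("device", "culture_mode", "media_id", "treatment",
                        "replicate_group")], f, row.names = FALSE)
  pm <- parse_plate_map(f)
  expect_s3_class(pm, "plate_map")
  expect_equal(nrow(pm), 96)
  expect_equal(sum(pm$culture_mode == "blank"), 8)

  f2 <- tempfile(fileext = ".csv")
  f3 <- tempfile(fileext = ".csv")
  write_plate_map(pm, f2)
  write_plate_map(parse_plate_map(f2), f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("malformed plate maps raise parse errors", {
  bad <- data.frame(device = c("A1", "A1"), culture_mode = c("co", "co"))
  expect_error(plate_map(bad), "duplicated")
  expect_error(plate_map(data.frame(device = "A1",
                                    culture_mode = "triculture")),
               "culture_mode")
  expect_error(plate_map(data.frame(device = "Z9", culture_mode = "co")),
               "address")
})
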