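test_that("metal segmentation handles empty, tiny and real cases", {
  base <- ct_volume(array(0, c(64, 64, 1)), c(3, 3, 2.5))
  expect_false(any(segment_metal(base)$mask))
  one <- base
  one$data[32, 32, 1] <- 3071
  expect_false(any(segment_metal(one)$mask))  # below minimum component size
  # configuration-1 image: components centered on slots A and B with the
  # area of the 1 cm insert disk
  run <- fx_study()
  seg <- run$datasets$lowZ$corrected$meta$segmentation
  expect_true(any(seg$mask))
  lab <- run$datasets$lowZ$labels
  disk_area <- pi * 0.5^2 / (0.3 * 0.3)
  for (k in seq_len(dim(seg$mask)[3])) {
    comp <- seg$components[, , k]
    ids <- setdiff(unique(as.integer(comp)), 0L)
    expect_equal(length(ids), 2L)
    for (cc in ids) {
      idx <- which(comp == cc, arr.ind = TRUE)
      cx <- (mean(idx[, 1]) - 64.5) * 0.3
      expect_lt(abs(abs(cx) - 7), 0.5)
      expect_lt(abs(mean((idx[, 2] - 64.5) * 0.3)), 0.5)
      expect_lt(abs(nrow(idx) - disk_area) / disk_area, 0.3)
    }
  }
})

test_that("metal trace flags the rays through metal plus starved bins", {
  geom <- scan_geometry(n_views = 45, n_bins = 96, bin_mm = 3)
  seg0 <- structure(list(mask = array(FALSE, c(96, 96, 1)),
                         components = array(0L, c(96, 96, 1)),
                         component_hu = numeric(0),
                         assignment = "generic", metal_hu = NA,
                         spacing = c(3, 3, 2.5), origin = c(-144, -144, 0)),
                    class = "metal_segmentation")
  starved <- array(FALSE, c(96, 45, 1))
  starved[10, 7, 1] <- TRUE
  tr0 <- metal_trace(seg0, geom, starved)
  expect_identical(tr0$trace, starved)
  # single metal voxel: exactly one contiguous flagged run per view
  seg1 <- seg0
  seg1$mask[40, 52, 1] <- TRUE
  tr1 <- metal_trace(seg1, geom, dilate_bins = 2)
  for (v in seq_len(45)) {
    r <- rle(tr1$metal[, v, 1])
    expect_equal(sum(r$values), 1L)
  }
  # the 3 cm insert trace covers more bins than the 1 cm one
  run <- fx_study()
  s1 <- run$datasets$lowZ$corrected$meta$segmentation
  s2 <- run$datasets$highZ$corrected$meta$segmentation
  geom2 <- scan_geometry(180, 256, 3)
  f1 <- mean(metal_trace(s1, geom2)$metal)
  f2 <- mean(metal_trace(s2, geom2)$metal)
  expect_gt(f2, f1)
})

test_that("physics correction inverts the polychromatic two-material model", {
  mats <- fx_materials(); tab <- fx_table(); spec <- fx_spectrum()
  eref <- fx_eref()
  geom <- scan_geometry(n_views = 4, n_bins = 128, bin_mm = 3)
  seg <- structure(list(mask = array(TRUE, c(4, 4, 1)),
                        assignment = "titanium"),
                   class = "metal_segmentation")
  mu_w_E <- fx_mu_water(spec$energy)
  mu_m_E <- linear_attenuation(mats$titanium, spec$energy, tab)
  set.seed(8)
  tw <- matrix(runif(128 * 4, 5, 33), 128, 4)
  tm <- matrix(0, 128, 4)
  tm[5:80, ] <- runif(76 * 4, 0.1, 1)
  pm <- matrix(0, 128, 4)
  for (i in seq_along(pm))
    pm[i] <- -log(sum(spec$weights * exp(-mu_w_E * tw[i] - mu_m_E * tm[i])))
  sino <- ctmar:::new_sinogram(array(pm, c(128, 4, 1)), "line-integral",
                               geom, valid = array(TRUE, c(128, 4, 1)))
  out <- physics_correct(sino, array(tm, c(128, 4, 1)), seg, spec, tab,
                         eref, mats)
  mu_w_ref <- fx_mu_water(eref)
  mu_m_ref <- linear_attenuation(mats$titanium, eref, tab)
  # round-trip oracle: the water part keeps its polychromatic response,
  # the metal part is replaced by its monochromatic equivalent
  pw0 <- matrix(vapply(tw, function(w)
    -log(sum(spec$weights * exp(-mu_w_E * w))), numeric(1)), 128, 4)
  ideal <- pw0 + mu_m_ref * tm
  sel <- tm > 0
  expect_lt(max(abs(out$values[, , 1][sel] - ideal[sel]) / ideal[sel]), 0.01)
  # bins without metal pass through exactly
  expect_identical(out$values[, , 1][!sel], pm[!sel])
  # no metal anywhere: exact pass-through
  out0 <- physics_correct(sino, array(0, c(128, 4, 1)), seg, spec, tab,
                          eref, mats)
  expect_identical(out0$values, sino$values)
  # monochromatic acquisition: correction is the identity up to lookup error
  spec1 <- xray_spectrum(eref, 1)
  pm1 <- mu_w_ref * tw + mu_m_ref * tm
  sino1 <- ctmar:::new_sinogram(array(pm1, c(128, 4, 1)), "line-integral",
                                geom, valid = array(TRUE, c(128, 4, 1)))
  out1 <- physics_correct(sino1, array(tm, c(128, 4, 1)), seg, spec1, tab,
                          eref, mats)
  expect_lt(max(abs(out1$values - sino1$values) / pmax(sino1$values, 1)),
            0.001)
})

test_that("sinogram completion recovers missing views and enforces mass conservation", {
  mats <- fx_materials(); tab <- fx_table()
  lab <- build_phantom(water_cylinder(n = 96, spacing_mm = 3,
                                      diameter_cm = 20))
  geom <- ctmar:::default_geometry(lab, 60)
  li <- forward_project(lab, geom, tab, 65, mats)
  p <- array(li$values[, , 1, 1], c(geom$n_bins, geom$n_views, 1))
  sino <- ctmar:::new_sinogram(p, "line-integral", geom,
                               valid = array(TRUE, dim(p)))
  # empty missing mask: identity
  none <- array(FALSE, dim(p))
  expect_identical(complete_sinogram(sino, none)$values, sino$values)
  # one fully missing view of a smooth disk sinogram
  miss <- none
  miss[, 30, 1] <- TRUE
  out <- complete_sinogram(sino, miss, mar_config())
  rel_rms <- sqrt(mean((out$values[, 30, 1] - p[, 30, 1])^2)) /
    sqrt(mean(p[, 30, 1]^2))
  expect_lt(rel_rms, 0.02)
  # objective non-increasing per iteration
  obj <- out$meta$objective[[1]]
  expect_true(all(diff(obj) <= 1e-9))
  # enforced constraint: every view's 0th moment within 1 percent of Mhat
  ds <- geom$bin_mm / 10
  masses <- colSums(out$values[, , 1]) * ds
  expect_lt(max(abs(masses - out$meta$Mhat[1]) / out$meta$Mhat[1]), 0.01)
  # a fully starved view with fully starved neighbors is unrecoverable
  allmiss <- none
  allmiss[, 29:31, 1] <- TRUE
  allmiss[5, 29, 1] <- FALSE
  allmiss[5, 31, 1] <- FALSE
  expect_error(complete_sinogram(sino, allmiss, mar_config()), NA)
  allmiss2 <- none
  allmiss2[, 29:31, 1] <- TRUE
  expect_error(complete_sinogram(sino, allmiss2, mar_config()),
               "unrecoverable")
})

test_that("the MAR pipeline is a near no-op on metal-free data", {
  f <- fx_acq3_small()
  corr <- mar_pipeline(f$acq$counts, f$acq$image, mar_config(),
                       f$acq$counts$geometry, fx_spectrum(), fx_table(),
                       fx_materials(), fx_eref())
  body <- ctmar:::body_mask_from_spec(f$labels$meta$spec, f$acq$image)
  rms <- sqrt(mean((corr$data[body$data] - f$acq$image$data[body$data])^2))
  expect_lt(rms, 2)
})

test_that("MAR monotonically improves both metal configurations", {
  run <- fx_study()
  for (key in c("lowZ", "highZ")) {
    ds <- run$datasets[[key]]
    region <- ds$body$data & !ds$metal$data
    rmse_unc <- sqrt(mean((ds$uncorrected$data[region] - ds$gt$data[region])^2))
    rmse_cor <- sqrt(mean((ds$corrected$data[region] - ds$gt$data[region])^2))
    expect_lt(rmse_cor, rmse_unc)
  }
  # severity ordering: high-Z artifacts dominate low-Z ones
  sd_u <- function(key) {
    ds <- run$datasets[[key]]
    region <- ds$body$data & !ds$metal$data
    stats::sd(ds$uncorrected$data[region] - ds$gt$data[region])
  }
  expect_gt(sd_u("highZ"), sd_u("lowZ"))
  # metal voxels carry the per-component reinsertion value
  seg <- run$datasets$highZ$corrected$meta$segmentation
  for (cc in seq_along(seg$reinserted_hu)) {
    vox <- run$datasets$highZ$corrected$data[seg$components == cc]
    expect_true(all(vox == seg$reinserted_hu[cc]))
  }
})
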