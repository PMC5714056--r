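test_that("the HU-density calibration is exact at control points and linear between", {
  pts <- data.frame(hu = c(-1000, 0, 1000), density = c(0, 1, 1.6))
  curve <- calibrate_hu_density(pts)
  expect_equal(ctmar:::curve_density(curve, -1000), 0)
  expect_equal(ctmar:::curve_density(curve, 0), 1)
  expect_equal(ctmar:::curve_density(curve, 500), (1 + 1.6) / 2)
  expect_equal(ctmar:::curve_density(curve, 5000), 1.6)   # clamped
  bad <- data.frame(hu = c(-1000, 0, 1000), density = c(0, 1.2, 1.0))
  expect_error(calibrate_hu_density(bad), "monotone")
  expect_error(calibrate_hu_density(data.frame(hu = c(0, 0),
                                               density = c(1, 1))),
               "duplicate")
})

test_that("HU volumes convert voxelwise and preserve monotonicity", {
  mats <- fx_materials(); tab <- fx_table()
  curve <- default_calibration(mats, tab, fx_eref(), metal = "titanium")
  u <- ct_volume(array(0, c(8, 8, 1)), c(1, 1, 1), kind = "HU")
  expect_true(all(hu_to_density(u, curve)$data == 1))
  ramp <- ct_volume(array(seq(-1000, 3000, length.out = 64), c(8, 8, 1)),
                    c(1, 1, 1), kind = "HU")
  d <- hu_to_density(ramp, curve)$data
  expect_true(all(diff(as.numeric(d)) >= 0))
  # ground-truth titanium voxels map to the titanium electron density
  ti <- ct_volume(array(3071, c(2, 2, 1)), c(1, 1, 1), kind = "HU")
  expect_equal(unique(as.numeric(hu_to_density(ti, curve)$data)),
               electron_density(mats$titanium), tolerance = 1e-6)
})

test_that("primary dose follows exponential attenuation and is linear in fluence", {
  tab <- fx_table()
  dens <- ct_volume(array(1, c(80, 80, 1)), c(2.5, 2.5, 2.5),
                    kind = "density")
  ptv <- array(FALSE, dim(dens$data)); ptv[38:42, 38:42, 1] <- TRUE
  plan <- plan_spec(c(0, 72, 144, 216, 288), 10,
                    structure_mask(ptv, dens, "PTV"),
                    beamlet_mm = 5, energy_mev = 2)
  # a single beam with one beamlet through the isocenter
  fl1 <- fluence_map(0, list(0), list(1))
  dose <- compute_dose(dens, plan, fl1, table = tab)
  mu <- ctmar:::mu_eff_water(tab, 2)
  j <- which.max(colSums(dose$data[, , 1]))   # column inside the beamlet strip
  prof <- dose$data[, j, 1]
  on_axis <- which(prof > 0)
  d1 <- on_axis[10]; d2 <- on_axis[40]
  depth_cm <- (d2 - d1) * 0.25
  ratio <- prof[d2] / prof[d1]
  expect_lt(abs(ratio - exp(-mu * depth_cm)) / exp(-mu * depth_cm), 0.01)
  # zero fluence gives zero dose; doubling fluence doubles dose exactly
  fl0 <- structure(list(angles = 0, offsets_cm = list(0), weights = list(0)),
                   class = "fluence_map")
  expect_true(all(compute_dose(dens, plan, fl0, table = tab)$data == 0))
  fl2 <- structure(list(angles = 0, offsets_cm = list(0), weights = list(2)),
                   class = "fluence_map")
  expect_equal(compute_dose(dens, plan, fl2, table = tab)$data, 2 * dose$data)
})

test_that("radiological path matches a dense-sampling line integral", {
  set.seed(9)
  dens2d <- matrix(runif(64 * 64, 0.2, 2), 64, 64)
  dx <- 0.25; g0 <- -8
  for (ang in c(0.3, 1.2, 2.5)) {
    rp <- ctmar:::cpp_radpath(dens2d, dx, dx, g0, g0, ang)
    # oracle: dense sampling along the ray to a probe voxel center
    for (probe in list(c(40, 31), c(20, 50))) {
      x0 <- g0 + (probe[1] - 0.5) * dx
      y0 <- g0 + (probe[2] - 0.5) * dx
      tt <- seq(0, 40, by = 0.002)
      xs <- x0 - cos(ang) * tt
      ys <- y0 - sin(ang) * tt
      ix <- floor((xs - g0) / dx) + 1
      iy <- floor((ys - g0) / dx) + 1
      ok <- ix >= 1 & ix <= 64 & iy >= 1 & iy <= 64
      oracle <- sum(dens2d[cbind(ix[ok], iy[ok])]) * 0.002
      expect_lt(abs(rp[probe[1], probe[2]] - oracle) / oracle, 0.005)
    }
  }
})

test_that("Monte Carlo and primary engines agree on a narrow-beam depth dose", {
  tab <- fx_table()
  dens <- ct_volume(array(1, c(60, 60, 1)), c(5, 5, 5), kind = "density")
  ptv <- array(FALSE, dim(dens$data)); ptv[28:32, 28:32, 1] <- TRUE
  plan <- plan_spec(c(0, 72, 144, 216, 288), 10,
                    structure_mask(ptv, dens, "PTV"), beamlet_mm = 5,
                    energy_mev = 2)
  fl1 <- structure(list(angles = 0, offsets_cm = list(0), weights = list(1)),
                   class = "fluence_map")
  dp <- compute_dose(dens, plan, fl1, mode = "primary", table = tab)
  dm <- compute_dose(dens, plan, fl1, mode = "mc", seed = 11,
                     histories = 2e5, table = tab)
  bal <- dm$meta$energy_balance
  expect_lte(bal["deposited_kev"], bal["emitted_kev"])
  j <- which(colSums(dp$data[, , 1]) > 0)[1]
  axis <- which(dp$data[, j, 1] > 0)
  probe <- axis[c(8, 20, 35)]
  for (i in probe) {
    se <- dm$meta$rel_unc[i, j] * dm$data[i, j, 1]
    expect_lt(abs(dm$data[i, j, 1] - dp$data[i, j, 1]), max(3 * se, 1e-6) +
                0.03 * dp$data[i, j, 1])
  }
})

test_that("beam-angle selection avoids metal and flags unavoidable targets", {
  dens <- ct_volume(array(1, c(96, 96, 1)), c(3, 3, 2.5), kind = "density")
  no_metal <- structure_mask(array(FALSE, dim(dens$data)), dens, "metal")
  ptv <- define_ptv(c(0, 0), 4, dens, "PTV")
  sel <- select_beam_angles(0:359, no_metal, ptv)
  expect_equal(sel$angles, c(0, 72, 144, 216, 288))
  expect_equal(sel$feasibility, "ok")
  # metal strictly north of the target: no beam travelling from the north
  north <- array(FALSE, dim(dens$data))
  n <- 96; xc <- ((1:n) - 48.5) * 0.3
  X <- matrix(xc, n, n); Y <- matrix(xc, n, n, byrow = TRUE)
  north[, , 1][X^2 + (Y - 6)^2 <= 1.5^2] <- TRUE
  selN <- select_beam_angles(0:359, structure_mask(north, dens, "metal"), ptv)
  expect_equal(selN$feasibility, "ok")
  # beams travelling from the metal side propagate along directions near
  # 270 degrees (from +y toward -y); the blocked window subtends the metal
  half_window <- asin(1.5 / 6) * 180 / pi + atan2(2, 6) * 180 / pi
  bad <- abs(((selN$angles - 270 + 180) %% 360) - 180) < half_window - 1
  expect_false(any(bad))
  # PTV overlapping metal is unavoidable
  inptv <- array(FALSE, dim(dens$data))
  inptv[, , 1][X^2 + Y^2 <= 1^2] <- TRUE
  selU <- select_beam_angles(0:359, structure_mask(inptv, dens, "metal"), ptv)
  expect_equal(selU$feasibility, "unavoidable")
  expect_error(select_beam_angles(integer(0), no_metal, ptv), "empty")
})

test_that("fluence optimization delivers the prescription to a water target", {
  # one beamlet with unit influence on the whole target: weight equals the
  # prescription (1-D least squares)
  H <- matrix(2 * 25, 1, 1)
  cvec <- 2 * 25 * 10
  sol <- ctmar:::pg_nnls(H, cvec, iters = 200)
  expect_equal(sol$w, 10, tolerance = 1e-6)
  expect_true(all(diff(sol$objective) <= 1e-8))
  # 5-beam plan on a water cylinder
  tab <- fx_table()
  lab <- build_phantom(water_cylinder(n = 96, spacing_mm = 3,
                                      diameter_cm = 24))
  dens <- ct_volume(array(1, dim(lab$data)), lab$spacing, lab$origin,
                    kind = "density")
  body <- ctmar:::body_mask_from_spec(lab$meta$spec, dens)
  dens$data[!body$data] <- 0.001
  ptv <- define_ptv(c(0, 0), 4, dens, "PTV")
  plan <- plan_spec(c(0, 72, 144, 216, 288), 10, ptv, beamlet_mm = 5)
  fl <- optimize_fluence(dens, plan, body = body, table = tab)
  expect_true(all(unlist(fl$weights) >= 0))
  expect_true(all(diff(attr(fl, "objective")) <= 1e-6))
  dose <- compute_dose(dens, plan, fl, table = tab)
  ptv_dose <- dose$data[ptv$data]
  expect_lt(abs(mean(ptv_dose) - 10) / 10, 0.02)
  expect_lt(stats::sd(ptv_dose) / mean(ptv_dose), 0.05)
})

test_that("plans recompute identically on identical volumes and reject grid mismatch", {
  tab <- fx_table()
  dens <- ct_volume(array(1, c(40, 40, 1)), c(5, 5, 5), kind = "density")
  ptv <- array(FALSE, dim(dens$data)); ptv[18:22, 18:22, 1] <- TRUE
  plan <- plan_spec(c(0, 72, 144, 216, 288), 10,
                    structure_mask(ptv, dens, "PTV"), beamlet_mm = 5)
  fl <- structure(list(angles = plan$angles,
                       offsets_cm = rep(list(c(-0.5, 0, 0.5)), 5),
                       weights = rep(list(c(1, 2, 1)), 5)),
                  class = "fluence_map")
  out <- recompute_plans(fl, plan, list(a = dens, b = dens, c = dens))
  expect_identical(out$a$data, out$b$data)
  expect_identical(out$a$data, out$c$data)
  other <- ct_volume(array(1, c(41, 41, 1)), c(5, 5, 5), kind = "density")
  expect_error(recompute_plans(fl, plan, list(a = dens, b = other)),
               "mismatch")
})
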