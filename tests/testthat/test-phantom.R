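test_that("insert voxelization matches the analytic disk area", {
  lab <- build_phantom(standard_phantom(2, n = 256, spacing_mm = 1.5,
                                        n_slices = 1))
  n_cer <- sum(ctmar:::label_mask(lab, "cerrobend"))
  expected <- 2 * pi * 1.5^2 / (0.15 * 0.15)   # two 3 cm slots
  expect_lt(abs(n_cer - expected) / expected, 0.02)
  # slot-A center voxel is titanium in configuration 1
  lab1 <- build_phantom(standard_phantom(1, n = 256, spacing_mm = 1.5,
                                         n_slices = 1))
  i <- round((-70 - lab1$origin[1]) / lab1$spacing[1] + 0.5)
  j <- round((0 - lab1$origin[2]) / lab1$spacing[2] + 0.5)
  expect_equal(lab1$meta$materials[lab1$data[i, j, 1]], "titanium")
})

test_that("a zero-slot phantom is body material inside and air outside", {
  spec <- phantom_spec(n = 64, spacing_mm = 6, n_slices = 1)
  lab <- build_phantom(spec)
  mats <- lab$meta$materials
  body <- ctmar:::body_mask_from_spec(spec, lab)
  expect_true(all(lab$data[body$data] == match("solid_water", mats)))
  expect_true(all(lab$data[!body$data] == match("air", mats)))
})

test_that("invalid slot layouts are rejected with the offending slots named", {
  slots <- data.frame(name = c("A", "B"), x_cm = c(0, 1), y_cm = c(0, 0),
                      diameter_cm = 3, material = "titanium")
  expect_error(phantom_spec(slots = slots), "A and B overlap")
  out <- data.frame(name = "C", x_cm = 16, y_cm = 0, diameter_cm = 3,
                    material = "titanium")
  expect_error(phantom_spec(slots = out), "outside")
})

test_that("phantom voxelization is deterministic", {
  a <- build_phantom(standard_phantom(1, n = 96, spacing_mm = 4))
  b <- build_phantom(standard_phantom(1, n = 96, spacing_mm = 4))
  expect_identical(a$data, b$data)
})

test_that("ground-truth substitution changes exactly the substituted voxel set", {
  mats <- fx_materials(); tab <- fx_table()
  lab <- build_phantom(standard_phantom(2, n = 96, spacing_mm = 4,
                                        n_slices = 1))
  base <- ct_volume(array(0, dim(lab$data)), lab$spacing, lab$origin, "HU")
  gt0 <- make_ground_truth(base, lab, list(), tab, 65)
  expect_identical(gt0$data, base$data)
  gtA <- make_ground_truth(base, lab, list(A = mats$titanium), tab, 65)
  diff_set <- which(gtA$data != base$data)
  expect_identical(sort(diff_set), sort(which(ctmar:::slot_mask(lab, "A"))))
  # substituted Cerrobend voxels saturate at the clamp
  gtC <- make_ground_truth(base, lab, list(A = mats$cerrobend), tab, 65)
  expect_true(all(gtC$data[ctmar:::slot_mask(lab, "A")] == 3071))
  expect_error(make_ground_truth(base, lab, list(Z = mats$titanium), tab, 65),
               "not defined")
})

test_that("PTV presets have the analytic area and the stated metal overlaps", {
  lab <- build_phantom(standard_phantom(2, n = 256, spacing_mm = 1.5,
                                        n_slices = 1))
  metal <- ctmar:::label_mask(lab, "cerrobend")
  areas <- integer(3)
  for (p in c("PTV1", "PTV2", "PTV3")) {
    m <- preset_ptv(p, lab)
    areas[match(p, c("PTV1", "PTV2", "PTV3"))] <- sum(m$data)
    expected <- pi * 2^2 / (0.15 * 0.15)
    expect_lt(abs(sum(m$data) - expected) / expected, 0.02)
  }
  expect_gt(sum(preset_ptv("PTV3", lab)$data & metal), 0)
  expect_equal(sum(preset_ptv("PTV1", lab)$data & metal), 0)
  expect_equal(sum(preset_ptv("PTV2", lab)$data & metal), 0)
  # preset volumes agree within one voxel per slice
  expect_lte(max(areas) - min(areas), dim(lab$data)[3])
  expect_error(define_ptv(c(50, 50), 4, lab), "misses")
})
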