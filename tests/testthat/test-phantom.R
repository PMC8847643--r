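# Digital thorax phantom: rasterization accuracy and geometry measurement

ph3 <- function() fixture("ph3", function()
  build_thorax_phantom(phantom_spec(ptv_width_cm = 6, ptv_length_cm = 18,
                                    spacing_mm = 3)))

test_that("PTV rasterizes to the analytic elliptic-cylinder volume", {
  st <- ph3()
  analytic <- pi * (6 / 2) * (7.5 / 2) * 18
  expect_lt(abs(mask_volume_cm3(st, "PTV") - analytic) / analytic, 0.03)
})

test_that("measured E, Lt, T recover the construction within one voxel", {
  st <- ph3()
  g <- measure_geometry(st)
  expect_lt(abs(g$E_cm - 6), 0.3 + 1e-9)
  expect_lt(abs(g$Lt_cm - 18), 0.3 + 1e-9)
  expect_lt(abs(g$T_cm - 30), 0.3 + 1e-9)
  expect_equal(g$V_W_cm3, mask_volume_cm3(st, "LUNG_WHOLE"))
})

test_that("measurement error shrinks at least linearly with voxel size", {
  # incommensurate dimensions so neither lattice hits the surfaces exactly
  spec_at <- function(sp) phantom_spec(ptv_width_cm = 6.472,
                                       ptv_length_cm = 17.386,
                                       body_semiaxes_cm = c(14.711, 10),
                                       spacing_mm = sp)
  err <- function(sp) {
    g <- measure_geometry(build_thorax_phantom(spec_at(sp)))
    c(abs(g$E_cm - 6.472), abs(g$Lt_cm - 17.386), abs(g$T_cm - 2 * 14.711))
  }
  e3 <- err(3); e15 <- err(1.5)
  expect_true(all(e3 <= 0.3 + 1e-9))
  expect_true(all(e15 <= pmax(e3 / 2, 0.15) + 1e-9))
})

test_that("rebuilding with the same spec and seed is bit-identical", {
  spec <- phantom_spec(spacing_mm = 6, jitter_cm = 0.3, seed = 42L)
  a <- build_thorax_phantom(spec)
  b <- build_thorax_phantom(spec)
  expect_identical(a$masks, b$masks)
  # a different seed produces a different anatomy
  d <- build_thorax_phantom(phantom_spec(spacing_mm = 6, jitter_cm = 0.3,
                                         seed = 43L))
  expect_false(identical(a$masks, d$masks))
})

test_that("zero lung semi-axes give V_W = 0 and the solver rejects it", {
  st <- build_thorax_phantom(phantom_spec(lung_semiaxes_cm = c(0, 0, 0),
                                          spacing_mm = 6))
  g <- measure_geometry(st)
  expect_equal(g$V_W_cm3, 0)
  expect_error(solve_opa_angle(g), "V_W")
})

test_that("impossible geometry (target wider than body) is rejected", {
  expect_error(phantom_spec(ptv_width_cm = 31), "wider than the body")
  st <- coarse_phantom()
  st$masks$PTV[] <- FALSE
  expect_error(measure_geometry(st), "PTV")
})

test_that("lungs fully inside the field slab give V_OW = 0", {
  st <- build_thorax_phantom(
    phantom_spec(lung_semiaxes_cm = c(5.5, 7.5, 8), ptv_length_cm = 18,
                 spacing_mm = 6))
  expect_equal(measure_geometry(st, field_margin_cm = 2)$V_OW_cm3, 0)
})

test_that("out-of-field lung volume matches the analytic ellipsoid caps", {
  # lungs reach 5 cm beyond each field edge: cap above z0 = Lt/2 + margin
  sp <- 0.25   # cm; chosen so the target surface falls on voxel centres
  a <- 4; b <- 5; cc <- 12; Lt <- 10; margin <- 2
  st <- build_thorax_phantom(
    phantom_spec(ptv_length_cm = Lt, lung_semiaxes_cm = c(a, b, cc),
                 spacing_mm = 10 * sp))
  g <- measure_geometry(st, field_margin_cm = margin)
  # half-voxel-corrected slab edge: PTV centre extent + margin + half voxel
  z0 <- (Lt / 2) + margin + sp / 2
  t <- z0 / cc
  cap <- pi * a * b * cc * (2 / 3 - t + t^3 / 3)
  analytic <- 4 * cap                      # two lungs, two ends
  expect_lt(abs(g$V_OW_cm3 - analytic) / analytic, 0.03)
})

test_that("V_OW is non-increasing as the field margin grows", {
  st <- ph3()
  v <- vapply(c(0, 1, 2, 3, 5, 8),
              function(m) measure_geometry(st, field_margin_cm = m)$V_OW_cm3,
              numeric(1))
  expect_true(all(diff(v) <= 1e-9))
})

test_that("volumes and measurements survive a rigid anatomy translation", {
  base <- phantom_spec(spacing_mm = 4)
  shifted <- phantom_spec(center_offset_cm = c(0.17, -0.23, 0.11),
                          spacing_mm = 4)
  g0 <- measure_geometry(build_thorax_phantom(base))
  g1 <- measure_geometry(build_thorax_phantom(shifted))
  expect_lt(abs(g1$V_W_cm3 - g0$V_W_cm3) / g0$V_W_cm3, 0.01)
  expect_lt(abs(g1$E_cm - g0$E_cm), 0.4 + 1e-9)
  expect_lt(abs(g1$Lt_cm - g0$Lt_cm), 0.4 + 1e-9)
})

test_that("bounding-box extent mode is available for concave targets", {
  st <- ph3()
  g1 <- measure_geometry(st)
  g2 <- measure_geometry(st, extent_mode = "bounding_box")
  # the convex default phantom gives the same answer either way
  expect_equal(g1$E_cm, g2$E_cm)
  expect_equal(g1$Lt_cm, g2$Lt_cm)
})
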