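# DVH construction, V_x / D_x interpolation, HI / CI, constraint verdicts

mk_grid <- function(vals, spacing = 4) {
  if (is.null(dim(vals))) vals <- array(vals, c(length(vals), 1, 1))
  volume_grid(vals, spacing_mm = spacing)
}

test_that("a uniform structure gives a step-function DVH", {
  dose <- mk_grid(rep(10, 200))
  mask <- array(TRUE, dim(dose$values))
  dvh <- compute_dvh(dose, mask, bin_width_gy = 0.05)
  expect_equal(dvh$volume_pct[dvh$dose_gy <= 10], rep(100, 201))
  expect_equal(dvh$volume_pct[dvh$dose_gy > 10], 0)
  expect_equal(V_at_dose(dvh, 5), 100)
  expect_equal(V_at_dose(dvh, 0), 100)
})

test_that("a half-4 / half-6 Gy structure has V5 = 50%", {
  dose <- mk_grid(c(rep(4, 100), rep(6, 100)))
  dvh <- compute_dvh(dose, array(TRUE, dim(dose$values)))
  expect_equal(V_at_dose(dvh, 5), 50)
  expect_equal(V_at_dose(dvh, 20), 0)   # dose capped below 20
})

test_that("V_x matches brute-force voxel counting within one bin", {
  set.seed(21)
  vals <- array(rgamma(24^3, shape = 2, scale = 6), c(24, 24, 24))
  dose <- volume_grid(vals, spacing_mm = 3)
  mask <- array(stats::runif(24^3) < 0.4, c(24, 24, 24))
  dvh <- compute_dvh(dose, mask, bin_width_gy = 0.05)
  for (x in c(5, 10, 15, 20)) {
    brute <- 100 * mean(vals[mask] >= x)
    expect_lt(abs(V_at_dose(dvh, x) - brute), 0.05 / 0.05 * 0.5)
    # refining the bins reproduces the interpolated value closely
    fine <- compute_dvh(dose, mask, bin_width_gy = 0.01)
    expect_lt(abs(V_at_dose(dvh, x) - V_at_dose(fine, x)), 0.1)
  }
})

test_that("D_x inverts the cumulative curve", {
  dose <- mk_grid(rep(45, 500))
  dvh <- compute_dvh(dose, array(TRUE, dim(dose$values)))
  expect_equal(D_at_volume(dvh, 95), 45, tolerance = 0.051)
  expect_equal(D_at_volume(dvh, 100), 45, tolerance = 0.051)

  # linear ramp 40 -> 50 Gy with uniform volume per dose
  ramp <- mk_grid(seq(40, 50, length.out = 4001))
  dvh_r <- compute_dvh(ramp, array(TRUE, dim(ramp$values)),
                       bin_width_gy = 0.05)
  expect_equal(D_at_volume(dvh_r, 5), 49.5, tolerance = 0.06)
  expect_equal(D_at_volume(dvh_r, 95), 40.5, tolerance = 0.06)
  expect_equal(D_at_volume(dvh_r, 100), 40, tolerance = 0.06)
  expect_error(D_at_volume(dvh_r, 0), "volume_pct")
})

test_that("V_x and D_x are mutually consistent on decreasing curves", {
  set.seed(5)
  vals <- array(stats::rnorm(20^3, 30, 8), c(20, 20, 20))
  vals[vals < 0] <- 0
  dose <- volume_grid(vals, spacing_mm = 3)
  dvh <- compute_dvh(dose, array(TRUE, dim(vals)), bin_width_gy = 0.05)
  for (d in c(10, 20, 30, 40)) {
    v <- V_at_dose(dvh, d)
    if (v <= 0 || v >= 100) next
    expect_lt(abs(D_at_volume(dvh, v) - d), 0.05 + 1e-9)
  }
})

test_that("HI and CI are exactly 1 on the ideal conformal uniform plan", {
  st <- fixture("ph6", function() coarse_phantom(6))
  dose <- uniform_dose(st, st$masks$PTV, 45)
  dvh <- compute_dvh(dose, st$masks$PTV)
  hi <- homogeneity_index(dvh)
  expect_equal(as.numeric(hi), 1, tolerance = 0.002)
  expect_true(attr(hi, "acceptable"))
  ci <- conformity_index(dose, st$masks$PTV, 45)
  expect_equal(as.numeric(ci), 1)
  expect_true(attr(ci, "acceptable"))
})

test_that("HI on the 40-50 Gy ramp equals the closed form 49.5 / 40.5", {
  ramp <- mk_grid(seq(40, 50, length.out = 4001))
  dvh <- compute_dvh(ramp, array(TRUE, dim(ramp$values)))
  expect_equal(as.numeric(homogeneity_index(dvh)), 49.5 / 40.5,
               tolerance = 0.005)
})

test_that("CI counts the reference isodose volume anywhere in the grid", {
  st <- fixture("ph6", function() coarse_phantom(6))
  # dose >= Rx exactly on the PTV plus an equal-volume shell -> CI = 2
  vals <- array(0, st$shape)
  vals[st$masks$PTV] <- 45
  extra <- which(!st$masks$PTV)[seq_len(sum(st$masks$PTV))]
  vals[extra] <- 45
  dose <- volume_grid(vals, spacing_mm = st$spacing, origin_mm = st$origin)
  expect_equal(as.numeric(conformity_index(dose, st$masks$PTV, 45)), 2)
  # brute-force voxel counting on a simulated plan
  sim <- simulate_dose(st, sequence_opa_arcs(140))
  ci <- conformity_index(sim, st$masks$PTV, 45)
  expect_equal(as.numeric(ci),
               sum(sim$values >= 45) / sum(st$masks$PTV))
})

test_that("constraint verdicts honour comparator semantics", {
  m <- data.frame(
    structure = c("CORD", "HEART", "HEART", "LUNG_WHOLE"),
    metric = c("max_gy", "mean_gy", "V40_pct", "V5_pct"),
    value = c(36.92, 20.76, 50, 55))
  tab <- default_constraint_table()
  tab <- tab[paste(tab$structure, tab$metric) %in%
               paste(m$structure, m$metric), ]
  v <- evaluate_constraints(m, tab)
  get <- function(s, met) v$pass[v$structure == s & v$metric == met]
  expect_true(get("CORD", "max_gy"))          # 36.92 < 45
  expect_true(get("LUNG_WHOLE", "V5_pct"))    # 55 <= 55: boundary passes
  expect_false(get("HEART", "V40_pct"))       # 50 < 50 fails: strict
  expect_false(attr(v, "overall_pass"))
})

test_that("a missing metric is an explicit error, not a silent pass", {
  m <- data.frame(structure = "CORD", metric = "max_gy", value = 30)
  expect_error(evaluate_constraints(m), "missing metric")
})

test_that("an empty mask names the offending structure", {
  dose <- mk_grid(rep(1, 10))
  expect_error(compute_dvh(dose, array(FALSE, dim(dose$values)),
                           structure = "HEART"), "HEART")
})
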