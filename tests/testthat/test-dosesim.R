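# Parallel-beam arc-dose simulator: control points, depth attenuation,
# aperture geometry and the voxel-level restricted fraction

ph6 <- function() fixture("ph6", function() coarse_phantom(6))

test_that("control points tile each arc at the requested spacing", {
  cp <- control_points(sequence_full_arcs(), 4)
  expect_equal(sum(cp$arc == 1), 91L)   # 0,4,...,356 plus the 359 stop
  expect_equal(sum(cp$arc == 2), 91L)
  # every control point lies inside its arc's sector
  plan <- sequence_full_arcs()
  for (i in 1:2) {
    a <- plan$arcs[i, ]
    d <- if (a$direction == "CW") (cp$angle[cp$arc == i] - a$start) %% 360
         else (a$start - cp$angle[cp$arc == i]) %% 360
    expect_true(all(d <= arc_span(a$start, a$stop, a$direction) + 1e-9))
  }
})

test_that("partial-arc control points stay inside the treated sectors", {
  th <- 110
  cp <- control_points(sequence_opa_arcs(th), 4)
  ang <- cp$angle
  in_anterior <- pmin(ang, 360 - ang) <= th / 4 + 1e-9
  in_posterior <- abs(ang - 180) <= th / 4 + 1e-9
  expect_true(all(in_anterior | in_posterior))
})

test_that("spacing wider than the arc span leaves only the endpoints", {
  plan <- sequence_opa_arcs(110)
  cp <- control_points(plan, 400)
  expect_equal(as.integer(table(cp$arc)), rep(2L, 6))
  expect_equal(cp$angle[cp$arc == 1], c(180, 207.5))
})

test_that("a single anterior beam attenuates monotonically with depth", {
  st <- ph6()
  # a 2-degree sliver of arc straddling the anterior axis
  plan <- sequence_full_arcs()
  plan$arcs <- data.frame(start = c(359, 1), stop = c(1, 359),
                          direction = c("CW", "CCW"),
                          collimator_offset = c(0, 5))
  dose <- simulate_dose(st, plan, beam_model(control_point_spacing_deg = 1))
  mid <- (st$shape + 1) %/% 2
  column <- dose$values[mid[1], , mid[3]]
  inside <- which(st$masks$BODY[mid[1], , mid[3]] & column > 0)
  # beam enters anteriorly (+y); dose must fall towards posterior
  profile <- column[inside][order(inside, decreasing = TRUE)]
  expect_true(all(diff(profile) <= 1e-9))
})

test_that("full rotation on a circular thorax is azimuthally uniform", {
  st <- build_thorax_phantom(
    phantom_spec(body_semiaxes_cm = c(12, 12), lung_offset_cm = 6.5,
                 lung_semiaxes_cm = c(4.5, 6, 11), spacing_mm = 6))
  dose <- simulate_dose(st, sequence_full_arcs())
  idx <- which(st$masks$LUNG_WHOLE)
  ijk <- arrayInd(idx, st$shape)
  x <- voxel_centers_cm(st, 1)[ijk[, 1]]
  y <- voxel_centers_cm(st, 2)[ijk[, 2]]
  z <- voxel_centers_cm(st, 3)[ijk[, 3]]
  r <- sqrt(x^2 + y^2)
  shell <- r > 6 & r < 7 & abs(z) < 5
  d <- dose$values[idx][shell]
  expect_gt(length(d), 50)
  expect_lt(stats::sd(d) / mean(d), 0.15)
})

test_that("lung voxels outside all apertures receive exactly zero dose", {
  st <- ph6()
  plan <- sequence_opa_arcs(80)
  dose <- simulate_dose(st, plan)
  idx <- which(st$masks$LUNG_WHOLE)
  ijk <- arrayInd(idx, st$shape)
  x <- voxel_centers_cm(st, 1)[ijk[, 1]]
  y <- voxel_centers_cm(st, 2)[ijk[, 2]]
  lateral <- abs(x) > 9.5 & abs(y) < 1.5   # far outside the narrow sectors
  expect_gt(sum(lateral), 10)
  expect_true(all(dose$values[idx][lateral] == 0))
})

test_that("doubling control-point density changes mean doses by < 1%", {
  st <- ph6()
  mean_doses <- function(spacing) {
    d <- simulate_dose(st, sequence_opa_arcs(140),
                       beam_model(control_point_spacing_deg = spacing))
    vapply(c("PTV", "LUNG_WHOLE", "HEART"),
           function(nm) mean(d$values[st$masks[[nm]]]), numeric(1))
  }
  m4 <- mean_doses(4); m2 <- mean_doses(2)
  expect_true(all(abs(m2 - m4) / m4 < 0.01))
})

test_that("lung V5 is non-increasing as the arc angle shrinks", {
  st <- ph6()
  v5 <- function(th) {
    plan <- if (th >= 360) sequence_full_arcs() else sequence_opa_arcs(th)
    V_at_dose(compute_dvh(simulate_dose(st, plan), st$masks$LUNG_WHOLE), 5)
  }
  v <- vapply(c(360, 310, 240, 180, 110, 80), v5, numeric(1))
  expect_true(all(diff(v) <= 1e-6))
})

test_that("a full rotation leaves no in-slab lung unirradiated", {
  st <- build_thorax_phantom(
    phantom_spec(lung_semiaxes_cm = c(5.5, 7.5, 8), ptv_length_cm = 18,
                 spacing_mm = 6))
  frac <- geometric_unirradiated_fraction(st, sequence_full_arcs())
  expect_lt(frac, 0.01)
})

test_that("a vanishing arc spares the lateral lung entirely", {
  st <- ph6()
  frac <- geometric_unirradiated_fraction(st, sequence_opa_arcs(8))
  # only the narrow anterior/posterior corridors are treated; nearly all
  # lateral lung escapes
  expect_gt(frac, 0.75)
})

test_that("solver angle delivers the expected restricted fraction on the
           cylinder idealization", {
  st <- build_cylinder_phantom(spacing_mm = 3)
  g <- measure_geometry(st, field_margin_cm = 0)
  res <- solve_opa_angle(g, margin_total_cm = 0)
  expect_identical(res$feasible, "OK")
  frac <- geometric_unirradiated_fraction(
    st, sequence_opa_arcs(res$theta_A), beam_model(aperture_margin_cm = 0))
  expect_gt(frac, 1 - g$expected_V5 - 0.05)
})

test_that("empty body or target is rejected before simulation", {
  st <- ph6()
  st2 <- st; st2$masks$PTV[] <- FALSE
  expect_error(simulate_dose(st2, sequence_full_arcs()), "PTV")
})
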