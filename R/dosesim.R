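#' Simple arc-beam model
#'
#' Parameters of the deliberately simple forward dose model used to exercise
#' the planning chain: at each control point a parallel beam travels along
#' the gantry direction, depositing `exp(-mu * depth)` of relative dose at
#' depth `depth` (cm) inside the body, inside a beam's-eye-view aperture
#' equal to the target projection dilated by `aperture_margin_cm`. Beams are
#' parallel (not divergent) and the body is homogeneous unit-density; scatter
#' outside the aperture is taken as zero.
#'
#' @param mu_per_cm Linear attenuation coefficient, 1/cm (megavoltage order
#'   of magnitude by default).
#' @param aperture_margin_cm Beam's-eye-view dilation of the target
#'   projection, cm; equals the 2 cm field border used by the angle solver.
#' @param control_point_spacing_deg Gantry angle step between control points.
#' @param normalization `"PTV_MEAN"` scales the summed dose so the target
#'   mean equals the prescription; `"PTV_D95"` scales so 95% of the target
#'   receives at least the prescription.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(mu_per_cm = 0.05, aperture_margin_cm = 2,
                       control_point_spacing_deg = 4,
                       normalization = c("PTV_MEAN", "PTV_D95")) {
  if (mu_per_cm <= 0) stop("mu_per_cm must be positive")
  if (aperture_margin_cm < 0) stop("aperture_margin_cm must be >= 0")
  if (control_point_spacing_deg <= 0)
    stop("control_point_spacing_deg must be positive")
  structure(list(mu_per_cm = mu_per_cm,
                 aperture_margin_cm = aperture_margin_cm,
                 control_point_spacing_deg = control_point_spacing_deg,
                 normalization = match.arg(normalization)),
            class = "beam_model")
}

#' Prescription
#'
#' @param total_dose_gy Total prescribed dose, Gy.
#' @param fractions Number of fractions.
#' @return An object of class `plan_spec`; the dose per fraction is derived
#'   as `total_dose_gy / fractions`.
#' @examples
#' plan_spec()$dose_per_fraction_gy   # 1.8
#' @export
plan_spec <- function(total_dose_gy = 45, fractions = 25) {
  if (total_dose_gy <= 0 || fractions < 1)
    stop("prescription must be positive with at least one fraction")
  structure(list(total_dose_gy = total_dose_gy,
                 fractions = as.integer(fractions),
                 dose_per_fraction_gy = total_dose_gy / fractions),
            class = "plan_spec")
}

#' Control-point gantry angles of a plan
#'
#' Walks each arc from start to stop in its rotation direction at the given
#' spacing, always including both endpoints (a shorter final step covers any
#' remainder).
#'
#' @param plan An `arc_plan`.
#' @param spacing_deg Control-point spacing in degrees; defaults to the
#'   spacing carried on the plan.
#' @return A data frame with columns `arc` (arc index) and `angle`
#'   (degrees, normalized to `[0, 360)`).
#' @export
control_points <- function(plan, spacing_deg = plan$gantry_spacing) {
  stopifnot(inherits(plan, "arc_plan"))
  if (spacing_deg <= 0) stop("spacing_deg must be positive")
  out <- lapply(seq_len(nrow(plan$arcs)), function(i) {
    a <- plan$arcs[i, ]
    span <- arc_span(a$start, a$stop, a$direction)
    steps <- seq(0, span, by = spacing_deg)
    if (steps[length(steps)] < span - 1e-9) steps <- c(steps, span)
    sgn <- if (a$direction == "CW") 1 else -1
    data.frame(arc = i,
               angle = normalize_gantry_angle(a$start + sgn * steps))
  })
  do.call(rbind, out)
}

# Shared beam's-eye-view machinery ------------------------------------------
#
# Beams are parallel rays in the axial plane. For gantry angle g the source
# direction is u = (sin g, cos g) (0 deg anterior, 90 deg patient-left); a
# voxel's along-beam coordinate is s = x ux + y uy and its lateral
# coordinate l = x uy - y ux. The aperture is a 2-D occupancy grid over
# (l-bin, z-slice) built from the target projection and dilated by the
# aperture margin (elliptical in index space when voxels are anisotropic).

.bev_setup <- function(structs, beam) {
  sp <- structs$spacing / 10                     # cm
  xs <- voxel_centers_cm(structs, 1)
  ys <- voxel_centers_cm(structs, 2)
  dims <- structs$shape
  if (!any(structs$masks$BODY)) stop("empty BODY mask")
  if (!any(structs$masks$PTV)) stop("empty PTV mask")
  bi <- arrayInd(which(structs$masks$BODY), dims)
  pv <- arrayInd(which(structs$masks$PTV), dims)
  dl <- min(sp[1:2])
  xb <- xs[bi[, 1]]; yb <- ys[bi[, 2]]
  L0 <- max(sqrt(xb^2 + yb^2)) + beam$aperture_margin_cm + 2 * dl
  nl <- as.integer(ceiling(2 * L0 / dl)) + 3L
  rl <- beam$aperture_margin_cm / dl
  rz <- beam$aperture_margin_cm / sp[3]
  off <- expand.grid(a = seq.int(-floor(rl), floor(rl)),
                     b = seq.int(-floor(rz), floor(rz)))
  keep <- (off$a / max(rl, 1e-9))^2 + (off$b / max(rz, 1e-9))^2 <= 1 + 1e-12
  off <- off[keep, , drop = FALSE]
  list(sp = sp, dims = dims, dl = dl, L0 = L0, nl = nl, nz = dims[3],
       off = off,
       body_lin = which(structs$masks$BODY),
       xb = xb, yb = yb, kb = bi[, 3],
       xp = xs[pv[, 1]], yp = ys[pv[, 2]], kp = pv[, 3])
}

.bev_bin <- function(st, l)
  pmin(pmax(as.integer(floor((l + st$L0) / st$dl)) + 1L, 1L), st$nl)

# Dilated aperture occupancy matrix (nl x nz) for one gantry angle
.bev_aperture <- function(st, angle_deg) {
  th <- angle_deg * pi / 180
  ux <- sin(th); uy <- cos(th)
  M <- matrix(FALSE, st$nl, st$nz)
  M[cbind(.bev_bin(st, st$xp * uy - st$yp * ux), st$kp)] <- TRUE
  if (nrow(st$off) <= 1L) return(M)
  Md <- matrix(FALSE, st$nl, st$nz)
  nl <- st$nl; nz <- st$nz
  for (r in seq_len(nrow(st$off))) {
    a <- st$off$a[r]; b <- st$off$b[r]
    i <- max(1L, 1L + a):min(nl, nl + a)
    j <- max(1L, 1L + b):min(nz, nz + b)
    Md[i, j] <- Md[i, j] | M[i - a, j - b]
  }
  Md
}

# Collapse control points to unique angles, each carrying a trapezoidal
# quadrature weight (degrees of arc represented), so an uneven final step
# does not bias the dose integral
.angle_table <- function(plan, spacing_deg) {
  ang <- numeric(0); wt <- numeric(0)
  for (i in seq_len(nrow(plan$arcs))) {
    a <- plan$arcs[i, ]
    span <- arc_span(a$start, a$stop, a$direction)
    steps <- seq(0, span, by = spacing_deg)
    if (steps[length(steps)] < span - 1e-9) steps <- c(steps, span)
    m <- length(steps)
    w <- if (m == 1L) span else
      (c(steps[-1], steps[m]) - c(steps[1], steps[-m])) / 2
    sgn <- if (a$direction == "CW") 1 else -1
    ang <- c(ang, normalize_gantry_angle(a$start + sgn * steps))
    wt <- c(wt, w)
  }
  key <- round(ang, 6)
  tot <- rowsum(wt, key)
  list(angle = as.numeric(rownames(tot)), mult = as.numeric(tot))
}

#' Accumulate dose over an arc plan
#'
#' Forward-simulates the plan on the structure set with the parallel-beam
#' model of [beam_model()]: each control point deposits exponentially
#' attenuated dose inside its beam's-eye-view aperture, the contributions are
#' summed, and the total is scaled so the normalization statistic of the
#' target equals the prescription. Deterministic.
#'
#' @param structs A [structure_set()] with non-empty `BODY` and `PTV`.
#' @param plan An `arc_plan`.
#' @param beam A [beam_model()].
#' @param rx A [plan_spec()].
#' @return A [volume_grid()] of dose in Gy on the structure lattice.
#' @export
simulate_dose <- function(structs, plan, beam = beam_model(),
                          rx = plan_spec()) {
  stopifnot(inherits(structs, "structure_set"), inherits(plan, "arc_plan"))
  st <- .bev_setup(structs, beam)
  at <- .angle_table(plan, beam$control_point_spacing_deg)
  nb <- length(st$body_lin)
  dose_b <- numeric(nb)
  key_cells <- st$nl * st$nz
  for (ia in seq_along(at$angle)) {
    th <- at$angle[ia] * pi / 180
    ux <- sin(th); uy <- cos(th)
    Md <- .bev_aperture(st, at$angle[ia])
    lb <- .bev_bin(st, st$xb * uy - st$yb * ux)
    inap <- Md[cbind(lb, st$kb)]
    if (!any(inap)) next
    s <- st$xb * ux + st$yb * uy
    key <- lb + st$nl * (st$kb - 1L)
    ord <- order(s)                       # last write per key = entry coord
    smax <- numeric(key_cells)
    smax[key[ord]] <- s[ord]
    idx <- which(inap)
    depth <- smax[key[idx]] - s[idx]
    dose_b[idx] <- dose_b[idx] +
      at$mult[ia] * exp(-beam$mu_per_cm * depth)
  }
  dose <- array(0, st$dims)
  dose[st$body_lin] <- dose_b
  dptv <- dose[structs$masks$PTV]
  stat <- switch(beam$normalization,
                 PTV_MEAN = mean(dptv),
                 PTV_D95 = stats::quantile(dptv, 0.05, names = FALSE))
  if (!is.finite(stat) || stat <= 0)
    stop("cannot normalize: target receives no dose under this plan")
  volume_grid(dose * (rx$total_dose_gy / stat),
              spacing_mm = structs$spacing, origin_mm = structs$origin)
}

#' Fraction of lung never traversed by any beam aperture
#'
#' Counts the lung voxels that fall inside no control point's beam's-eye-view
#' aperture over the whole plan; the returned fraction of the whole-lung
#' volume is the voxel-level counterpart of the cylinder model's restricted
#' fraction (the angle solver's geometric premise).
#'
#' @inheritParams simulate_dose
#' @return Fraction in `[0, 1]`.
#' @export
geometric_unirradiated_fraction <- function(structs, plan,
                                            beam = beam_model()) {
  stopifnot(inherits(structs, "structure_set"), inherits(plan, "arc_plan"))
  lung <- structs$masks$LUNG_WHOLE
  if (!any(lung)) stop("empty LUNG_WHOLE mask")
  st <- .bev_setup(structs, beam)
  li <- arrayInd(which(lung), structs$shape)
  xs <- voxel_centers_cm(structs, 1)
  ys <- voxel_centers_cm(structs, 2)
  xl <- xs[li[, 1]]; yl <- ys[li[, 2]]; kl <- li[, 3]
  hit <- logical(nrow(li))
  at <- .angle_table(plan, beam$control_point_spacing_deg)
  for (ia in seq_along(at$angle)) {
    th <- at$angle[ia] * pi / 180
    ux <- sin(th); uy <- cos(th)
    Md <- .bev_aperture(st, at$angle[ia])
    todo <- which(!hit)
    if (!length(todo)) break
    lb <- .bev_bin(st, xl[todo] * uy - yl[todo] * ux)
    hit[todo] <- Md[cbind(lb, kl[todo])]
  }
  mean(!hit)
}
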