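#' Parameter set for the digital thorax phantom
#'
#' Describes an idealized thorax built from quadric solids: an elliptic-
#' cylinder body, two lateral ellipsoidal lungs, a central mediastinal
#' elliptic-cylinder target (PTV), an ellipsoidal heart and a cylindrical
#' spinal cord. All lengths are in cm; the voxel size is in mm. Defaults
#' emulate a mid-thoracic esophageal case: a 30 cm wide thorax, a 7 cm wide
#' and 18 cm long central target (target lengths of 6-25 cm are clinically
#' typical) and a combined lung volume of roughly 4.5 L.
#'
#' With `jitter_cm > 0` the solid centres and semi-axes are perturbed by
#' zero-mean Gaussian noise (SD `jitter_cm`) drawn from `seed`, so cohorts of
#' distinct but reproducible phantoms can be generated.
#'
#' @param body_semiaxes_cm Body ellipse semi-axes (x = lateral,
#'   y = anterior-posterior), cm.
#' @param lung_offset_cm Lateral distance from midline to each lung centre, cm.
#' @param lung_semiaxes_cm Lung ellipsoid semi-axes (x, y, z), cm.
#' @param ptv_width_cm Target width E (left-right), cm.
#' @param ptv_depth_cm Target anterior-posterior depth, cm.
#' @param ptv_length_cm Target axial length Lt (superior-inferior), cm.
#' @param heart_center_cm,heart_semiaxes_cm Heart ellipsoid placement, cm.
#' @param cord_center_ap_cm,cord_radius_cm Spinal-cord cylinder placement, cm.
#' @param center_offset_cm Rigid translation of the whole anatomy relative to
#'   the lattice (x, y, z), cm; useful for decentring studies.
#' @param spacing_mm Voxel size, mm (scalar or length 3).
#' @param jitter_cm SD of the optional boundary jitter, cm (0 = none).
#' @param seed Integer seed for the jitter draws.
#' @param pad_cm Air margin added around the body when sizing the lattice, cm.
#' @return An object of class `phantom_spec`.
#' @seealso [build_thorax_phantom()], [measure_geometry()]
#' @export
phantom_spec <- function(body_semiaxes_cm = c(15, 10),
                         lung_offset_cm = 7.5,
                         lung_semiaxes_cm = c(5.5, 7.5, 13),
                         ptv_width_cm = 7,
                         ptv_depth_cm = 7.5,
                         ptv_length_cm = 18,
                         heart_center_cm = c(2, 2, -6),
                         heart_semiaxes_cm = c(4, 4, 4.5),
                         cord_center_ap_cm = -7.5,
                         cord_radius_cm = 0.6,
                         center_offset_cm = c(0, 0, 0),
                         spacing_mm = 3,
                         jitter_cm = 0,
                         seed = 1L,
                         pad_cm = 1) {
  spec <- list(body_semiaxes_cm = as.numeric(body_semiaxes_cm),
               lung_offset_cm = lung_offset_cm,
               lung_semiaxes_cm = as.numeric(lung_semiaxes_cm),
               ptv_width_cm = ptv_width_cm,
               ptv_depth_cm = ptv_depth_cm,
               ptv_length_cm = ptv_length_cm,
               heart_center_cm = as.numeric(heart_center_cm),
               heart_semiaxes_cm = as.numeric(heart_semiaxes_cm),
               cord_center_ap_cm = cord_center_ap_cm,
               cord_radius_cm = cord_radius_cm,
               center_offset_cm = as.numeric(center_offset_cm),
               spacing_mm = as.numeric(spacing_mm),
               jitter_cm = jitter_cm,
               seed = as.integer(seed),
               pad_cm = pad_cm)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(body_semiaxes_cm <= 0))
      stop("body semi-axes must be positive")
    if (ptv_width_cm <= 0 || ptv_depth_cm <= 0 || ptv_length_cm <= 0)
      stop("PTV dimensions must be positive")
    if (ptv_width_cm >= 2 * body_semiaxes_cm[1])
      stop("impossible geometry: PTV wider than the body")
    if (ptv_depth_cm >= 2 * body_semiaxes_cm[2])
      stop("impossible geometry: PTV deeper than the body")
    if (any(lung_semiaxes_cm < 0))
      stop("lung semi-axes must be non-negative")
    if (any(spacing_mm <= 0))
      stop("voxel spacing must be positive")
  })
  invisible(spec)
}

#' Build the digital thorax phantom
#'
#' Rasterizes the solids described by a [phantom_spec()] onto a centred
#' lattice and returns the named binary masks (`BODY`, `LUNG_L`, `LUNG_R`,
#' `LUNG_WHOLE`, `PTV`, `HEART`, `CORD`). Every organ mask is clipped to the
#' body. The lattice is sized from the body extent, the lungs and the target
#' plus the superior/inferior field margin, so a 2 cm field border always
#' fits. Deterministic for a fixed spec (including seed).
#'
#' @param spec A [phantom_spec()].
#' @return A [structure_set()].
#' @examples
#' ph <- build_thorax_phantom(phantom_spec(spacing_mm = 6))
#' mask_volume_cm3(ph, "PTV")
#' @export
build_thorax_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  p <- spec
  if (p$jitter_cm > 0) {
    # jitter in a private RNG stream so global RNG state is untouched
    rng <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(rng)) assign(".Random.seed", rng,
                                      envir = globalenv()), add = TRUE)
    set.seed(p$seed)
    jig <- function(x) x + stats::rnorm(length(x), sd = p$jitter_cm)
    p$body_semiaxes_cm  <- pmax(jig(p$body_semiaxes_cm), 1)
    p$lung_semiaxes_cm  <- pmax(jig(p$lung_semiaxes_cm), 0)
    p$lung_offset_cm    <- max(jig(p$lung_offset_cm), 0)
    p$ptv_width_cm      <- max(jig(p$ptv_width_cm), 0.5)
    p$ptv_depth_cm      <- max(jig(p$ptv_depth_cm), 0.5)
    p$ptv_length_cm     <- max(jig(p$ptv_length_cm), 1)
    p$heart_center_cm   <- jig(p$heart_center_cm)
    if (p$ptv_width_cm >= 2 * p$body_semiaxes_cm[1])
      stop("impossible geometry after jitter: PTV wider than the body")
  }
  sp <- if (length(p$spacing_mm) == 1L) rep(p$spacing_mm, 3L) else p$spacing_mm

  half_x <- p$body_semiaxes_cm[1] + p$pad_cm
  half_y <- p$body_semiaxes_cm[2] + p$pad_cm
  half_z <- max(p$lung_semiaxes_cm[3],
                p$ptv_length_cm / 2 + 2.5,
                p$heart_semiaxes_cm[3] + abs(p$heart_center_cm[3])) + p$pad_cm
  n <- 2L * as.integer(ceiling((c(half_x, half_y, half_z) +
                                  abs(p$center_offset_cm)) * 10 / sp)) + 1L
  origin <- -(n - 1) / 2 * sp
  # anatomy coordinates relative to the (possibly shifted) anatomy centre
  xs <- (origin[1] + (seq_len(n[1]) - 1) * sp[1]) / 10 - p$center_offset_cm[1]
  ys <- (origin[2] + (seq_len(n[2]) - 1) * sp[2]) / 10 - p$center_offset_cm[2]
  zs <- (origin[3] + (seq_len(n[3]) - 1) * sp[3]) / 10 - p$center_offset_cm[3]

  ellipse2 <- function(cx, cy, a, b)   # axial quadric, matrix over (x, y)
    outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, "+")
  extrude <- function(m2, zkeep) outer(m2 <= 1, zkeep, "&")

  body <- extrude(ellipse2(0, 0, p$body_semiaxes_cm[1], p$body_semiaxes_cm[2]),
                  rep(TRUE, n[3]))

  lung <- function(sgn) {
    if (any(p$lung_semiaxes_cm == 0))
      return(array(FALSE, n))
    m2 <- ellipse2(sgn * p$lung_offset_cm, 0,
                   p$lung_semiaxes_cm[1], p$lung_semiaxes_cm[2])
    q <- outer(m2, (zs / p$lung_semiaxes_cm[3])^2, "+")
    q <= 1
  }
  lung_l <- lung(+1) & body   # +x = patient left
  lung_r <- lung(-1) & body

  ptv <- extrude(ellipse2(0, 0, p$ptv_width_cm / 2, p$ptv_depth_cm / 2),
                 abs(zs) <= p$ptv_length_cm / 2) & body

  hq <- outer(ellipse2(p$heart_center_cm[1], p$heart_center_cm[2],
                       p$heart_semiaxes_cm[1], p$heart_semiaxes_cm[2]),
              ((zs - p$heart_center_cm[3]) / p$heart_semiaxes_cm[3])^2, "+")
  heart <- (hq <= 1) & body

  cord <- extrude(ellipse2(0, p$cord_center_ap_cm,
                           p$cord_radius_cm, p$cord_radius_cm),
                  rep(TRUE, n[3])) & body

  if (!any(ptv)) stop("impossible geometry: PTV rasterized to an empty mask")

  structure_set(list(BODY = body,
                     LUNG_L = lung_l, LUNG_R = lung_r,
                     LUNG_WHOLE = lung_l | lung_r,
                     PTV = ptv, HEART = heart, CORD = cord),
                spacing_mm = sp, origin_mm = origin)
}

#' The six scalar geometry inputs of the volume-based algorithm
#'
#' @param T_cm Transverse thorax diameter T, cm.
#' @param E_cm Target (PTV) width E on the axial centroid plane, cm.
#' @param Lt_cm Target axial length Lt, cm.
#' @param V_W_cm3 Whole-lung volume, cm^3.
#' @param V_OW_cm3 Lung volume outside the cranio-caudal field extent, cm^3.
#' @param expected_V5 Target fractional lung V5 (0-1), default 0.55.
#' @return An object of class `geometry_inputs`.
#' @export
geometry_inputs <- function(T_cm, E_cm, Lt_cm, V_W_cm3, V_OW_cm3,
                            expected_V5 = 0.55) {
  if (!(T_cm > E_cm)) stop("need T > E (thorax wider than target)")
  if (E_cm <= 0 || Lt_cm <= 0) stop("all lengths must be positive")
  if (V_W_cm3 < 0 || V_OW_cm3 < 0 || V_OW_cm3 > V_W_cm3 + 1e-9)
    stop("need 0 <= V_OW <= V_W")
  if (!(expected_V5 > 0 && expected_V5 < 1))
    stop("expected_V5 must lie in (0, 1)")
  structure(list(T_cm = T_cm, E_cm = E_cm, Lt_cm = Lt_cm,
                 V_W_cm3 = V_W_cm3, V_OW_cm3 = V_OW_cm3,
                 expected_V5 = expected_V5),
            class = "geometry_inputs")
}

#' @export
print.geometry_inputs <- function(x, ...) {
  cat("<geometry_inputs>\n")
  cat(sprintf("  T  = %6.2f cm   E    = %6.2f cm   Lt = %6.2f cm\n",
              x$T_cm, x$E_cm, x$Lt_cm))
  cat(sprintf("  V_W = %8.1f cm^3   V_OW = %8.1f cm^3   expected V5 = %.2f\n",
              x$V_W_cm3, x$V_OW_cm3, x$expected_V5))
  invisible(x)
}

#' Measure the VBA geometry inputs from structure masks
#'
#' Reproduces the manual measurements the algorithm expects: the target width
#' `E` is the maximal left-right PTV extent on the axial slice through the
#' PTV centroid; the axial length `Lt` is the superior-inferior PTV extent on
#' the coronal plane through the centroid; `T` is the maximal left-right body
#' extent on the same axial slice. Extents are centre-to-centre plus one
#' voxel. `V_W` is the voxelized whole-lung volume, and `V_OW` the lung
#' volume outside the axial field slab spanning the PTV plus
#' `field_margin_cm` on each side (default 2 cm, giving the customary
#' `Lt + 4` cm field length).
#'
#' For a concave target the single-plane measurement can under-read the
#' global footprint; `extent_mode = "bounding_box"` instead takes extents of
#' the whole mask.
#'
#' @param structs A [structure_set()] with non-empty `PTV` mask.
#' @param field_margin_cm Superior/inferior field margin per side, cm.
#' @param expected_V5 Target fractional lung V5 passed through to the result.
#' @param extent_mode `"centroid_plane"` (default, as measured clinically) or
#'   `"bounding_box"`.
#' @return A [geometry_inputs()] object.
#' @export
measure_geometry <- function(structs, field_margin_cm = 2,
                             expected_V5 = 0.55,
                             extent_mode = c("centroid_plane",
                                             "bounding_box")) {
  stopifnot(inherits(structs, "structure_set"))
  extent_mode <- match.arg(extent_mode)
  ptv <- structs$masks$PTV
  if (!any(ptv)) stop("measurement error: PTV mask is empty")
  body <- structs$masks$BODY
  lung <- structs$masks$LUNG_WHOLE
  sp_cm <- structs$spacing / 10
  idx <- arrayInd(which(ptv), structs$shape)
  cen <- round(colMeans(idx))

  extent_cm <- function(ind, axis)
    (diff(range(ind[, axis])) + 1) * sp_cm[axis]

  if (extent_mode == "centroid_plane") {
    ax <- idx[idx[, 3] == cen[3], , drop = FALSE]        # axial slice
    co <- idx[idx[, 2] == cen[2], , drop = FALSE]        # coronal plane
    if (!nrow(ax) || !nrow(co))
      stop("measurement error: PTV missing on its centroid plane")
    E <- extent_cm(ax, 1)
    Lt <- extent_cm(co, 3)
    bx <- arrayInd(which(body[, , cen[3]]), structs$shape[1:2])
    if (!nrow(bx)) stop("measurement error: BODY empty on the axial plane")
    T_cm <- (diff(range(bx[, 1])) + 1) * sp_cm[1]
  } else {
    E <- extent_cm(idx, 1)
    Lt <- extent_cm(idx, 3)
    bidx <- arrayInd(which(body), structs$shape)
    T_cm <- extent_cm(bidx, 1)
  }

  vv <- voxel_volume_cm3(structs)
  V_W <- sum(lung) * vv
  zs <- voxel_centers_cm(structs, 3)
  z_ptv <- range(zs[unique(idx[, 3])])
  out_slab <- zs < (z_ptv[1] - field_margin_cm) |
              zs > (z_ptv[2] + field_margin_cm)
  V_OW <- if (any(out_slab))
    sum(lung[, , out_slab, drop = FALSE]) * vv else 0

  geometry_inputs(T_cm = T_cm, E_cm = E, Lt_cm = Lt,
                  V_W_cm3 = V_W, V_OW_cm3 = V_OW,
                  expected_V5 = expected_V5)
}

#' Idealized cylindrical phantom matching the angle solver's volume model
#'
#' The angle solver models the never-irradiated ("restricted") lung as a
#' partial cylinder: a full lung cylinder of radius `lung_radius_cm` centred
#' on the rotation axis, of which the angular fraction outside the arc
#' sectors escapes irradiation. This builder realizes exactly that geometry
#' on a lattice -- a centred lung cylinder, a thin central target rod (so
#' the treated corridor is negligibly narrow, as the model assumes), and a
#' body cylinder just enclosing the lung -- so voxel counting can be checked
#' against the closed-form restricted volume. Use a zero aperture margin
#' with it.
#'
#' @param lung_radius_cm Radius of the centred lung cylinder, cm.
#' @param ptv_length_cm Axial length of the central target rod, cm.
#' @param lung_halflength_cm Half-length of the lung cylinder, cm; anything
#'   beyond the target's axial extent contributes out-of-field lung.
#' @param rod_halfwidth_cm Half-width of the target rod, cm (keep at one
#'   voxel or less; the model assumes a vanishing corridor).
#' @param spacing_mm Voxel size, mm.
#' @return A [structure_set()] with `BODY`, `LUNG_WHOLE` and `PTV` masks.
#' @seealso [geometric_unirradiated_fraction()]
#' @export
build_cylinder_phantom <- function(lung_radius_cm = 12, ptv_length_cm = 16,
                                   lung_halflength_cm = 12,
                                   rod_halfwidth_cm = 0.16,
                                   spacing_mm = 3) {
  if (lung_radius_cm <= 0 || ptv_length_cm <= 0 || lung_halflength_cm <= 0)
    stop("all dimensions must be positive")
  sp <- spacing_mm
  body_r <- lung_radius_cm + 2 * sp / 10
  half_xy <- body_r + 0.5
  half_z <- lung_halflength_cm + 1
  n <- 2L * as.integer(ceiling(c(half_xy, half_xy, half_z) * 10 / sp)) + 1L
  org <- -(n - 1) / 2 * sp
  xs <- (org[1] + (seq_len(n[1]) - 1) * sp) / 10
  ys <- (org[2] + (seq_len(n[2]) - 1) * sp) / 10
  zs <- (org[3] + (seq_len(n[3]) - 1) * sp) / 10
  r2 <- outer(xs^2, ys^2, "+")
  body <- outer(r2 <= body_r^2, rep(TRUE, n[3]), "&")
  lung <- outer(r2 <= lung_radius_cm^2, abs(zs) <= lung_halflength_cm, "&")
  rod2 <- outer(abs(xs) <= rod_halfwidth_cm, abs(ys) <= rod_halfwidth_cm, "&")
  ptv <- outer(rod2, abs(zs) <= ptv_length_cm / 2, "&")
  if (!any(ptv))
    stop("target rod rasterized to an empty mask; widen rod_halfwidth_cm")
  structure_set(list(BODY = body, LUNG_WHOLE = lung, PTV = ptv),
                spacing_mm = sp, origin_mm = org)
}
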