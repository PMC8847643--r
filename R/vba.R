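#' Restricted-volume radius from thorax and target width
#'
#' The lateral lung regions that a partial arc never traverses (the
#' "restricted volume") are modelled as cylinders whose radius is half the
#' lateral gap between the treated corridor and the body surface:
#' `R = (T - E - margin_total) / 2`, with the default 4 cm accounting for a
#' 2 cm field border on each side of the target.
#'
#' @param T_cm Transverse thorax diameter, cm.
#' @param E_cm Target width, cm.
#' @param margin_total_cm Total lateral field margin (both sides), cm.
#' @return Restricted radius R in cm.
#' @examples
#' restricted_radius(30, 6)   # 10
#' @export
restricted_radius <- function(T_cm, E_cm, margin_total_cm = 4) {
  if (!is.finite(T_cm) || !is.finite(E_cm))
    stop("T and E must be finite")
  if (T_cm <= E_cm + margin_total_cm)
    stop("infeasible geometry: no lateral restricted region exists ",
         "(need T > E + ", margin_total_cm, " cm)")
  (T_cm - E_cm - margin_total_cm) / 2
}

#' Solve the volume-based algorithm for the optimal partial-arc angle
#'
#' The algorithm bounds the low-dose lung volume by demanding that the lung
#' volume left untraversed by the arc equals the complement of the expected
#' lung V5: a partial cylinder of radius `R` over the field length `Lt +
#' margin` supplies the in-field restricted volume, and `V_OW` the lung
#' beyond the field,
#'
#' \deqn{\pi R^2 \frac{360 - \theta_A}{360} (Lt + m) + V_{OW}
#'       = V_W (1 - V_5^{exp}),}
#'
#' solved in closed form for the arc angle
#' \deqn{\theta_A = 360 \left[1 - \frac{V_W (1 - V_5^{exp}) - V_{OW}}
#'       {\pi R^2 (Lt + m)}\right].}
#'
#' At the default `expected_V5 = 0.55` the right-hand factor is the customary
#' 0.45. The result is classified: `OK` when `0 < theta_A < 360`;
#' `NEEDS_FULL_ARC` when the lungs already meet the V5 target without any
#' angular restriction (implied `theta_A >= 360`); `INFEASIBLE` when even a
#' vanishing arc cannot spare enough lung (implied `theta_A <= 0`, or no
#' lateral restricted region exists). `theta_A` is reported clamped to
#' `[0, 360]` and `achieved_geometric_V5` is the expected V5 implied by the
#' clamped angle.
#'
#' @param geom A [geometry_inputs()] object.
#' @param margin_total_cm Total field margin added to both `E` (laterally)
#'   and `Lt` (axially), cm; default 4.
#' @return An object of class `opa_result` with fields `R`, `theta_A`,
#'   `feasible` and `achieved_geometric_V5`.
#' @examples
#' g <- geometry_inputs(T_cm = 30, E_cm = 6, Lt_cm = 16,
#'                      V_W_cm3 = 4000, V_OW_cm3 = 500)
#' solve_opa_angle(g)
#' @export
solve_opa_angle <- function(geom, margin_total_cm = 4) {
  stopifnot(inherits(geom, "geometry_inputs"))
  if (geom$V_W_cm3 <= 0)
    stop("invalid geometry: whole-lung volume V_W must be positive")
  required <- geom$V_W_cm3 * (1 - geom$expected_V5) - geom$V_OW_cm3
  slab <- geom$Lt_cm + margin_total_cm

  R <- if (geom$T_cm > geom$E_cm + margin_total_cm)
    restricted_radius(geom$T_cm, geom$E_cm, margin_total_cm) else 0

  achieved_v5 <- function(theta)
    1 - (pi * R^2 * (360 - theta) / 360 * slab + geom$V_OW_cm3) /
      geom$V_W_cm3

  if (required <= 0) {
    res <- list(R = R, theta_A = 360, feasible = "NEEDS_FULL_ARC",
                achieved_geometric_V5 = achieved_v5(360))
  } else if (R <= 0) {
    res <- list(R = R, theta_A = 0, feasible = "INFEASIBLE",
                achieved_geometric_V5 = achieved_v5(0))
  } else {
    theta <- 360 * (1 - required / (pi * R^2 * slab))
    if (theta <= 0) {
      res <- list(R = R, theta_A = 0, feasible = "INFEASIBLE",
                  achieved_geometric_V5 = achieved_v5(0))
    } else {
      res <- list(R = R, theta_A = theta, feasible = "OK",
                  achieved_geometric_V5 = geom$expected_V5)
    }
  }
  res$geometry <- geom
  res$margin_total_cm <- margin_total_cm
  class(res) <- "opa_result"
  res
}

#' @export
print.opa_result <- function(x, ...) {
  cat("<opa_result>\n")
  cat(sprintf("  restricted radius R : %.3f cm\n", x$R))
  cat(sprintf("  OPA angle theta_A   : %.1f deg  [%s]\n",
              x$theta_A, x$feasible))
  cat(sprintf("  implied lung V5     : %.1f %%\n",
              100 * x$achieved_geometric_V5))
  invisible(x)
}
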