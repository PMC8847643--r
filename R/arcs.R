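#' Normalize a gantry angle to [0, 360)
#'
#' Angles follow the IEC-style convention used throughout: 0 deg enters
#' anteriorly, 90 deg from the patient's left, values stored in `[0, 360)`.
#'
#' @param angle Gantry angle(s) in degrees (any finite value).
#' @return Angle(s) reduced modulo 360 into `[0, 360)`.
#' @examples
#' normalize_gantry_angle(c(-27.5, 360, 207.5))
#' @export
normalize_gantry_angle <- function(angle) {
  if (any(!is.finite(angle))) stop("angle must be finite")
  angle %% 360
}

#' Angular span of an arc in its direction of travel
#'
#' @param start,stop Gantry angles in degrees.
#' @param direction `"CW"` (increasing angle) or `"CCW"`.
#' @return Span in degrees, in `(0, 360)`.
#' @export
arc_span <- function(start, stop, direction) {
  d <- normalize_gantry_angle(stop) - normalize_gantry_angle(start)
  ifelse(direction == "CW", d %% 360, (-d) %% 360)
}

# TRUE when traversal crosses the 180 deg meridian strictly inside the arc
# (the linac gantry cannot pass from 180 to -180)
.crosses_machine_limit <- function(start, stop, direction) {
  span <- arc_span(start, stop, direction)
  t <- ifelse(direction == "CW", (180 - start) %% 360, (start - 180) %% 360)
  t > 1e-9 & t < span - 1e-9
}

.make_arcs <- function(start, stop, direction, collimator_offset) {
  start <- normalize_gantry_angle(start)
  stop <- normalize_gantry_angle(stop)
  if (any(abs(start - stop) < 1e-9))
    stop("degenerate arc: start equals stop")
  bad <- .crosses_machine_limit(start, stop, direction)
  if (any(bad))
    stop("arc ", which(bad)[1],
         " crosses the 180 deg machine limit inside its traversal")
  data.frame(start = start, stop = stop, direction = direction,
             collimator_offset = collimator_offset)
}

.new_arc_plan <- function(arcs, plan_type, gantry_spacing,
                          max_seconds_per_arc) {
  n_expected <- if (plan_type == "FA") 2L else 6L
  if (nrow(arcs) != n_expected)
    stop(plan_type, " plans must contain exactly ", n_expected, " arcs")
  structure(list(arcs = arcs, plan_type = plan_type,
                 gantry_spacing = gantry_spacing,
                 max_seconds_per_arc = max_seconds_per_arc),
            class = "arc_plan")
}

#' Sequence an optimal partial-arc angle into six deliverable arcs
#'
#' Splits the solved arc angle `theta_A` into the standard six partial arcs,
#' three clockwise and three counter-clockwise, covering an anterior sector
#' of width `theta_A / 2` and a posterior sector of the same width. Because
#' the gantry cannot pass from 180 to -180 deg, the posterior sector is split
#' at that meridian, and the final clockwise arc stops `sentinel_gap` short
#' of 180 (at 179 deg by default):
#'
#' * CW: `180 -> 180 + theta_A/4`, `-theta_A/4 -> theta_A/4`,
#'   `180 - theta_A/4 -> 179`
#' * CCW: `179 -> 180 - theta_A/4`, `theta_A/4 -> -theta_A/4`,
#'   `180 + theta_A/4 -> 180`
#'
#' All endpoints are normalized to `[0, 360)`. The collimator is rotated by
#' `collimator_offset` on every second arc to wash out tongue-and-groove
#' effects.
#'
#' @param theta_A Partial-arc angle in degrees, in
#'   `(4 * sentinel_gap, 360)`.
#' @param collimator_offset Extra collimator rotation (degrees) applied to
#'   alternating arcs.
#' @param sentinel_gap Gap (degrees) left between the last clockwise stop and
#'   the 180 deg meridian; default 1.
#' @param gantry_spacing Control-point spacing carried on the plan, degrees.
#' @param max_seconds_per_arc Delivery-time cap carried as configuration
#'   (not used in any computation).
#' @return An `arc_plan` with `plan_type = "OPA"` and six arcs.
#' @examples
#' sequence_opa_arcs(110)
#' @export
sequence_opa_arcs <- function(theta_A, collimator_offset = 5,
                              sentinel_gap = 1, gantry_spacing = 4,
                              max_seconds_per_arc = 40) {
  if (!is.finite(theta_A) || theta_A <= 0 || theta_A >= 360)
    stop("theta_A must lie strictly between 0 and 360 degrees")
  q <- theta_A / 4
  if (q <= sentinel_gap)
    stop("theta_A too small to sequence: need theta_A > 4 * sentinel_gap")
  arcs <- .make_arcs(
    start = c(180, -q, 180 - q, 180 - sentinel_gap, q, 180 + q),
    stop  = c(180 + q, q, 180 - sentinel_gap, 180 - q, -q, 180),
    direction = c("CW", "CW", "CW", "CCW", "CCW", "CCW"),
    collimator_offset = collimator_offset * (seq_len(6L) %% 2L == 0L))
  .new_arc_plan(arcs, "OPA", gantry_spacing, max_seconds_per_arc)
}

#' Sequence the two-full-arc baseline plan
#'
#' The full-arc reference plan uses one clockwise arc from 180 to 179 deg
#' (359 deg of travel) followed by a counter-clockwise arc from 179 back to
#' 180, with the collimator rotated by `collimator_offset` on the second arc.
#'
#' @inheritParams sequence_opa_arcs
#' @return An `arc_plan` with `plan_type = "FA"` and two arcs.
#' @export
sequence_full_arcs <- function(collimator_offset = 5, gantry_spacing = 4,
                               max_seconds_per_arc = 120) {
  arcs <- .make_arcs(start = c(180, 179), stop = c(179, 180),
                     direction = c("CW", "CCW"),
                     collimator_offset = c(0, collimator_offset))
  .new_arc_plan(arcs, "FA", gantry_spacing, max_seconds_per_arc)
}

#' Total angular coverage of a plan in one rotation sense
#'
#' Sums the spans of the plan's arcs travelling in `direction`. For the
#' six-arc partial plan this recovers `theta_A - sentinel_gap` per sense.
#'
#' @param plan An `arc_plan`.
#' @param direction `"CW"` or `"CCW"`.
#' @return Total covered degrees.
#' @export
plan_coverage_deg <- function(plan, direction = "CW") {
  stopifnot(inherits(plan, "arc_plan"))
  a <- plan$arcs[plan$arcs$direction == direction, , drop = FALSE]
  if (!nrow(a)) return(0)
  sum(arc_span(a$start, a$stop, a$direction))
}

#' @export
print.arc_plan <- function(x, ...) {
  cat("<arc_plan> ", x$plan_type, " (", nrow(x$arcs), " arcs, ",
      format(x$gantry_spacing), " deg control-point spacing)\n", sep = "")
  for (i in seq_len(nrow(x$arcs))) {
    a <- x$arcs[i, ]
    cat(sprintf("  arc %d: %6.1f -> %6.1f deg  %-3s  collimator %+.1f deg\n",
                i, round(a$start, 1), round(a$stop, 1), a$direction,
                a$collimator_offset))
  }
  invisible(x)
}
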