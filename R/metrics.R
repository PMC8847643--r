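#' Cumulative dose-volume histogram of one structure
#'
#' The curve value at dose bin edge `d` is the percentage of the structure's
#' volume receiving at least `d` Gy; the first value (at 0 Gy) is therefore
#' 100.
#'
#' @param dose A [volume_grid()] of dose in Gy.
#' @param mask Logical array on the same lattice (or a `structure_set` plus
#'   `structure` name).
#' @param bin_width_gy Dose bin width, Gy.
#' @param structure Structure name recorded on the curve (and used to look
#'   `mask` up when a `structure_set` is supplied).
#' @return A `dvh_curve`: data frame with columns `dose_gy` and `volume_pct`,
#'   with attributes `structure`, `volume_cm3` and `bin_width_gy`.
#' @export
compute_dvh <- function(dose, mask, bin_width_gy = 0.05,
                        structure = "structure") {
  stopifnot(inherits(dose, "volume_grid"))
  if (inherits(mask, "structure_set")) {
    if (!structure %in% names(mask$masks))
      stop("no mask named '", structure, "'")
    mask <- mask$masks[[structure]]
  }
  if (!identical(dim(mask), dim(dose$values)))
    stop("mask and dose must share one lattice")
  d <- dose$values[mask]
  if (!length(d))
    stop("empty mask for structure '", structure, "'")
  if (any(d < 0)) stop("negative dose values")
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  ds <- sort(d)
  n_lt <- findInterval(edges, ds, left.open = TRUE)   # voxels with dose < edge
  pct <- 100 * (length(ds) - n_lt) / length(ds)
  out <- data.frame(dose_gy = edges, volume_pct = pct)
  attr(out, "structure") <- structure
  attr(out, "volume_cm3") <- length(d) * voxel_volume_cm3(dose)
  attr(out, "bin_width_gy") <- bin_width_gy
  class(out) <- c("dvh_curve", "data.frame")
  out
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("<dvh_curve> ", attr(x, "structure"), ": ",
      sprintf("%.1f cm^3, %d bins of %.3g Gy\n", attr(x, "volume_cm3"),
              nrow(x), attr(x, "bin_width_gy")), sep = "")
  invisible(x)
}

#' Volume receiving at least a given dose (V_x)
#'
#' Linear interpolation on the cumulative curve; `V_at_dose(dvh, 0)` is 100
#' and doses beyond the curve return 0.
#'
#' @param dvh A `dvh_curve`.
#' @param dose_gy Dose level(s) x in Gy (>= 0).
#' @return Volume percentage(s).
#' @export
V_at_dose <- function(dvh, dose_gy) {
  if (any(dose_gy < 0)) stop("dose must be >= 0")
  stats::approx(dvh$dose_gy, dvh$volume_pct, xout = dose_gy,
                rule = 2, ties = "ordered")$y
}

#' Minimum dose to the hottest v% of a structure (D_v)
#'
#' Inverse of the cumulative curve: the smallest dose at which the covered
#' volume drops to `volume_pct`, linearly interpolated between bin edges.
#' `D_at_volume(dvh, 100)` is the minimum structure dose (to within one bin).
#'
#' @param dvh A `dvh_curve`.
#' @param volume_pct Volume percentage in `(0, 100]`.
#' @return Dose in Gy.
#' @export
D_at_volume <- function(dvh, volume_pct) {
  if (length(volume_pct) > 1L)
    return(vapply(volume_pct, function(v) D_at_volume(dvh, v), numeric(1)))
  v <- volume_pct
  if (!(v > 0 && v <= 100)) stop("volume_pct must lie in (0, 100]")
  pct <- dvh$volume_pct
  d <- dvh$dose_gy
  i <- which(pct < v)[1L]
  if (is.na(i)) return(d[length(d)])
  if (i == 1L) return(d[1L])
  d[i - 1L] + (pct[i - 1L] - v) / (pct[i - 1L] - pct[i]) * (d[i] - d[i - 1L])
}

#' Homogeneity index HI = D_5% / D_95%
#'
#' Perfectly uniform target dose gives 1; values between 1.00 and 1.40 are
#' considered clinically acceptable.
#'
#' @param dvh A `dvh_curve` of the target.
#' @return HI, with attribute `acceptable` (`TRUE` when `1 <= HI <= 1.4`).
#' @export
homogeneity_index <- function(dvh) {
  d95 <- D_at_volume(dvh, 95)
  if (d95 <= 0) stop("undefined HI: D_95 is zero")
  hi <- D_at_volume(dvh, 5) / d95
  attr(hi, "acceptable") <- hi >= 1 && hi <= 1.4
  hi
}

#' Conformity index CI = V_RI / TV
#'
#' Ratio of the reference-isodose volume (all voxels at or above the
#' reference dose, anywhere in the grid) to the target volume. 1 is perfectly
#' conformal; 0.9-2 is considered acceptable.
#'
#' @param dose A [volume_grid()] of dose in Gy.
#' @param ptv_mask Logical target mask on the same lattice (or a
#'   `structure_set`, whose `PTV` mask is used).
#' @param reference_dose_gy Isodose level defining `V_RI`; defaults to the
#'   45 Gy prescription.
#' @return CI, with attribute `acceptable` (`TRUE` when `0.9 <= CI <= 2`).
#' @export
conformity_index <- function(dose, ptv_mask, reference_dose_gy = 45) {
  stopifnot(inherits(dose, "volume_grid"))
  if (inherits(ptv_mask, "structure_set")) ptv_mask <- ptv_mask$masks$PTV
  if (!any(ptv_mask)) stop("empty target mask")
  if (reference_dose_gy <= 0) stop("reference dose must be positive")
  ci <- sum(dose$values >= reference_dose_gy) / sum(ptv_mask)
  attr(ci, "acceptable") <- ci >= 0.9 && ci <= 2
  ci
}

#' Default organ-at-risk constraint table
#'
#' The planning constraints used for central thoracic targets at 45 Gy:
#' spinal-cord maximum below 45 Gy; mean heart dose below 34 Gy and heart
#' V40 below 50%; for the whole, right and left lung a mean dose below
#' 20 Gy and V20 / V15 / V10 / V5 at or below 20 / 30 / 50 / 55%.
#'
#' @return Data frame with columns `structure`, `metric`, `comparator`
#'   (`"<"` or `"<="`) and `limit`.
#' @export
default_constraint_table <- function() {
  lungs <- c("LUNG_WHOLE", "LUNG_R", "LUNG_L")
  rbind(
    data.frame(structure = "CORD", metric = "max_gy",
               comparator = "<", limit = 45),
    data.frame(structure = "HEART", metric = c("mean_gy", "V40_pct"),
               comparator = "<", limit = c(34, 50)),
    data.frame(structure = rep(lungs, each = 5),
               metric = rep(c("mean_gy", "V20_pct", "V15_pct",
                              "V10_pct", "V5_pct"), times = 3),
               comparator = rep(c("<", "<=", "<=", "<=", "<="), times = 3),
               limit = rep(c(20, 20, 30, 50, 55), times = 3)))
}

#' Check measured plan metrics against a constraint table
#'
#' @param metrics Data frame with columns `structure`, `metric`, `value`
#'   holding the measured quantities.
#' @param table Constraint table as from [default_constraint_table()].
#' @return The table with added columns `value` and `pass`, plus attribute
#'   `overall_pass`. A constraint whose metric is absent from `metrics` is an
#'   error, never a silent pass.
#' @export
evaluate_constraints <- function(metrics, table = default_constraint_table()) {
  stopifnot(is.data.frame(metrics),
            all(c("structure", "metric", "value") %in% names(metrics)))
  key_m <- paste(metrics$structure, metrics$metric)
  key_t <- paste(table$structure, table$metric)
  hit <- match(key_t, key_m)
  if (anyNA(hit))
    stop("missing metric(s) for constraint(s): ",
         paste(key_t[is.na(hit)], collapse = ", "))
  out <- table
  out$value <- metrics$value[hit]
  out$pass <- ifelse(out$comparator == "<",
                     out$value < out$limit,
                     out$value <= out$limit)
  attr(out, "overall_pass") <- all(out$pass)
  out
}

#' Full plan-quality report for one dose distribution
#'
#' Computes, per structure, the mean and maximum dose and the V_x levels the
#' constraint table needs; for the target additionally D_5, D_95, HI and CI;
#' then evaluates the constraint table.
#'
#' @param dose A [volume_grid()] of dose in Gy.
#' @param structs A [structure_set()].
#' @param rx A [plan_spec()]; the prescription is the CI reference isodose.
#' @param constraints Constraint table; `NULL` skips the verdicts.
#' @param bin_width_gy DVH bin width, Gy.
#' @param plan_type Label stored on the report (e.g. `"FA"` or `"OPA"`).
#' @return An object of class `plan_report` with fields `metrics` (long data
#'   frame), `ptv` (D5/D95/HI/CI), `constraints` and `plan_type`.
#' @export
plan_report <- function(dose, structs, rx = plan_spec(),
                        constraints = default_constraint_table(),
                        bin_width_gy = 0.05, plan_type = "plan") {
  stopifnot(inherits(dose, "volume_grid"), inherits(structs, "structure_set"))
  levels_needed <- c(5, 10, 15, 20, 30, 40)
  rows <- list()
  for (nm in names(structs$masks)) {
    if (nm == "BODY" || !any(structs$masks[[nm]])) next
    dvh <- compute_dvh(dose, structs$masks[[nm]], bin_width_gy, structure = nm)
    dv <- dose$values[structs$masks[[nm]]]
    rows[[nm]] <- data.frame(
      structure = nm,
      metric = c("mean_gy", "max_gy",
                 paste0("V", levels_needed, "_pct")),
      value = c(mean(dv), max(dv), V_at_dose(dvh, levels_needed)))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  dvh_ptv <- compute_dvh(dose, structs$masks$PTV, bin_width_gy, "PTV")
  hi <- homogeneity_index(dvh_ptv)
  ci <- conformity_index(dose, structs$masks$PTV, rx$total_dose_gy)
  ptv <- list(D5_gy = D_at_volume(dvh_ptv, 5),
              D95_gy = D_at_volume(dvh_ptv, 95),
              HI = as.numeric(hi), HI_acceptable = attr(hi, "acceptable"),
              CI = as.numeric(ci), CI_acceptable = attr(ci, "acceptable"))

  verdicts <- if (is.null(constraints)) NULL else {
    have <- paste(constraints$structure, constraints$metric) %in%
      paste(metrics$structure, metrics$metric)
    evaluate_constraints(metrics, constraints[have, , drop = FALSE])
  }
  structure(list(plan_type = plan_type, metrics = metrics, ptv = ptv,
                 constraints = verdicts, rx = rx),
            class = "plan_report")
}

#' @export
print.plan_report <- function(x, ...) {
  cat("<plan_report> ", x$plan_type, " (prescription ",
      x$rx$total_dose_gy, " Gy / ", x$rx$fractions, " fx)\n", sep = "")
  cat(sprintf("  PTV: D5 %.2f Gy  D95 %.2f Gy  HI %.3f  CI %.3f\n",
              x$ptv$D5_gy, x$ptv$D95_gy, x$ptv$HI, x$ptv$CI))
  wide <- stats::reshape(x$metrics, idvar = "structure",
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(format(wide, digits = 4), row.names = FALSE)
  if (!is.null(x$constraints)) {
    np <- sum(!x$constraints$pass)
    cat("  constraints: ",
        if (np == 0) "all pass" else paste(np, "FAIL"), "\n", sep = "")
  }
  invisible(x)
}
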