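#' Gamma-comparison settings
#'
#' Defaults follow routine patient-specific QA practice: 3% global dose
#' difference, 3 mm distance-to-agreement, a 95% clinical passing threshold
#' and a 10% low-dose cutoff. The dose criterion is global: it is taken as a
#' percentage of the reference grid's maximum.
#'
#' @param dose_criterion_pct Dose-difference criterion, % of the reference
#'   maximum.
#' @param dta_mm Distance-to-agreement criterion, mm.
#' @param pass_threshold_pct Clinical passing threshold on the rate, %.
#' @param low_dose_cutoff_pct Reference points below this % of the reference
#'   maximum are excluded.
#' @param search_radius_mult Spatial search radius as a multiple of `dta_mm`
#'   (gamma values are capped there).
#' @param subsample Evaluated-grid samples per DTA along each axis when
#'   searching (the evaluated dose is interpolated trilinearly).
#' @return An object of class `gamma_spec`.
#' @export
gamma_spec <- function(dose_criterion_pct = 3, dta_mm = 3,
                       pass_threshold_pct = 95, low_dose_cutoff_pct = 10,
                       search_radius_mult = 3, subsample = 10) {
  vals <- c(dose_criterion_pct, dta_mm, pass_threshold_pct,
            low_dose_cutoff_pct, search_radius_mult, subsample)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gamma settings must be positive and finite ",
         "(degenerate 0% or infinite-DTA criteria are not allowed)")
  structure(list(dose_criterion_pct = dose_criterion_pct, dta_mm = dta_mm,
                 pass_threshold_pct = pass_threshold_pct,
                 low_dose_cutoff_pct = low_dose_cutoff_pct,
                 search_radius_mult = search_radius_mult,
                 subsample = subsample),
            class = "gamma_spec")
}

# Evaluated dose sampled at every reference voxel centre displaced by a fixed
# physical offset (mm), trilinear interpolation; NA outside the evaluated
# grid.
.shifted_eval <- function(ref, ev, offset_mm) {
  nr <- dim(ref$values); ne <- dim(ev$values)
  ax <- vector("list", 3L)
  for (a in 1:3) {
    pos <- ref$origin[a] + (seq_len(nr[a]) - 1) * ref$spacing[a] +
      offset_mm[a]
    idx <- (pos - ev$origin[a]) / ev$spacing[a] + 1
    f <- floor(idx)
    ax[[a]] <- list(f = f, w = idx - f)
  }
  out <- array(0, nr)
  valid <- array(TRUE, nr)
  evv <- ev$values
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    i1 <- ax[[1]]$f + c1; i2 <- ax[[2]]$f + c2; i3 <- ax[[3]]$f + c3
    w1 <- if (c1) ax[[1]]$w else 1 - ax[[1]]$w
    w2 <- if (c2) ax[[2]]$w else 1 - ax[[2]]$w
    w3 <- if (c3) ax[[3]]$w else 1 - ax[[3]]$w
    w <- outer(outer(w1, w2), w3)
    rel <- w > 1e-12
    ok1 <- i1 >= 1 & i1 <= ne[1]
    ok2 <- i2 >= 1 & i2 <= ne[2]
    ok3 <- i3 >= 1 & i3 <= ne[3]
    ok <- outer(outer(ok1, ok2, "&"), ok3, "&")
    bad <- rel & !ok
    if (any(bad)) valid[bad] <- FALSE
    i1c <- pmin(pmax(i1, 1L), ne[1])
    i2c <- pmin(pmax(i2, 1L), ne[2])
    i3c <- pmin(pmax(i3, 1L), ne[3])
    lin <- outer(outer(i1c, (i2c - 1) * ne[1], "+"),
                 (i3c - 1) * ne[1] * ne[2], "+")
    out <- out + w * evv[lin]
  }
  out[!valid] <- NA_real_
  out
}

#' Gamma index between two dose grids
#'
#' Computes the standard gamma index of `evaluated` against `reference` on
#' the reference lattice: for each reference point above the low-dose cutoff,
#' \deqn{\gamma = \min_p \sqrt{\Delta r(p)^2 / DTA^2 +
#'   \Delta D(p)^2 / \Delta D_c^2},}
#' where `p` ranges over evaluated-dose samples (trilinearly interpolated at
#' `subsample` points per DTA) within the search radius, and the dose
#' criterion \eqn{\Delta D_c} is `dose_criterion_pct` of the reference
#' maximum (global normalization). Works on single-slice grids, so 2-D planes
#' are compared by giving them a third dimension of length 1.
#'
#' @param reference,evaluated [volume_grid()] dose grids; lattices may
#'   differ, but must overlap.
#' @param spec A [gamma_spec()].
#' @return List with `gamma` (array on the reference lattice, `NA` below the
#'   cutoff), `passing_rate_pct`, `pass` (rate at or above the threshold) and
#'   `n_points`.
#' @export
gamma_index <- function(reference, evaluated, spec = gamma_spec()) {
  stopifnot(inherits(reference, "volume_grid"),
            inherits(evaluated, "volume_grid"),
            inherits(spec, "gamma_spec"))
  R <- reference$values
  if (any(!is.finite(R)) || any(!is.finite(evaluated$values)))
    stop("dose grids must be finite")
  dmax <- max(R)
  if (dmax <= 0) stop("reference grid has no positive dose")
  dd <- spec$dose_criterion_pct / 100 * dmax
  sel <- R >= spec$low_dose_cutoff_pct / 100 * dmax
  if (!any(sel))
    stop("undefined passing rate: all reference points below the cutoff")

  step <- spec$dta_mm / spec$subsample
  radius <- spec$search_radius_mult * spec$dta_mm
  ax_off <- function(a) {
    # a flat axis (single slice in both grids) is not searched
    if (dim(R)[a] == 1L && dim(evaluated$values)[a] == 1L) return(0)
    s <- seq(0, radius, by = step)
    sort(unique(c(-s, s)))
  }
  offs <- expand.grid(x = ax_off(1), y = ax_off(2), z = ax_off(3))
  dist2 <- offs$x^2 + offs$y^2 + offs$z^2
  keep <- dist2 <= radius^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  dist2 <- dist2[keep]
  o <- order(dist2)
  offs <- offs[o, , drop = FALSE]
  dist2 <- dist2[o]

  g2 <- array(Inf, dim(R))
  cap2 <- spec$search_radius_mult^2
  for (i in seq_len(nrow(offs))) {
    base2 <- dist2[i] / spec$dta_mm^2
    worst <- suppressWarnings(max(g2[sel]))
    if (base2 >= min(worst, cap2)) break
    ev <- .shifted_eval(reference, evaluated, as.numeric(offs[i, ]))
    cand <- base2 + ((ev - R) / dd)^2
    better <- !is.na(cand) & cand < g2
    g2[better] <- cand[better]
  }
  if (all(is.infinite(g2[sel])))
    stop("disjoint geometry: no evaluated dose within the search radius")
  g <- sqrt(pmin(g2, cap2))
  rate <- 100 * mean(g[sel] <= 1 + 1e-9)
  g[!sel] <- NA_real_
  list(gamma = g, passing_rate_pct = rate,
       pass = rate >= spec$pass_threshold_pct,
       n_points = sum(sel))
}

#' Gamma passing rate (percent)
#'
#' Convenience wrapper around [gamma_index()] returning only the passing
#' rate, with the pass/fail flag against the clinical threshold attached as
#' an attribute.
#'
#' @inheritParams gamma_index
#' @return Passing rate in percent with attribute `pass`.
#' @export
gamma_passing_rate <- function(reference, evaluated, spec = gamma_spec()) {
  res <- gamma_index(reference, evaluated, spec)
  structure(res$passing_rate_pct, pass = res$pass)
}
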