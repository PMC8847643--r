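# Shared fixtures and independent oracles, all built in code.

# Coarse realistic phantom for fast simulator tests
coarse_phantom <- function(spacing_mm = 6, ...) {
  build_thorax_phantom(phantom_spec(spacing_mm = spacing_mm, ...))
}

# Memoised copies of the phantoms several files reuse
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Small uniform dose grid: `inside_gy` on the mask, `outside_gy` elsewhere
uniform_dose <- function(mask_grid, mask, inside_gy, outside_gy = 0) {
  vals <- array(outside_gy, dim(mask))
  vals[mask] <- inside_gy
  volume_grid(vals, spacing_mm = mask_grid$spacing,
              origin_mm = mask_grid$origin)
}

# Independent bisection oracle for the partial-arc angle equation
bisect_theta <- function(R, Lt, V_W, V_OW, v5, margin = 4,
                         tol = 1e-12) {
  f <- function(th)
    pi * R^2 * (360 - th) / 360 * (Lt + margin) + V_OW - V_W * (1 - v5)
  stats::uniroot(f, c(0, 360), tol = tol)$root
}

# Brute-force gamma oracle: per reference voxel, exhaustive search over
# interpolated evaluated samples. Independent implementation path from
# gamma_index(): explicit per-voxel loops and its own trilinear code.
brute_gamma_rate <- function(reference, evaluated, spec) {
  R <- reference$values
  dims <- dim(R)
  dmax <- max(R)
  dd <- spec$dose_criterion_pct / 100 * dmax
  step <- spec$dta_mm / spec$subsample
  radius <- spec$search_radius_mult * spec$dta_mm
  ax <- function(a) {
    if (dims[a] == 1L && dim(evaluated$values)[a] == 1L) return(0)
    s <- seq(0, radius, by = step)
    sort(unique(c(-s, s)))
  }
  offs <- as.matrix(expand.grid(ax(1), ax(2), ax(3)))
  offs <- offs[rowSums(offs^2) <= radius^2 + 1e-9, , drop = FALSE]
  dist2 <- rowSums(offs^2)
  ord <- order(dist2)
  offs <- offs[ord, , drop = FALSE]
  dist2 <- dist2[ord]

  interp_eval <- function(pos_mm) {    # own trilinear interpolation
    idx <- (pos_mm - evaluated$origin) / evaluated$spacing + 1
    f <- floor(idx); w <- idx - f
    tot <- 0
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      i <- f + c(c1, c2, c3)
      wt <- prod(ifelse(c(c1, c2, c3) == 1, w, 1 - w))
      if (wt < 1e-12) next
      if (any(i < 1) || any(i > dim(evaluated$values))) return(NA_real_)
      tot <- tot + wt * evaluated$values[i[1], i[2], i[3]]
    }
    tot
  }

  sel <- which(R >= spec$low_dose_cutoff_pct / 100 * dmax, arr.ind = TRUE)
  pass <- logical(nrow(sel))
  for (v in seq_len(nrow(sel))) {
    ijk <- sel[v, ]
    pos <- reference$origin + (ijk - 1) * reference$spacing
    dref <- R[ijk[1], ijk[2], ijk[3]]
    g2min <- Inf
    for (o in seq_len(nrow(offs))) {
      base2 <- dist2[o] / spec$dta_mm^2
      if (base2 >= min(g2min, 1)) break   # offsets sorted by distance
      de <- interp_eval(pos + offs[o, ])
      if (is.na(de)) next
      g2 <- base2 + ((de - dref) / dd)^2
      if (g2 < g2min) g2min <- g2
    }
    pass[v] <- g2min <= 1 + 1e-9
  }
  100 * mean(pass)
}

# Smooth 3-D dose blob for gamma fixtures: Gaussian bump plus optional
# rigid shift (mm) and a steep lateral edge
gamma_fixture <- function(n = 20, spacing = 2, shift_mm = c(0, 0, 0),
                          edge = FALSE, sigma_mm = 14) {
  org <- -(n - 1) / 2 * rep(spacing, 3)
  ax <- function(a) org[a] + (seq_len(n) - 1) * spacing - shift_mm[a]
  r2 <- outer(outer(ax(1)^2, ax(2)^2, "+"), ax(3)^2, "+")
  vals <- 10 * exp(-r2 / (2 * sigma_mm^2))
  if (edge) {
    xpos <- ax(1) > 0
    vals <- vals * array(rep(ifelse(xpos, 1, 0.45), n * n), c(n, n, n))
  }
  volume_grid(vals, spacing_mm = spacing)
}
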