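#' Scalar volume on a regular 3-D lattice
#'
#' A `volume_grid` couples a voxel array with its physical geometry. The axis
#' convention is fixed throughout the package: dimension 1 runs patient
#' left to right (x), dimension 2 posterior to anterior (y), dimension 3
#' inferior to superior (z). `origin_mm` is the physical coordinate (mm) of
#' the centre of voxel `(1, 1, 1)`; by default the lattice is centred on the
#' physical origin. Values are in Gy for dose grids and dimensionless for
#' masks.
#'
#' @param values 3-D numeric or logical array of voxel values.
#' @param spacing_mm Voxel size in mm, a single number or a length-3 vector
#'   (x, y, z). Must be strictly positive.
#' @param origin_mm Physical coordinate (mm) of the centre of voxel
#'   `(1, 1, 1)`; defaults to centring the grid on the origin.
#' @return An object of class `volume_grid` with fields `values`, `spacing`
#'   (mm) and `origin` (mm).
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 2)), spacing_mm = 3)
#' voxel_volume_cm3(g)
#' @export
volume_grid <- function(values, spacing_mm, origin_mm = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (x, y, z)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers")
  if (is.null(origin_mm)) origin_mm <- -(dim(values) - 1) / 2 * spacing_mm
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers")
  structure(list(values = values, spacing = spacing_mm, origin = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"),
      " mm\n", sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat("  value range: ", format(min(v)), " .. ", format(max(v)), "\n",
        sep = "")
  invisible(x)
}

#' Physical voxel-centre coordinates along one axis
#'
#' @param x A `volume_grid` or `structure_set`.
#' @param axis Axis index: 1 = x (left-right), 2 = y (posterior-anterior),
#'   3 = z (inferior-superior).
#' @return Numeric vector of voxel-centre coordinates in cm.
#' @export
voxel_centers_cm <- function(x, axis) {
  n <- grid_shape(x)[axis]
  (x$origin[axis] + (seq_len(n) - 1) * x$spacing[axis]) / 10
}

#' Volume of one voxel in cm^3
#' @param x A `volume_grid` or `structure_set`.
#' @export
voxel_volume_cm3 <- function(x) prod(x$spacing) / 1000

#' @rdname voxel_centers_cm
#' @export
grid_shape <- function(x) {
  if (inherits(x, "volume_grid")) dim(x$values) else x$shape
}

#' Named binary structure masks on a shared lattice
#'
#' Holds the segmentation of a (real or synthetic) thorax: body outline,
#' lungs, target and organs at risk, all as logical voxel arrays on one
#' lattice. `BODY`, `PTV` and `LUNG_WHOLE` are required; when `LUNG_L` and
#' `LUNG_R` are present their union must equal `LUNG_WHOLE`. Every mask must
#' be contained in `BODY`. The target may overlap the lung masks (a
#' mediastinal target abuts lung).
#'
#' @param masks Named list of logical arrays of identical dimension. Standard
#'   names: `BODY`, `LUNG_L`, `LUNG_R`, `LUNG_WHOLE`, `PTV`, `HEART`, `CORD`.
#' @inheritParams volume_grid
#' @return An object of class `structure_set` with fields `masks`, `spacing`
#'   (mm), `origin` (mm) and `shape`.
#' @export
structure_set <- function(masks, spacing_mm, origin_mm = NULL) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a named list of logical arrays")
  need <- c("BODY", "PTV", "LUNG_WHOLE")
  miss <- setdiff(need, names(masks))
  if (length(miss))
    stop("missing required masks: ", paste(miss, collapse = ", "))
  masks <- lapply(masks, function(m) {
    m <- as.array(m)
    storage.mode(m) <- "logical"
    m
  })
  shp <- dim(masks[[1L]])
  if (length(shp) != 3L) stop("masks must be 3-D arrays")
  ok <- vapply(masks, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stop("all masks must share one lattice")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  if (is.null(origin_mm)) origin_mm <- -(shp - 1) / 2 * spacing_mm
  body <- masks$BODY
  for (nm in setdiff(names(masks), "BODY"))
    if (any(masks[[nm]] & !body))
      stop("mask '", nm, "' extends outside BODY")
  if (all(c("LUNG_L", "LUNG_R") %in% names(masks))) {
    if (!identical(masks$LUNG_WHOLE, masks$LUNG_L | masks$LUNG_R))
      stop("LUNG_WHOLE must equal LUNG_L | LUNG_R")
  }
  structure(list(masks = masks, spacing = spacing_mm,
                 origin = as.numeric(origin_mm), shape = shp),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> ", paste(x$shape, collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = "/"),
      " mm\n", sep = "")
  vv <- voxel_volume_cm3(x)
  for (nm in names(x$masks))
    cat(sprintf("  %-10s %8.1f cm^3\n", nm, sum(x$masks[[nm]]) * vv))
  invisible(x)
}

#' Volume of one structure in cm^3
#'
#' @param structs A `structure_set`.
#' @param name Mask name, e.g. `"LUNG_WHOLE"`.
#' @export
mask_volume_cm3 <- function(structs, name) {
  if (!name %in% names(structs$masks))
    stop("no mask named '", name, "'")
  sum(structs$masks[[name]]) * voxel_volume_cm3(structs)
}
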