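# File formats: NIfTI rasters (via RNifti) with a YAML sidecar carrying the
# authoritative geometry, JSON arc plans and reports (jsonlite), CSV DVH
# exports. Every writer stamps a provenance block (package version + content
# hash); no timestamps, so identical runs produce identical bytes.

.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor into the low byte (h can exceed the integer range; stay in doubles)
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply, split so every product stays double-exact
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(payload)
  list(package = "vbarc",
       version = as.character(utils::packageVersion("vbarc")),
       content_hash = .fnv1a(payload))

.sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write / read a volume raster
#'
#' The voxel array is stored as NIfTI (readable by any imaging toolkit); the
#' geometry (spacing, origin, axis order) is carried authoritatively in a
#' plain-text YAML sidecar `<path>.meta.yaml` so a round trip is lossless.
#'
#' @param grid A [volume_grid()].
#' @param path Output path (conventionally `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_grid()].
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$values * 1)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  meta <- list(format = "vbarc-volume", shape = as.integer(dim(grid$values)),
               spacing_mm = grid$spacing, origin_mm = grid$origin,
               axis_order = "x:left-right y:posterior-anterior z:inferior-superior")
  meta$provenance <- .provenance(yaml::as.yaml(meta))
  yaml::write_yaml(meta, .sidecar_path(path))
  invisible(path)
}

.read_sidecar <- function(path, expect_format) {
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar file: ", sc)
  meta <- yaml::read_yaml(sc)
  need <- c("format", "shape", "spacing_mm", "origin_mm")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("malformed sidecar ", sc, ": missing field(s) ",
         paste(miss, collapse = ", "))
  if (!identical(meta$format, expect_format))
    stop("sidecar ", sc, " has format '", meta$format, "', expected '",
         expect_format, "'")
  meta
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- .read_sidecar(path, "vbarc-volume")
  vals <- as.array(RNifti::readNifti(path))
  attributes(vals) <- list(dim = dim(vals))   # drop RNifti bookkeeping
  if (!identical(dim(vals), as.integer(meta$shape)))
    stop("raster ", path, " has shape ", paste(dim(vals), collapse = "x"),
         " but sidecar declares ", paste(meta$shape, collapse = "x"),
         " (truncated or partial file?)")
  volume_grid(vals, spacing_mm = as.numeric(meta$spacing_mm),
              origin_mm = as.numeric(meta$origin_mm))
}

#' Write / read a structure set
#'
#' Each mask is written as `<prefix>_<NAME>.nii.gz`; the shared geometry and
#' the mask list live in `<prefix>.meta.yaml`.
#'
#' @param structs A [structure_set()].
#' @param prefix Path prefix for the mask files.
#' @export
write_structure_set <- function(structs, prefix) {
  stopifnot(inherits(structs, "structure_set"))
  for (nm in names(structs$masks)) {
    img <- RNifti::asNifti(structs$masks[[nm]] * 1L)
    RNifti::pixdim(img) <- structs$spacing
    RNifti::writeNifti(img, paste0(prefix, "_", nm, ".nii.gz"))
  }
  meta <- list(format = "vbarc-structure-set",
               shape = as.integer(structs$shape),
               spacing_mm = structs$spacing, origin_mm = structs$origin,
               masks = names(structs$masks),
               axis_order = "x:left-right y:posterior-anterior z:inferior-superior")
  meta$provenance <- .provenance(yaml::as.yaml(meta))
  yaml::write_yaml(meta, paste0(prefix, ".meta.yaml"))
  invisible(prefix)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(prefix) {
  sc <- paste0(prefix, ".meta.yaml")
  if (!file.exists(sc)) stop("missing sidecar file: ", sc)
  meta <- yaml::read_yaml(sc)
  if (!identical(meta$format, "vbarc-structure-set"))
    stop("malformed sidecar ", sc)
  masks <- lapply(meta$masks, function(nm) {
    arr <- as.array(RNifti::readNifti(paste0(prefix, "_", nm, ".nii.gz")))
    arr > 0.5
  })
  names(masks) <- meta$masks
  structure_set(masks, spacing_mm = as.numeric(meta$spacing_mm),
                origin_mm = as.numeric(meta$origin_mm))
}

#' Write / read an arc plan as JSON
#'
#' Gantry angles are serialized at 0.1 degree precision (the precision at
#' which arcs are reported clinically); all other fields are exact.
#'
#' @param plan An `arc_plan`.
#' @param path Output `.json` path.
#' @param digits Decimal places kept for the gantry angles.
#' @export
write_arc_plan <- function(plan, path, digits = 1) {
  stopifnot(inherits(plan, "arc_plan"))
  arcs <- plan$arcs
  arcs$start <- round(arcs$start, digits)
  arcs$stop <- round(arcs$stop, digits)
  body <- list(format = "vbarc-arc-plan", plan_type = plan$plan_type,
               gantry_spacing = plan$gantry_spacing,
               max_seconds_per_arc = plan$max_seconds_per_arc,
               arcs = arcs)
  body$provenance <- .provenance(
    jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_arc_plan
#' @export
read_arc_plan <- function(path) {
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(body$format, "vbarc-arc-plan"))
    stop("not an arc-plan file: ", path)
  .new_arc_plan(as.data.frame(body$arcs), body$plan_type,
                body$gantry_spacing, body$max_seconds_per_arc)
}

#' Write / read a DVH curve as CSV
#'
#' Columns `dose_gy, volume_pct`; the structure name, absolute volume and bin
#' width are carried in `#`-prefixed header comments.
#'
#' @param dvh A `dvh_curve`.
#' @param path Output `.csv` path.
#' @export
write_dvh <- function(dvh, path) {
  stopifnot(inherits(dvh, "dvh_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# structure: ", attr(dvh, "structure")),
               paste0("# volume_cm3: ", format(attr(dvh, "volume_cm3"),
                                               digits = 15)),
               paste0("# bin_width_gy: ", format(attr(dvh, "bin_width_gy"),
                                                 digits = 15))), con)
  utils::write.csv(as.data.frame(dvh)[, c("dose_gy", "volume_pct")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  field <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("malformed DVH file ", path, ": missing ", key)
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  out <- utils::read.csv(path, comment.char = "#")
  if (!all(c("dose_gy", "volume_pct") %in% names(out)))
    stop("malformed DVH file ", path, ": need dose_gy, volume_pct columns")
  attr(out, "structure") <- field("structure")
  attr(out, "volume_cm3") <- as.numeric(field("volume_cm3"))
  attr(out, "bin_width_gy") <- as.numeric(field("bin_width_gy"))
  class(out) <- c("dvh_curve", "data.frame")
  out
}
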