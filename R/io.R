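#' Write a velocity field to NIfTI component files
#'
#' One 4D NIfTI per velocity component (`<prefix>_vx.nii`, `_vy`, `_vz`)
#' plus a JSON sidecar (`<prefix>.json`) with spacing (mm), origin, frame
#' times (ms) and VENC (cm/s).
#'
#' @param field a [velocity_field()].
#' @param prefix output path prefix.
#' @param compress write `.nii.gz` instead of `.nii`.
#' @return the sidecar path, invisibly.
#' @export
write_velocity_field <- function(field, prefix, compress = FALSE) {
  ext <- if (compress) ".nii.gz" else ".nii"
  comp <- c("vx", "vy", "vz")
  for (cc in comp) {
    dt <- if (length(field$times) > 1) diff(field$times[1:2]) else 1
    img <- RNifti::asNifti(field[[cc]], pixdim = c(field$spacing, dt))
    RNifti::writeNifti(img, paste0(prefix, "_", cc, ext))
  }
  sidecar <- list(spacing_mm = field$spacing, origin_mm = field$origin,
                  times_ms = field$times, venc_cms = field$venc,
                  components = paste0(basename(prefix), "_", comp, ext))
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a velocity field written by [write_velocity_field()]
#'
#' Validates that the three component files exist and agree in shape. A
#' missing VENC entry loads as `NA` with a warning (downstream noise
#' checks are disabled in that case).
#'
#' @param prefix path prefix used at write time (or the sidecar path).
#' @return a [velocity_field()].
#' @export
read_velocity_field <- function(prefix) {
  sidecar_path <- if (grepl("\\.json$", prefix)) prefix else paste0(prefix, ".json")
  if (!file.exists(sidecar_path)) stop("missing sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  dir <- dirname(sidecar_path)
  arrs <- lapply(meta$components, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing component file: ", path)
    a <- as.array(RNifti::readNifti(path))
    a <- array(as.vector(a), dim(a))  # plain array, no image attributes
    if (length(dim(a)) == 3) a <- array(a, c(dim(a), 1))
    a
  })
  d <- dim(arrs[[1]])
  for (k in 2:3) if (!identical(dim(arrs[[k]]), d))
    stop("component shape mismatch in ", meta$components[k])
  venc <- meta$venc_cms
  if (is.null(venc) || length(venc) == 0 || all(is.na(venc))) {
    warning("sidecar has no venc; noise-level checks disabled")
    venc <- NA_real_
  }
  velocity_field(arrs[[1]], arrs[[2]], arrs[[3]],
                 spacing = meta$spacing_mm, origin = meta$origin_mm,
                 times = meta$times_ms, venc = venc)
}

#' Write / read a 2D mask as NIfTI
#' @param mask logical matrix.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing pixel spacing, mm.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = 1) {
  img <- RNifti::asNifti(array(mask * 1L, dim = c(dim(mask), 1)),
                         pixdim = c(spacing, spacing, 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Write / read a centerline with landmarks as CSV
#'
#' CSV with columns `x`, `y`, `z` (mm) and, on landmark rows, `landmark`.
#'
#' @param cl a [centerline()].
#' @param path CSV path.
#' @return `path` invisibly / a [centerline()].
#' @export
write_centerline <- function(cl, path) {
  d <- data.frame(x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
                  landmark = "", stringsAsFactors = FALSE)
  for (nm in names(cl$landmarks)) {
    i <- which.min(abs(cl$arc - cl$landmarks[nm]))
    d$landmark[i] <- nm
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pts <- as.matrix(d[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  li <- which(nzchar(d$landmark))
  lm <- stats::setNames(arc[li], d$landmark[li])
  centerline(pts, lm)
}

#' Default run configuration
#'
#' All defaults match the standardized analysis settings: 1 mm MPR
#' resolution, the fixed normalization ranges, bin width 25, the
#' 5 + 3 intermediate plane split (12 planes total), two-way random
#' absolute-agreement single-rating ICC with the moderate selection
#' threshold, and stratified 5-fold cross-validation.
#'
#' @param seed master seed.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    mpr_resolution_mm = 1,
    bin_width = 25,
    n_ascending = 5L, n_descending = 3L,
    normalization = lapply(
      c("throughflow", "wpd", "angle", "lnh", "vorticity"),
      normalization_spec),
    icc_model = "two_way_random_absolute_single",
    min_category = "moderate",
    protocol = "stratified 5-fold CV",
    n_folds = 5L,
    lambda = 1e-2,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Serialize / load a run configuration (YAML)
#' @param config a `run_config`.
#' @param path YAML path.
#' @return `path` invisibly / a `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base$seed <- as.integer(base$seed)
  base
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash; enough to fingerprint a config in logs
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
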