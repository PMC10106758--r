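#' Fixed-bin-width discretization of a parameter map
#'
#' Maps ROI pixel intensities to 1-based integer gray levels with bins of
#' constant width anchored at the ROI minimum:
#' `level = floor((value - min_ROI) / bin_width) + 1`. With the fixed
#' normalization ranges, a bin width of 25 normalized units yields at most
#' 164 levels over a full `[0, 4096]` span.
#'
#' @param map a normalized `parameter_map` (see [normalize_map()]), or a
#'   plain numeric matrix.
#' @param bin_width bin width in normalized intensity units.
#' @param mask optional ROI mask; defaults to the map's mask, then to its
#'   valid pixels.
#' @return an object of class `discretized_map`: integer `levels` matrix
#'   (`NA` outside the ROI), `n_levels`, `bin_width`, `mask`, `spacing`.
#' @export
discretize <- function(map, bin_width = 25, mask = NULL) {
  if (inherits(map, "parameter_map")) {
    vals <- map$values
    if (is.null(mask)) mask <- map$mask %||% map$valid
    spacing <- map$spacing %||% 1
  } else {
    vals <- map
    if (is.null(mask)) mask <- !is.na(vals)
    spacing <- 1
  }
  stopifnot(bin_width > 0)
  if (!any(mask)) stop("empty ROI: nothing to discretize")
  v <- vals[mask]
  if (any(!is.finite(v))) stop("non-finite values inside the ROI")
  lev <- matrix(NA_integer_, nrow(vals), ncol(vals))
  lev[mask] <- as.integer(floor((v - min(v)) / bin_width) + 1)
  structure(list(levels = lev, n_levels = max(lev, na.rm = TRUE),
                 bin_width = bin_width, mask = mask, spacing = spacing),
            class = "discretized_map")
}

#' Label connected components of a binary mask
#'
#' Two-dimensional connected-component labeling by iterative flood fill,
#' 8- or 4-connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background), labels
#'   numbered from 1 in first-encounter order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  nu <- nrow(mask); nv <- ncol(mask)
  lab <- matrix(0L, nu, nv)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  stack <- integer(sum(mask))
  seeds <- which(mask)
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      i <- ((p - 1L) %% nu) + 1L
      j <- ((p - 1L) %/% nu) + 1L
      for (k in seq_len(nrow(offs))) {
        ni <- i + offs[k, 1]; nj <- j + offs[k, 2]
        if (ni >= 1L && ni <= nu && nj >= 1L && nj <= nv) {
          q <- (nj - 1L) * nu + ni
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}
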