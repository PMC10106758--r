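#' Default radiomics feature catalogue
#'
#' The shipped catalogue keeps 79 features per parameter map and 16 shape
#' features, for 5 x 79 + 16 = 411 features per plane and timeframe. The six
#' per-map families total 93 under their full definitions (18 first-order +
#' 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM); a 14-feature default
#' exclusion list removes near-duplicates — total energy and range
#' (first-order), sum average / sum of squares / joint average (linear
#' transforms of other GLCM features), the informational-correlation trio
#' MCC/Imc1/Imc2 and Idmn (GLCM), and the normalized non-uniformity variants
#' (GLRLM, GLSZM, GLDM).
#'
#' @return list with elements `families` (named list: family -> kept feature
#'   names) and `shape` (kept shape feature names).
#' @export
default_catalogue <- function() {
  excl <- list(
    firstorder = c("TotalEnergy", "Range"),
    glcm = c("SumAverage", "SumSquares", "MCC", "Imc1", "Imc2", "Idmn",
             "JointAverage"),
    glrlm = c("GrayLevelNonUniformityNormalized",
              "RunLengthNonUniformityNormalized"),
    glszm = c("GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformityNormalized"),
    gldm = c("DependenceNonUniformityNormalized"),
    ngtdm = character(0)
  )
  full <- full_feature_names()
  fams <- lapply(names(full$families), function(f)
    setdiff(full$families[[f]], excl[[f]]))
  names(fams) <- names(full$families)
  list(families = fams, shape = full$shape)
}

# every feature name each family function emits, in emission order
full_feature_names <- function() {
  toy <- discretize(matrix(c(1, 2, 60, 4), 2, 2), bin_width = 25)
  list(families = list(
    firstorder = names(first_order_features(matrix(c(1, 2, 60, 4), 2, 2),
                                            d = toy)),
    glcm = names(glcm_features(toy)),
    glrlm = names(glrlm_features(toy)),
    glszm = names(glszm_features(toy)),
    gldm = names(gldm_features(toy)),
    ngtdm = names(ngtdm_features(toy))
  ),
  shape = names(shape2d_features(matrix(TRUE, 3, 3))))
}

#' Extract the radiomics signature of one plane and timeframe
#'
#' Discretizes each of the five normalized parameter maps with the fixed bin
#' width and computes the six per-map feature families (79 features per map
#' under the default catalogue) plus the 16 contour shape features — exactly
#' 411 named values.
#'
#' @param maps named list of the five normalized `parameter_map`s
#'   (`throughflow`, `wpd`, `angle`, `lnh`, `vorticity`), sharing grid and
#'   ROI.
#' @param mask logical ROI matrix.
#' @param reference_mask reference-frame ROI for the motion shape features.
#' @param bin_width discretization bin width (normalized units).
#' @param catalogue feature catalogue, see [default_catalogue()].
#' @param spacing pixel spacing, mm.
#' @return named numeric vector; names are `<map>__<family>__<feature>` and
#'   `shape__<feature>`.
#' @export
extract_signature <- function(maps, mask, reference_mask = mask,
                              bin_width = 25, catalogue = default_catalogue(),
                              spacing = 1) {
  kinds <- c("throughflow", "wpd", "angle", "lnh", "vorticity")
  if (!all(kinds %in% names(maps)))
    stop("maps must contain: ", paste(kinds, collapse = ", "))
  out <- list()
  for (kind in kinds) {
    m <- maps[[kind]]
    if (!isTRUE(m$normalized))
      stop("map '", kind, "' must be normalized before feature extraction")
    d <- tryCatch(discretize(m, bin_width, mask),
                  error = function(e) stop("map '", kind,
                                           "': discretization failed: ",
                                           conditionMessage(e)))
    fam_vals <- list(
      firstorder = function() first_order_features(m, d = d, mask = mask),
      glcm = function() glcm_features(d),
      glrlm = function() glrlm_features(d),
      glszm = function() glszm_features(d),
      gldm = function() gldm_features(d),
      ngtdm = function() ngtdm_features(d)
    )
    for (fam in names(catalogue$families)) {
      v <- tryCatch(fam_vals[[fam]](),
                    error = function(e) stop("map '", kind, "', family '",
                                             fam, "': ",
                                             conditionMessage(e)))
      keep <- catalogue$families[[fam]]
      v <- v[keep]
      names(v) <- paste0(kind, "__", fam, "__", keep)
      out[[length(out) + 1]] <- v
    }
  }
  sh <- shape2d_features(mask, spacing, reference_mask)[catalogue$shape]
  names(sh) <- paste0("shape__", catalogue$shape)
  out[[length(out) + 1]] <- sh
  res <- unlist(out)
  if (any(!is.finite(res)))
    stop("non-finite features: ",
         paste(utils::head(names(res)[!is.finite(res)], 5), collapse = ", "))
  res
}

#' Signature over all timeframes of a plane
#'
#' Runs [compute_parameter_maps()] and [extract_signature()] for every
#' timeframe, propagating the ROI by centroid tracking from the reference
#' frame.
#'
#' @param field a [velocity_field()].
#' @param plane a `plane_definition`.
#' @param mask reference-frame ROI on the plane grid.
#' @param timeframes frames to process (default all).
#' @param reference_frame frame the mask is defined on.
#' @param bin_width,catalogue,spacing passed through.
#' @return matrix: one row per timeframe, 411 feature columns.
#' @export
signature_curves <- function(field, plane, mask,
                             timeframes = seq_along(field$times),
                             reference_frame = timeframes[1],
                             bin_width = 25, catalogue = default_catalogue(),
                             spacing = 1) {
  samples <- lapply(timeframes, function(t) resample_mpr(field, plane, t, spacing))
  masks <- propagate_roi(mask, samples)
  rows <- lapply(seq_along(timeframes), function(k) {
    t <- timeframes[k]
    maps <- compute_parameter_maps(field, plane, t, mask = masks[[k]],
                                   spacing = spacing)
    extract_signature(maps, masks[[k]], reference_mask = mask,
                      bin_width = bin_width, catalogue = catalogue,
                      spacing = spacing)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- timeframes
  mat
}
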