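#' Resample a feature curve onto a uniform cycle grid
#'
#' Feature curves from scanners with lower temporal resolution are linearly
#' upsampled to a common grid so they can be compared at the finest temporal
#' sampling. Times are normalized to cycle fraction in `[0, 1]` (heart rates
#' differ across scanners, so absolute milliseconds are not comparable); the
#' target grid is `seq(0, 1, length.out = target_n)` and endpoints are
#' preserved.
#'
#' @param values per-timeframe feature values.
#' @param target_n number of output samples (>= 2).
#' @param times frame times; any monotone scale (normalized internally).
#' @return list with `values` and `times` (cycle fraction) of length
#'   `target_n`.
#' @export
upsample_curve <- function(values, target_n, times = NULL) {
  if (target_n < 2) stop("target_n must be at least 2")
  n <- length(values)
  if (n < 2) stop("curve needs at least 2 frames")
  if (is.null(times)) times <- seq(0, 1, length.out = n)
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  f <- (times - times[1]) / (times[n] - times[1])
  out_t <- seq(0, 1, length.out = target_n)
  list(values = stats::approx(f, values, xout = out_t)$y, times = out_t)
}

#' Intraclass correlation coefficient
#'
#' Two-way ANOVA decomposition of a complete units-by-raters matrix. The
#' default is the two-way random-effects, absolute-agreement, single-rating
#' form `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`; the
#' consistency form `(MSR - MSE) / (MSR + (k-1) MSE)` ignores systematic
#' rater offsets. A matrix with zero total variance is perfect agreement by
#' definition: the ICC is 1 with a `degenerate` attribute.
#'
#' @param ratings numeric matrix, one row per unit, one column per rater;
#'   no missing cells.
#' @param model `"two_way_random_absolute_single"` (default) or
#'   `"two_way_mixed_consistency_single"`.
#' @return the ICC value (attributes: `model`, `n_units`, `n_raters`,
#'   `degenerate`).
#' @export
icc <- function(ratings,
                model = c("two_way_random_absolute_single",
                          "two_way_mixed_consistency_single")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 units and 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be complete and finite")
  gm <- mean(ratings)
  if (sum((ratings - gm)^2) < 1e-24) {
    return(structure(1, model = model, n_units = n, n_raters = k,
                     degenerate = TRUE))
  }
  rm_ <- rowMeans(ratings)
  cm_ <- colMeans(ratings)
  ssr <- k * sum((rm_ - gm)^2)            # between units (rows)
  ssc <- n * sum((cm_ - gm)^2)            # between raters (columns)
  sst <- sum((ratings - gm)^2)
  sse <- sst - ssr - ssc                  # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- if (model == "two_way_random_absolute_single") {
    den <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (den <= 0) 1 else (msr - mse) / den
  } else {
    den <- msr + (k - 1) * mse
    if (den <= 0) 1 else (msr - mse) / den
  }
  structure(val, model = model, n_units = n, n_raters = k, degenerate = FALSE)
}

#' Categorize an ICC value
#'
#' Reproducibility categories: below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to
#' 0.9 good, above 0.9 excellent. Boundary convention: 0.5 and 0.75 belong to
#' the higher category; 0.9 itself is good (excellent requires strictly more
#' than 0.9).
#'
#' @param value finite ICC value (may be negative).
#' @return ordered factor with levels poor < moderate < good < excellent.
#' @export
categorize_icc <- function(value) {
  stopifnot(all(is.finite(value)))
  lv <- c("poor", "moderate", "good", "excellent")
  cat <- ifelse(value > 0.9, "excellent",
         ifelse(value >= 0.75, "good",
         ifelse(value >= 0.5, "moderate", "poor")))
  factor(cat, levels = lv, ordered = TRUE)
}

#' Per-feature reproducibility table across raters
#'
#' Builds, for every feature, a complete ratings matrix with one row per
#' (subject, plane, timeframe) unit and one column per rater (scanner or
#' observer), then computes the ICC and its category. Curves from raters
#' with fewer timeframes must be upsampled to the common grid beforehand
#' (see [upsample_curve()]); this function requires complete rater coverage
#' and errors with the missing cells otherwise.
#'
#' @param features long-format data frame with columns `subject`, `rater`,
#'   `plane`, `timeframe`, `feature`, `value`.
#' @param model ICC model passed to [icc()].
#' @return data frame: `feature`, `icc`, `model`, `n_units`, `n_raters`,
#'   `category`.
#' @export
reproducibility_table <- function(features,
                                  model = "two_way_random_absolute_single") {
  need <- c("subject", "rater", "plane", "timeframe", "feature", "value")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  features$unit <- interaction(features$subject, features$plane,
                               features$timeframe, drop = TRUE)
  raters <- sort(unique(features$rater))
  feats <- unique(features$feature)
  res <- lapply(feats, function(f) {
    d <- features[features$feature == f, ]
    tab <- stats::xtabs(value ~ unit + rater, data = d)
    cnt <- stats::xtabs(~ unit + rater, data = d)
    if (any(cnt != 1)) {
      miss <- which(cnt == 0, arr.ind = TRUE)
      stop("incomplete rater coverage for feature '", f, "': ",
           nrow(miss), " missing (unit, rater) cells")
    }
    v <- icc(as.matrix(tab)[, raters, drop = FALSE], model = model)
    data.frame(feature = f, icc = as.numeric(v), model = attr(v, "model"),
               n_units = attr(v, "n_units"), n_raters = attr(v, "n_raters"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$category <- categorize_icc(out$icc)
  out
}

#' Select features reproducible across scanners and observers
#'
#' Keeps the features whose category meets `min_category` in BOTH the
#' inter-scanner and the inter-observer table (conjunction rule), in
#' deterministic (inter-scanner table) order.
#'
#' @param interscanner,interobserver data frames from
#'   [reproducibility_table()].
#' @param min_category minimum acceptable category.
#' @return list with `selected` (feature names) and `criterion` (record of
#'   thresholds and table sizes).
#' @export
select_features <- function(interscanner, interobserver,
                            min_category = "moderate") {
  lv <- c("poor", "moderate", "good", "excellent")
  min_category <- match.arg(min_category, lv)
  ok1 <- interscanner$feature[
    as.integer(interscanner$category) >= match(min_category, lv)]
  ok2 <- interobserver$feature[
    as.integer(interobserver$category) >= match(min_category, lv)]
  sel <- ok1[ok1 %in% ok2]
  if (!length(sel)) warning("no feature meets the reproducibility criterion")
  list(selected = sel,
       criterion = list(min_category = min_category,
                        n_interscanner = nrow(interscanner),
                        n_interobserver = nrow(interobserver)))
}

#' Group envelopes of feature curves
#'
#' Per group and timeframe: mean, minimum and maximum of a feature across
#' subjects. Age grouping uses the closed intervals 20-39, 40-59 and 60-80
#' years.
#'
#' @param curves data frame with columns `subject`, `feature`, `timeframe`,
#'   `value` and the grouping column.
#' @param grouping name of the grouping column (`"sex"`, `"age_group"`,
#'   `"cohort"`, ...).
#' @return data frame: group, feature, timeframe, mean, min, max, n.
#' @export
summarize_group_curves <- function(curves, grouping) {
  stopifnot(grouping %in% names(curves))
  g <- curves[[grouping]]
  keep <- !is.na(g)
  if (any(!keep)) warning(sum(!keep), " rows with empty group omitted")
  d <- curves[keep, ]
  agg <- stats::aggregate(d$value,
    by = list(group = d[[grouping]], feature = d$feature,
              timeframe = d$timeframe),
    FUN = function(x) c(mean = mean(x), min = min(x), max = max(x),
                        n = length(x)))
  out <- data.frame(agg[c("group", "feature", "timeframe")],
                    mean = agg$x[, "mean"], min = agg$x[, "min"],
                    max = agg$x[, "max"], n = agg$x[, "n"])
  out[order(out$feature, out$group, out$timeframe), ]
}

#' Assign the standard age groups
#'
#' Group 1: 20-39 years, group 2: 40-59, group 3: 60-80 (closed intervals);
#' ages outside return `NA`.
#'
#' @param age numeric ages in years.
#' @return integer group (1, 2, 3) or `NA`.
#' @export
age_group <- function(age) {
  ifelse(age >= 20 & age <= 39, 1L,
  ifelse(age >= 40 & age <= 59, 2L,
  ifelse(age >= 60 & age <= 80, 3L, NA_integer_)))
}
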