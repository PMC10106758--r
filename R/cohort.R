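#' Volume flow rate through an ROI
#'
#' Sum of throughflow velocity over the ROI times pixel area, in mL/s
#' (1 m/s over 1 mm2 is exactly 1 mL/s).
#'
#' @param throughflow a `parameter_map` of kind `"throughflow"` in native m/s
#'   (not normalized), or a numeric matrix of m/s values.
#' @param mask logical ROI matrix.
#' @param pixel_area_mm2 pixel area in mm2.
#' @return flow rate in mL/s.
#' @export
volume_flow_rate <- function(throughflow, mask = NULL, pixel_area_mm2 = NULL) {
  if (inherits(throughflow, "parameter_map")) {
    if (isTRUE(throughflow$normalized))
      stop("flow rate needs the throughflow map in native units")
    vals <- throughflow$values
    if (is.null(mask)) mask <- throughflow$mask %||% throughflow$valid
    if (is.null(pixel_area_mm2)) pixel_area_mm2 <- (throughflow$spacing %||% 1)^2
  } else {
    vals <- throughflow
    if (is.null(pixel_area_mm2)) pixel_area_mm2 <- 1
  }
  if (is.null(mask) || !any(mask)) stop("empty mask")
  sum(vals[mask]) * pixel_area_mm2
}

#' Detect the peak-systolic timeframe
#'
#' The timeframe with maximum volume flow rate; ties resolve to the earlier
#' frame.
#'
#' @param flow_rates per-timeframe volume flow rates.
#' @return 1-based timeframe index.
#' @export
detect_peak_systole <- function(flow_rates) {
  stopifnot(length(flow_rates) >= 1)
  which.max(flow_rates)  # which.max takes the first maximum
}

#' Per-plane flow-rate curve of a velocity field
#'
#' @param field a [velocity_field()].
#' @param plane a `plane_definition`.
#' @param mask ROI on the plane grid.
#' @param spacing MPR resolution, mm.
#' @return numeric vector of flow rates (mL/s), one per timeframe.
#' @export
flow_rate_curve <- function(field, plane, mask, spacing = 1) {
  vapply(seq_along(field$times), function(t) {
    s <- resample_mpr(field, plane, t, spacing)
    volume_flow_rate(throughflow_map(s), mask = mask,
                     pixel_area_mm2 = spacing^2)
  }, 1)
}

#' Train the flow-profile classifier
#'
#' Ridge-penalized logistic regression (weak L2, configurable) on z-scored
#' features, distinguishing aortic stenosis from no valve disease. Reports
#' stratified 5-fold cross-validated accuracy, F1 (positive class =
#' stenosis) and the CV confusion matrix; resubstitution metrics are also
#' computed and labeled as such.
#'
#' @param x numeric feature matrix, one row per subject.
#' @param labels factor or character; must contain exactly two classes.
#' @param positive name of the positive class (default
#'   `"aortic_stenosis"` when present, else the second level).
#' @param lambda ridge penalty.
#' @param n_folds CV folds.
#' @param seed fold-assignment seed.
#' @return list of class `flow_classifier`: `fit` (glmnet), `report` (a
#'   `classifier_report`), standardization parameters and feature names.
#' @export
train_classifier <- function(x, labels, positive = NULL, lambda = 1e-2,
                             n_folds = 5L, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2) stop("need exactly 2 classes, got ", length(cls))
  if (min(table(labels)) < 2) stop("need at least 2 subjects per class")
  if (is.null(positive))
    positive <- if ("aortic_stenosis" %in% cls) "aortic_stenosis" else cls[2]
  y <- as.integer(labels == positive)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) stop("all features are constant")
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], `/`)
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  pred_resub <- as.integer(stats::predict(fit, z, type = "response") > 0.5)
  resub <- classifier_report(y, pred_resub, positive, cls,
                             protocol = "resubstitution")
  # every CV training fold must retain at least 2 subjects per class
  n_folds <- min(n_folds, min(table(y)) %/% 2)
  if (n_folds >= 2) {
    folds <- stratified_folds(y, n_folds, seed)
    pred_cv <- integer(length(y))
    for (f in seq_len(n_folds)) {
      te <- folds == f
      ft <- glmnet::glmnet(z[!te, , drop = FALSE], y[!te],
                           family = "binomial", alpha = 0, lambda = lambda,
                           standardize = FALSE)
      pred_cv[te] <- as.integer(
        stats::predict(ft, z[te, , drop = FALSE], type = "response") > 0.5)
    }
    report <- classifier_report(y, pred_cv, positive, cls,
                                protocol = sprintf("stratified %d-fold CV",
                                                   n_folds))
  } else {
    warning("too few subjects per class for cross-validation; ",
            "reporting resubstitution only")
    report <- resub
  }
  report$resubstitution <- resub
  structure(list(fit = fit, report = report, positive = positive,
                 classes = cls, center = mu[keep], scale = sd_[keep],
                 features = colnames(x)[keep],
                 dropped_constant = colnames(x)[!keep],
                 lambda = lambda, seed = seed),
            class = "flow_classifier")
}

stratified_folds <- function(y, n_folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    folds[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  folds
}

# metrics from true/predicted 0-1 vectors; positive class coded 1
classifier_report <- function(y, pred, positive, classes, protocol) {
  tp <- sum(y == 1 & pred == 1); tn <- sum(y == 0 & pred == 0)
  fp <- sum(y == 0 & pred == 1); fn <- sum(y == 1 & pred == 0)
  cm <- matrix(c(tn, fn, fp, tp), 2, 2,
               dimnames = list(truth = c("negative", "positive"),
                               predicted = c("negative", "positive")))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(accuracy = (tp + tn) / length(y), f1 = f1,
                 confusion = cm, positive = positive, classes = classes,
                 protocol = protocol, n = length(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: accuracy %.3f, F1 %.3f (positive = %s, n = %d)\n",
              x$protocol, x$accuracy, x$f1, x$positive, x$n))
  print(x$confusion)
  invisible(x)
}

#' Rank features by classifier importance
#'
#' Features are ranked by the absolute value of their standardized logistic
#' regression coefficient, descending; ties are broken alphabetically.
#'
#' @param model a `flow_classifier` from [train_classifier()].
#' @return data frame: `feature`, `coefficient`, `importance`, `rank`.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "flow_classifier")) stop("model must be a fitted flow_classifier")
  co <- as.matrix(stats::coef(model$fit))[-1, 1]
  d <- data.frame(feature = model$features, coefficient = co,
                  importance = abs(co), stringsAsFactors = FALSE)
  d <- d[order(-d$importance, d$feature), ]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Export min-max scaled signatures for parallel-coordinates display
#'
#' Long-format table of the selected features at peak systole, min-max scaled
#' per feature across subjects (constant features scale to 0 by convention).
#' The scaling parameters are recorded so the transform is invertible.
#'
#' @param features numeric matrix, one row per subject, named feature columns.
#' @param selection character vector of selected feature names.
#' @param metadata data frame with `subject_id` and `label` rows matching
#'   `features`.
#' @return list: `table` (subject, cohort, feature, value, scaled) and
#'   `scaling` (feature, min, max).
#' @export
export_signatures <- function(features, selection, metadata) {
  if (!length(selection)) stop("selection is empty")
  sel <- intersect(selection, colnames(features))
  x <- features[, sel, drop = FALSE]
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  scl <- sweep(x, 2, lo)
  scl <- sweep(scl, 2, ifelse(rng > 0, rng, 1), `/`)
  scl[, rng == 0] <- 0
  tab <- data.frame(
    subject = rep(metadata$subject_id, times = length(sel)),
    cohort = rep(metadata$label, times = length(sel)),
    feature = rep(sel, each = nrow(x)),
    value = as.vector(x),
    scaled = as.vector(scl),
    stringsAsFactors = FALSE
  )
  list(table = tab, scaling = data.frame(feature = sel, min = lo, max = hi))
}

#' Systolic signature table for a cohort
#'
#' For every subject: generate the phantom field under the given scanner,
#' place the A1.1 analysis plane, detect peak systole by maximum volume flow
#' rate, and extract the 411-feature signature there.
#'
#' @param cohort data frame from [generate_cohort()].
#' @param scanner a [scanner_profile()] (per-subject seeds are derived from
#'   its seed).
#' @param plane_arc arc position of the analysis plane along the subject's
#'   centerline; `NULL` uses the A1.1 landmark of the straight centerline.
#' @param spacing MPR resolution, mm.
#' @return list: `features` (subjects x 411 matrix), `peak_frames`,
#'   `metadata` (the cohort data frame).
#' @export
cohort_signatures <- function(cohort, scanner = scanner_profile(),
                              plane_arc = NULL, spacing = 1) {
  n <- nrow(cohort)
  rows <- vector("list", n)
  peaks <- integer(n)
  for (i in seq_len(n)) {
    ph <- cohort$phantom[[i]]
    sc <- scanner
    sc$seed <- scanner$seed + i
    field <- generate_velocity_field(ph, sc, z_extent_mm = 14)
    cl <- straight_centerline(length_mm = 10, n_points = 11L)
    plane <- plane_at(cl, if (is.null(plane_arc)) cl$landmarks["A1.1"] else plane_arc,
                      label = "A1.1", extent = ph$tube_radius + 4)
    mask <- phantom_plane_roi(ph, plane, spacing)
    fr <- flow_rate_curve(field, plane, mask, spacing)
    peaks[i] <- detect_peak_systole(fr)
    maps <- compute_parameter_maps(field, plane, peaks[i], mask = mask,
                                   spacing = spacing)
    rows[[i]] <- extract_signature(maps, mask, spacing = spacing)
  }
  list(features = do.call(rbind, rows), peak_frames = peaks,
       metadata = cohort)
}

#' The shipped synthetic classification benchmark
#'
#' Two seeded cohorts of 30 subjects (aortic stenosis with eccentric jets and
#' elevated peak velocities vs. no valve disease), systolic signatures on
#' plane A1.1, and the default classifier.
#'
#' @param seed master seed.
#' @param n_per_cohort subjects per cohort.
#' @return list: `model` (a `flow_classifier`), `features`, `labels`,
#'   `metadata`.
#' @export
classification_benchmark <- function(seed = 1L, n_per_cohort = 30L) {
  ctrl <- generate_cohort(cohort_spec(n_per_cohort, "no_valve_disease",
                                      seed = seed))
  sten <- generate_cohort(cohort_spec(n_per_cohort, "aortic_stenosis",
                                      seed = seed + 1000L))
  sig_c <- cohort_signatures(ctrl, scanner_profile(seed = seed * 7L))
  sig_s <- cohort_signatures(sten, scanner_profile(seed = seed * 7L + 500L))
  x <- rbind(sig_c$features, sig_s$features)
  meta <- rbind(sig_c$metadata[names(sig_c$metadata) != "phantom"],
                sig_s$metadata[names(sig_s$metadata) != "phantom"])
  labels <- meta$label
  model <- train_classifier(x, labels, seed = seed)
  list(model = model, features = x, labels = labels, metadata = meta)
}
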