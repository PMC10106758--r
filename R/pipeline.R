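#' Pipeline stages
#'
#' The processing chain mirrors the analysis workflow: simulate (synthetic
#' cohort + scanner/observer replicates), planes (standardized cross-section
#' placement), features (parameter maps + radiomics signatures), icc
#' (inter-scanner / inter-observer reproducibility), select (reproducible
#' feature set), classify (stenosis vs. no-valve-disease logistic
#' regression), report (category count tables and classifier summary). Each
#' stage reads the artifacts of its predecessors from the run directory and
#' writes its own, together with a log entry carrying the config hash and
#' seed, so a run is reproducible from the config alone.
#'
#' @name pipeline
NULL

stage_log <- function(dir, stage, config, info = list()) {
  entry <- c(list(stage = stage, time = format(Sys.time()),
                  config_hash = config_hash(config), seed = config$seed),
             info)
  path <- file.path(dir, "run_log.json")
  log <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  log[[length(log) + 1]] <- entry
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA)
  invisible(entry)
}

#' @param dir run directory (created if missing).
#' @param config a `run_config` from [default_config()].
#' @param n_subjects subjects per cohort half; the demo cohort is half
#'   no-valve-disease, half aortic-stenosis.
#' @param scanners named list of [scanner_profile()]s (the first is the
#'   reference scanner used for the inter-observer arm).
#' @param observer an [observer_profile()] for the second observer.
#' @param n_timeframes frames per cycle for the demo phantoms.
#' @rdname pipeline
#' @export
stage_simulate <- function(dir, config = default_config(),
                           n_subjects = 8L,
                           scanners = list(
                             scanner1 = scanner_profile(venc = 250, seed = 11L),
                             scanner2 = scanner_profile(venc = 150,
                               velocity_scale_bias = 1.05, n_timeframes = 25L,
                               seed = 12L)),
                           observer = observer_profile(contour_jitter_mm = 0.5,
                                                       seed = 21L),
                           n_timeframes = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_ctrl <- ceiling(n_subjects / 2)
  ctrl <- generate_cohort(cohort_spec(n_ctrl, "no_valve_disease",
                                      seed = config$seed))
  sten <- generate_cohort(cohort_spec(n_subjects - n_ctrl, "aortic_stenosis",
                                      seed = config$seed + 1000L))
  cohort <- rbind(ctrl, sten)
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    ph <- cohort$phantom[[i]]
    ph$n_timeframes <- as.integer(n_timeframes)
    ph$waveform <- systolic_waveform(n_timeframes)
    for (sc_name in names(scanners)) {
      sc <- scanners[[sc_name]]
      sc$seed <- sc$seed + i * 101L
      field <- generate_velocity_field(ph, sc, z_extent_mm = 14)
      prefix <- file.path(dir, sprintf("%s_%s", cohort$subject_id[i], sc_name))
      write_velocity_field(field, prefix)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = cohort$subject_id[i], scanner = sc_name,
        label = cohort$label[i], age = cohort$age[i], sex = cohort$sex[i],
        radius = cohort$radius[i], profile = cohort$profile[i],
        peak_velocity = cohort$peak_velocity[i],
        n_timeframes = sc$n_timeframes,
        path = basename(prefix), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(contour_jitter_mm = observer$contour_jitter_mm,
         dilation_bias_mm = observer$dilation_bias_mm, seed = observer$seed),
    file.path(dir, "observer.json"), auto_unbox = TRUE, digits = NA)
  stage_log(dir, "simulate", config,
            list(n_subjects = n_subjects, n_fields = nrow(manifest)))
  invisible(manifest)
}

#' @rdname pipeline
#' @export
stage_planes <- function(dir, config = default_config()) {
  cl <- straight_centerline(length_mm = 10, n_points = 11L)
  planes <- place_planes(cl, config$n_ascending, config$n_descending,
                         extent = 25)
  write_centerline(cl, file.path(dir, "centerline.csv"))
  jsonlite::write_json(
    lapply(planes, function(p) list(label = p$label, origin = p$origin,
                                    normal = p$normal, e1 = p$e1, e2 = p$e2,
                                    extent = p$extent, arc = p$arc)),
    file.path(dir, "planes.json"), auto_unbox = TRUE, digits = NA)
  stage_log(dir, "planes", config, list(n_planes = length(planes)))
  invisible(planes)
}

read_planes <- function(dir) {
  pl <- jsonlite::read_json(file.path(dir, "planes.json"),
                            simplifyVector = FALSE)
  lapply(pl, function(p) {
    structure(list(label = p$label, origin = unlist(p$origin),
                   normal = unlist(p$normal), e1 = unlist(p$e1),
                   e2 = unlist(p$e2), extent = p$extent, arc = p$arc),
              class = "plane_definition")
  })
}

#' @param planes_subset labels of planes to process (default: `"A1.1"` to
#'   keep the demo chain light; pass `NULL` for all 12).
#' @param timeframes frames to process; `NULL` means all.
#' @rdname pipeline
#' @export
stage_features <- function(dir, config = default_config(),
                           planes_subset = "A1.1", timeframes = NULL) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  planes <- read_planes(dir)
  if (!is.null(planes_subset))
    planes <- Filter(function(p) p$label %in% planes_subset, planes)
  if (!length(planes)) stop("no planes to process; run the planes stage first")
  obs <- jsonlite::read_json(file.path(dir, "observer.json"),
                             simplifyVector = TRUE)
  observer2 <- observer_profile(obs$contour_jitter_mm, obs$dilation_bias_mm,
                                obs$seed)
  ref_scanner <- manifest$scanner[1]
  sp <- config$mpr_resolution_mm
  rows <- list()
  for (r in seq_len(nrow(manifest))) {
    field <- read_velocity_field(file.path(dir, manifest$path[r]))
    ph <- phantom_spec(tube_radius = manifest$radius[r],
                       profile_kind = manifest$profile[r],
                       peak_velocity = manifest$peak_velocity[r],
                       n_timeframes = manifest$n_timeframes[r])
    tfs <- if (is.null(timeframes)) seq_along(field$times) else
      timeframes[timeframes <= length(field$times)]
    for (plane in planes) {
      mask1 <- phantom_plane_roi(ph, plane, sp)
      obs_masks <- list(observer1 = mask1)
      if (manifest$scanner[r] == ref_scanner)
        obs_masks$observer2 <- perturb_roi(mask1, observer2, sp)
      for (ob in names(obs_masks)) {
        mask <- obs_masks[[ob]]
        for (t in tfs) {
          maps <- compute_parameter_maps(field, plane, t, mask = mask,
                                         spacing = sp)
          sig <- extract_signature(maps, mask, reference_mask = obs_masks[[ob]],
                                   bin_width = config$bin_width, spacing = sp)
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = manifest$subject_id[r],
            scanner = manifest$scanner[r], observer = ob,
            label = manifest$label[r], plane = plane$label,
            timeframe = t, cycle_fraction = (t - 1) / length(field$times),
            t(sig), check.names = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  features <- do.call(rbind, rows)
  utils::write.csv(features, file.path(dir, "features.csv"), row.names = FALSE)
  stage_log(dir, "features", config,
            list(n_rows = nrow(features), n_features = ncol(features) - 7L))
  invisible(features)
}

features_long <- function(features, id_cols) {
  fcols <- setdiff(names(features), c("subject_id", "scanner", "observer",
                                      "label", "plane", "timeframe",
                                      "cycle_fraction"))
  long <- do.call(rbind, lapply(fcols, function(f) {
    d <- features[id_cols]
    d$feature <- f
    d$value <- features[[f]]
    d
  }))
  long
}

#' @rdname pipeline
#' @export
stage_icc <- function(dir, config = default_config()) {
  features <- utils::read.csv(file.path(dir, "features.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  # inter-scanner arm: observer1 rows, scanners as raters (common frame grid:
  # curves upsampled to the finest temporal sampling per subject/plane)
  fs <- features[features$observer == "observer1", ]
  fs <- harmonize_timeframes(fs, rater_col = "scanner")
  long_s <- features_long(fs, c("subject_id", "scanner", "plane", "timeframe"))
  names(long_s)[names(long_s) == "subject_id"] <- "subject"
  names(long_s)[names(long_s) == "scanner"] <- "rater"
  icc_scanner <- reproducibility_table(long_s, model = config$icc_model)
  # inter-observer arm: reference scanner, observers as raters
  ref_scanner <- features$scanner[1]
  fo <- features[features$scanner == ref_scanner, ]
  long_o <- features_long(fo, c("subject_id", "observer", "plane", "timeframe"))
  names(long_o)[names(long_o) == "subject_id"] <- "subject"
  names(long_o)[names(long_o) == "observer"] <- "rater"
  icc_observer <- reproducibility_table(long_o, model = config$icc_model)
  utils::write.csv(icc_scanner, file.path(dir, "icc_interscanner.csv"),
                   row.names = FALSE)
  utils::write.csv(icc_observer, file.path(dir, "icc_interobserver.csv"),
                   row.names = FALSE)
  stage_log(dir, "icc", config, list(n_features = nrow(icc_scanner)))
  invisible(list(interscanner = icc_scanner, interobserver = icc_observer))
}

# linear upsampling of every feature curve to the finest frame grid across
# raters, per subject/plane/rater
harmonize_timeframes <- function(features, rater_col) {
  nmax <- max(tapply(features$timeframe,
                     features[c("subject_id", rater_col, "plane")],
                     function(x) length(unique(x))), na.rm = TRUE)
  fcols <- setdiff(names(features), c("subject_id", "scanner", "observer",
                                      "label", "plane", "timeframe",
                                      "cycle_fraction"))
  keys <- unique(features[c("subject_id", rater_col, "plane")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- features$subject_id == keys$subject_id[k] &
      features[[rater_col]] == keys[[rater_col]][k] &
      features$plane == keys$plane[k]
    d <- features[sel, ]
    d <- d[order(d$timeframe), ]
    if (nrow(d) == nmax) { out[[k]] <- transform(d, timeframe = seq_len(nmax)); next }
    up <- d[rep(1, nmax), ]
    up$timeframe <- seq_len(nmax)
    for (f in fcols)
      up[[f]] <- upsample_curve(d[[f]], nmax, times = d$timeframe)$values
    up$cycle_fraction <- seq(0, 1, length.out = nmax)
    out[[k]] <- up
  }
  do.call(rbind, out)
}

#' @rdname pipeline
#' @export
stage_select <- function(dir, config = default_config()) {
  icc_s <- utils::read.csv(file.path(dir, "icc_interscanner.csv"),
                           stringsAsFactors = FALSE)
  icc_o <- utils::read.csv(file.path(dir, "icc_interobserver.csv"),
                           stringsAsFactors = FALSE)
  lv <- c("poor", "moderate", "good", "excellent")
  icc_s$category <- factor(icc_s$category, lv, ordered = TRUE)
  icc_o$category <- factor(icc_o$category, lv, ordered = TRUE)
  sel <- select_features(icc_s, icc_o, config$min_category)
  utils::write.csv(data.frame(feature = sel$selected),
                   file.path(dir, "selected.csv"), row.names = FALSE)
  stage_log(dir, "select", config, list(n_selected = length(sel$selected)))
  invisible(sel)
}

#' @rdname pipeline
#' @export
stage_classify <- function(dir, config = default_config()) {
  features <- utils::read.csv(file.path(dir, "features.csv"),
                              check.names = FALSE, stringsAsFactors = FALSE)
  selected <- utils::read.csv(file.path(dir, "selected.csv"),
                              stringsAsFactors = FALSE)$feature
  if (!length(selected)) stop("empty feature selection; cannot classify")
  ref_scanner <- features$scanner[1]
  d <- features[features$scanner == ref_scanner &
                features$observer == "observer1" &
                features$plane == "A1.1", ]
  if (!nrow(d)) stop("no A1.1 features from the reference scanner")
  # peak systole per subject: frame with maximum throughflow mean is a
  # monotone surrogate of flow rate on a fixed ROI
  subj <- unique(d$subject_id)
  rows <- lapply(subj, function(s) {
    ds <- d[d$subject_id == s, ]
    pk <- detect_peak_systole(ds[["throughflow__firstorder__Mean"]])
    ds[pk, ]
  })
  peak <- do.call(rbind, rows)
  x <- as.matrix(peak[, selected, drop = FALSE])
  model <- train_classifier(x, peak$label, lambda = config$lambda,
                            n_folds = min(config$n_folds,
                                          min(table(peak$label))),
                            seed = config$seed)
  imp <- feature_importance(model)
  utils::write.csv(imp, file.path(dir, "importance.csv"), row.names = FALSE)
  rep <- model$report
  jsonlite::write_json(
    list(protocol = rep$protocol, accuracy = rep$accuracy, f1 = rep$f1,
         confusion = as.vector(rep$confusion), positive = rep$positive,
         resubstitution = list(accuracy = rep$resubstitution$accuracy,
                               f1 = rep$resubstitution$f1),
         seed = config$seed),
    file.path(dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
  sig <- export_signatures(x, selected,
                           data.frame(subject_id = peak$subject_id,
                                      label = peak$label))
  utils::write.csv(sig$table, file.path(dir, "signatures.csv"),
                   row.names = FALSE)
  stage_log(dir, "classify", config,
            list(accuracy = rep$accuracy, f1 = rep$f1))
  invisible(model)
}

#' @rdname pipeline
#' @export
stage_report <- function(dir, config = default_config()) {
  out <- list()
  for (arm in c("interscanner", "interobserver")) {
    path <- file.path(dir, sprintf("icc_%s.csv", arm))
    if (!file.exists(path)) stop("missing ICC table: ", path,
                                 "; run the icc stage first")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    tab$map <- sub("__.*", "", tab$feature)
    cats <- c("poor", "moderate", "good", "excellent")
    counts <- table(factor(tab$category, cats), tab$map)
    df <- as.data.frame.matrix(counts)
    df <- cbind(category = rownames(df), df)
    utils::write.csv(df, file.path(dir, sprintf("report_%s_counts.csv", arm)),
                     row.names = FALSE)
    out[[arm]] <- df
  }
  cls_path <- file.path(dir, "classifier.json")
  if (file.exists(cls_path))
    out$classifier <- jsonlite::read_json(cls_path, simplifyVector = TRUE)
  stage_log(dir, "report", config, list())
  invisible(out)
}

#' Run the full pipeline chain
#'
#' @param dir run directory.
#' @param config a `run_config`.
#' @param n_subjects,n_timeframes,planes_subset,timeframes forwarded to the
#'   stages.
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(dir, config = default_config(), n_subjects = 8L,
                         n_timeframes = 20L, planes_subset = "A1.1",
                         timeframes = NULL) {
  stage_simulate(dir, config, n_subjects = n_subjects,
                 n_timeframes = n_timeframes)
  stage_planes(dir, config)
  stage_features(dir, config, planes_subset = planes_subset,
                 timeframes = timeframes)
  stage_icc(dir, config)
  stage_select(dir, config)
  stage_classify(dir, config)
  stage_report(dir, config)
}
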