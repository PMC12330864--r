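#' @title End-to-end orchestration
#' @description
#' Runs the full per-subject analysis (preprocess, fluidity, microstates,
#' spectra, kinematics) with stage-level caching and a manifest, and the
#' group-level comparisons (bootstrap KS between fluidity distributions,
#' correlation of mean dynamics fluidity with mean microstate metrics).
#' @name pipeline-module
NULL

# content hash of arbitrary R objects via serialization + md5
content_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(...), tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

# run `fun()` with caching under results_dir keyed on stage name + hash
cached_stage <- function(results_dir, stage, hash, fun) {
  if (is.null(results_dir)) return(fun())
  f <- file.path(results_dir, sprintf("%s-%s.rds", stage, substr(hash, 1, 12)))
  if (file.exists(f)) return(readRDS(f))
  out <- fun()
  saveRDS(out, f)
  out
}

#' Run the full analysis for one subject
#'
#' Stages: (1) preprocessing — optional channel rejection, optional lowpass
#' (applied when the input rate exceeds 200 Hz), coarse-graining to the
#' analysis rate; (2) dynamics fluidity; (3) microstate sweep over a
#' cluster range with fluidity and MDL complexity per K; (4) relative band
#' power on the raw series; (5) kinematics, when a pose track is supplied.
#' Stage outputs are cached in `results_dir` keyed on a content hash of the
#' stage inputs and parameters, and a manifest (JSON) records every
#' parameter, seed and output file.
#'
#' @param eeg an [mc_series()], a `synthetic_eeg`, or a path readable by
#'   [read_series_matrix()].
#' @param pose optional [pose_track()] or DLC CSV path.
#' @param params list of analysis parameters; missing entries take the
#'   defaults of [default_params()].
#' @param results_dir directory for cached stage outputs and the manifest,
#'   or `NULL` to skip writing.
#' @param subject_id label used in the manifest.
#' @return list of class `subject_result` with `fluidity`,
#'   `microstates` (sweep), `band_power`, `kinematics` (or `NULL`),
#'   `rejection`, `params`, `manifest`.
#' @export
run_subject <- function(eeg, pose = NULL, params = list(),
                        results_dir = NULL, subject_id = "subject") {
  params <- utils::modifyList(default_params(), params)
  if (is.character(eeg)) eeg <- read_series_matrix(eeg)
  if (inherits(eeg, "synthetic_eeg")) eeg <- eeg$series
  stopifnot_series(eeg)
  if (!is.null(results_dir) &&
      !dir.exists(results_dir))
    dir.create(results_dir, recursive = TRUE)

  outputs <- character(0)
  # --- preprocess ---
  rejection <- NULL
  pre <- eeg
  if (!is.null(params$reject_list) || isTRUE(params$auto_reject)) {
    rr <- reject_channels(pre, reject_list = params$reject_list)
    rejection <- rr$report
    pre <- rr$series
  }
  raw <- pre                         # spectral analysis uses this
  if (pre$rate > params$analysis_rate) {
    if (pre$rate / 2 > params$lowpass_hz)
      pre <- lowpass_filter(pre, params$lowpass_hz)
    pre <- coarse_grain(pre, window_ms = 1000 / params$analysis_rate)
  }

  h <- content_hash(pre$values, params[c("quantile", "ref_stride")])
  fl <- cached_stage(results_dir, "fluidity", h, function()
    fluidity(pre, q = params$quantile, ref_stride = params$ref_stride))
  outputs <- c(outputs, "fluidity")

  h <- content_hash(pre$values, params[c("k_min", "k_max", "seed")])
  ms <- cached_stage(results_dir, "microstates", h, function()
    sweep_k(pre, params$k_min, params$k_max, seed = params$seed))
  outputs <- c(outputs, "microstates")

  h <- content_hash(raw$values, params[c("spec_window_s", "spec_overlap_s")])
  bp <- cached_stage(results_dir, "band_power", h, function() {
    sp <- multitaper_spectrogram(raw, params$spec_window_s,
                                 params$spec_overlap_s,
                                 params$time_bandwidth, params$n_tapers)
    # drop bands that start beyond this recording's spectral range
    bands <- Filter(function(b) b[1L] <= max(sp$freq), default_bands())
    relative_band_power(sp, bands = bands,
                        region_map = default_region_map(raw$channel_names))
  })
  outputs <- c(outputs, "band_power")

  kin <- NULL
  if (!is.null(pose)) {
    if (is.character(pose)) pose <- read_dlc_csv(pose)
    nt <- normalize_arena(pose)
    kin <- list(speed = compute_speed(nt),
                head_movement = compute_head_movement(nt))
    outputs <- c(outputs, "kinematics")
  }
  outputs <- c(outputs, "preprocess")

  manifest <- list(subject_id = subject_id,
                   package_version = as.character(utils::packageVersion("eegfluidity")),
                   params = params[!vapply(params, is.null, logical(1L))],
                   n_channels = nrow(pre$values),
                   n_samples_coarse = ncol(pre$values),
                   stages = sort(outputs),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(results_dir)) {
    jsonlite::write_json(manifest,
                         file.path(results_dir,
                                   paste0(subject_id, "-manifest.json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(as.data.frame(fl),
                       file.path(results_dir, paste0(subject_id, "-fluidity.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  structure(list(fluidity = fl, microstates = ms, band_power = bp,
                 kinematics = kin, rejection = rejection,
                 params = params, manifest = manifest),
            class = "subject_result")
}

#' Default pipeline parameters
#'
#' Analysis rate 25 Hz (40 ms coarse-graining), lowpass 100 Hz, fluidity
#' quantile 0.98, cluster range 3..8, 10 s / 5 s multitaper windows with
#' NW = 3 and 5 tapers.
#'
#' @return named list of defaults; override any entry through the `params`
#'   argument of [run_subject()].
#' @export
default_params <- function() {
  list(analysis_rate = 25, lowpass_hz = 100,
       quantile = 0.98, ref_stride = 1L,
       k_min = 3L, k_max = 8L, seed = 1L,
       spec_window_s = 10, spec_overlap_s = 5,
       time_bandwidth = 3, n_tapers = 5,
       reject_list = NULL, auto_reject = FALSE)
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s\n", x$manifest$subject_id))
  cat(sprintf("  mean theta %.4f | mean ms fluidity %.4f | mean DL %.2f\n",
              mean(x$fluidity), x$microstates$mean_fluidity,
              x$microstates$mean_complexity))
  invisible(x)
}

#' Group comparison of fluidity distributions and microstate metrics
#'
#' Runs [run_subject()] for every subject of a cohort (skipping subjects
#' whose analysis fails, with the error recorded), then: (1) compares the
#' group fluidity distributions with [bootstrap_ks_compare()], either
#' pooling theta values across subjects within each group (`mode =
#' "pooled"`, default) or using per-subject mean thetas (`mode =
#' "per-subject"`); (2) correlates subject-mean dynamics fluidity with
#' subject-mean microstate fluidity and complexity (Pearson).
#'
#' @param cohort a `synthetic_cohort` from [gen_cohort()], or a list with
#'   `subjects` (list of series) and `group` (per-subject labels, exactly
#'   two distinct values).
#' @param params passed to [run_subject()].
#' @param mode `"pooled"` or `"per-subject"` fluidity comparison.
#' @param m_comparisons Bonferroni factor for the KS comparison.
#' @param seed seed for the resampling.
#' @param results_dir optional cache/manifest directory.
#' @return list of class `group_comparison`: `ks` (a `bootstrap_ks`),
#'   `correlations` (data frame: metric, r, p, n), `subject_table`,
#'   `failed` (per-subject error messages), `mode`.
#' @export
run_group_comparison <- function(cohort, params = list(),
                                 mode = c("pooled", "per-subject"),
                                 m_comparisons = 1L, seed = 1L,
                                 results_dir = NULL) {
  mode <- match.arg(mode)
  subjects <- cohort$subjects
  group <- as.character(cohort$group)
  if (!length(subjects)) stop("empty subject list")
  if (length(unique(group)) != 2L)
    stop("need exactly two groups")
  res <- vector("list", length(subjects))
  failed <- character(0)
  for (i in seq_along(subjects)) {
    res[[i]] <- tryCatch(
      run_subject(subjects[[i]], params = params, results_dir = results_dir,
                  subject_id = sprintf("s%02d", i)),
      error = function(e) {
        failed <<- c(failed, sprintf("s%02d: %s", i, conditionMessage(e)))
        NULL
      })
  }
  ok <- !vapply(res, is.null, logical(1L))
  res <- res[ok]; group <- group[ok]
  glev <- unique(group)
  if (length(glev) < 2L || length(res) < 3L)
    stop("too few analyzable subjects to compare groups")
  theta_of <- function(r) r$fluidity$theta[!is.nan(r$fluidity$theta)]
  if (mode == "pooled") {
    da <- unlist(lapply(res[group == glev[1L]], theta_of))
    db <- unlist(lapply(res[group == glev[2L]], theta_of))
  } else {
    da <- vapply(res[group == glev[1L]], function(r) mean(r$fluidity),
                 numeric(1L))
    db <- vapply(res[group == glev[2L]], function(r) mean(r$fluidity),
                 numeric(1L))
  }
  ks <- bootstrap_ks_compare(da, db, m_comparisons = m_comparisons,
                             seed = seed)
  tab <- data.frame(
    subject = vapply(res, function(r) r$manifest$subject_id, character(1L)),
    group = group,
    mean_theta = vapply(res, function(r) mean(r$fluidity), numeric(1L)),
    ms_fluidity = vapply(res, function(r) r$microstates$mean_fluidity,
                         numeric(1L)),
    dl_complexity = vapply(res, function(r) r$microstates$mean_complexity,
                           numeric(1L)))
  cors <- do.call(rbind, lapply(c("ms_fluidity", "dl_complexity"),
    function(metric) {
      ct <- stats::cor.test(tab$mean_theta, tab[[metric]])
      data.frame(metric = metric, r = unname(ct$estimate),
                 p = ct$p.value, n = nrow(tab))
    }))
  structure(list(ks = ks, correlations = cors, subject_table = tab,
                 failed = failed, mode = mode, groups = glev),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (%s mode)\n",
              x$groups[1L], x$groups[2L], x$mode))
  print(x$ks)
  print(x$correlations, row.names = FALSE)
  if (length(x$failed)) cat("  failed:", paste(x$failed, collapse = "; "), "\n")
  invisible(x)
}
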