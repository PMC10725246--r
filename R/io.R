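#' Read a respiratory belt recording from text
#'
#' Accepts two-column whitespace/TSV text (time in seconds, amplitude), in
#' which case the sampling rate is inferred from the time stamps, or a
#' single-column amplitude file with an explicit `sampling_rate`.
#'
#' @param path File path.
#' @param sampling_rate Required for single-column files; overrides the
#'   inferred rate when given for two-column files.
#' @return A [resp_trace()].
#' @export
read_physio <- function(path, sampling_rate = NULL) {
  first <- strsplit(trimws(readLines(path, n = 1)), "[\t ]+")[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  tab <- read.table(path, header = has_header)
  if (ncol(tab) >= 2L) {
    time <- tab[[1]]
    amp <- tab[[2]]
    dt <- diff(time)
    if (any(dt <= 0)) stop("time stamps must be strictly increasing")
    rate <- if (is.null(sampling_rate)) 1 / median(dt) else sampling_rate
    resp_trace(amp, rate, t0 = time[1])
  } else {
    if (is.null(sampling_rate)) {
      stop("single-column physio input needs an explicit sampling_rate")
    }
    resp_trace(tab[[1]], sampling_rate)
  }
}

#' Write/read BIDS-style events tables
#'
#' Events tables carry columns `onset`, `duration`, `trial_type` (one of
#' `i_air`, `i_odorant`, `unassigned`).
#'
#' @param events An `inhalation_events` data frame.
#' @param path Output TSV path.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   `inhalation_events` data frame.
#' @export
write_events <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = as.character(events$condition))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  ev <- data.frame(
    onset = as.numeric(tab$onset),
    duration = as.numeric(tab$duration),
    peak_time = as.numeric(tab$onset) + as.numeric(tab$duration),
    condition = factor(tab$trial_type,
                       levels = c("i_air", "i_odorant", "unassigned")))
  class(ev) <- c("inhalation_events", "data.frame")
  ev
}

#' Write/read a design matrix as TSV
#'
#' The first column is `time_s`, followed by the named predictors.
#'
#' @param X A [design_matrix()].
#' @param path TSV path.
#' @param label Strategy label to attach on read.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   [design_matrix()].
#' @export
write_design <- function(X, path) {
  out <- data.frame(time_s = X$times, X$values, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, label = NA_character_) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  design_matrix(tab$time_s, as.matrix(tab[, -1, drop = FALSE]), label)
}

#' Read a BOLD run from NIfTI or TSV
#'
#' 4D NIfTI images are flattened to a voxels x volumes matrix (column-major
#' voxel order) and carry their grid and affine as geometry; TSV input is a
#' plain voxels x volumes matrix without geometry.
#'
#' @param path `.nii`, `.nii.gz` or `.tsv` file.
#' @param tr Repetition time (s); for NIfTI input, defaults to the pixdim
#'   time step when present.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4L) stop("expected a 4D NIfTI image")
    if (is.null(tr)) {
      tr <- RNifti::pixdim(img)[4]
      if (!is.finite(tr) || tr <= 0) stop("cannot infer TR; pass tr explicitly")
    }
    mat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
    bold_run(mat, tr = tr,
             geometry = list(dim = d[1:3], affine = RNifti::xform(img)))
  } else {
    if (is.null(tr)) stop("TSV input needs an explicit tr")
    bold_run(as.matrix(read.table(path, header = FALSE, sep = "\t")), tr = tr)
  }
}

#' Write a statistic map
#'
#' With geometry the map is written as 3D NIfTI; otherwise as a single-column
#' TSV of voxel values.
#'
#' @param map A [stat_map()] (or numeric vector).
#' @param path Output path (`.nii`, `.nii.gz` or `.tsv`).
#' @param geometry Optional geometry list (`dim`, `affine`) as produced by
#'   [read_bold()].
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, geometry = NULL) {
  values <- if (inherits(map, "stat_map")) map$values else as.numeric(map)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (is.null(geometry)) stop("NIfTI output needs geometry")
    arr <- array(values, dim = geometry$dim)
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, path)
  } else {
    write.table(data.frame(value = values), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the four-strategy comparison. Unknown
#' keys are rejected so that a config file round-trips losslessly.
#'
#' @param schedule A [block_schedule()].
#' @param hrf An [hrf_model()].
#' @param normalization A [norm_params()].
#' @param peaks A [peak_params()].
#' @param strategies Strategy labels to run.
#' @param q FDR level.
#' @param g_threshold Winner-map threshold.
#' @param tr Repetition time (s).
#' @param n_volumes Volumes per run.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(schedule = block_schedule(), hrf = hrf_model(),
                            normalization = norm_params(),
                            peaks = peak_params(),
                            strategies = c("SBD1", "SBD2", "MBD1", "MBD2"),
                            q = 0.05, g_threshold = 0.4, tr = 2,
                            n_volumes = 104) {
  stopifnot(q > 0, q < 1, g_threshold >= 0,
            all(strategies %in% c("SBD1", "SBD2", "MBD1", "MBD2")))
  structure(list(schedule = schedule, hrf = hrf,
                 normalization = normalization, peaks = peaks,
                 strategies = strategies, q = q, g_threshold = g_threshold,
                 tr = tr, n_volumes = as.integer(n_volumes)),
            class = "analysis_config")
}

#' Write/read an analysis configuration as YAML
#'
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` an
#'   [analysis_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  plain <- list(
    schedule = unclass(config$schedule),
    hrf = unclass(config$hrf),
    normalization = unclass(config$normalization),
    peaks = unclass(config$peaks),
    strategies = config$strategies,
    q = config$q, g_threshold = config$g_threshold,
    tr = config$tr, n_volumes = config$n_volumes)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("schedule", "hrf", "normalization", "peaks", "strategies",
             "q", "g_threshold", "tr", "n_volumes")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  analysis_config(
    schedule = do.call(block_schedule, raw$schedule),
    hrf = do.call(hrf_model, raw$hrf),
    normalization = do.call(norm_params, raw$normalization),
    peaks = do.call(peak_params, raw$peaks),
    strategies = raw$strategies %||% c("SBD1", "SBD2", "MBD1", "MBD2"),
    q = raw$q %||% 0.05, g_threshold = raw$g_threshold %||% 0.4,
    tr = raw$tr %||% 2, n_volumes = raw$n_volumes %||% 104)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic study to a BIDS-like tree
#'
#' Writes `sub-XX/sub-XX_run-YY_physio.tsv`, `_events.tsv` (the
#' pipeline-extracted, labelled events) and `_bold.tsv` (when the study
#' carries BOLD data), plus a `manifest.json` holding every parameter and
#' seed needed to regenerate the study.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param schedule A [block_schedule()] used to label the events.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, schedule = block_schedule()) {
  stopifnot(inherits(study, "sniff_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(study$subjects)) {
    sub <- sprintf("sub-%02d", s)
    subdir <- file.path(dir, sub)
    dir.create(subdir, showWarnings = FALSE)
    for (r in seq_along(study$subjects[[s]]$runs)) {
      run <- study$subjects[[s]]$runs[[r]]
      stem <- file.path(subdir, sprintf("%s_run-%02d", sub, r))
      tr_ <- run$trace
      write.table(
        data.frame(time_s = trace_times(tr_), amplitude = tr_$samples),
        paste0(stem, "_physio.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      ev <- respiratory_events(tr_, schedule)
      write_events(ev, paste0(stem, "_events.tsv"))
      if (!is.null(run$bold)) {
        write.table(run$bold$run$data, paste0(stem, "_bold.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
      }
    }
  }
  manifest <- study$manifest
  manifest$run_seeds <- as.vector(manifest$run_seeds)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
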