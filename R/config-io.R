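## Configuration handling and plain-text I/O.

#' Default run configuration
#'
#' All tunables of the pipeline with their default values. The defaults
#' describe the macaque preparation: 30 Hz checkerboard with 67 um checks,
#' foveal ganglion-cell density 51108 cells/mm^2 with a 40 percent
#' transfection ratio, 82 um receptive-field diameter, letters repositioned
#' every 67 ms, a 60 ms presentation window in the decoder, and 500 trials
#' per letter size. For the mouse recordings use 40 Hz, 50 um checks and a
#' 99 um receptive field.
#'
#' @return named list of configuration values.
#' @export
defaultConfig <- function() {
  list(
    frame_rate_hz = 30,
    check_size_um = 67,
    sta_window_ms = 200,
    reliability_threshold = 0.5,
    density_mm2 = 51108,
    transfection_ratio = 0.4,
    rf_diameter_um = 82,
    softplus_beta = 10,
    softplus_theta = -0.5,
    jitter_period_s = 0.067,
    delta_t_s = 0.06,
    jitter_window_um = 100,
    pixel_size_um = 10,
    n_trials = 500L,
    duration_s = 1.0,
    letter_sizes_um = defaultLetterSizes(),
    decoder_variant = "eq1",
    seed = 1L
  )
}

#' Validate a configuration list
#'
#' Fills missing fields with defaults, rejects unknown keys and
#' out-of-range values.
#'
#' @param config named list (possibly partial).
#' @return completed, validated configuration list.
#' @export
validateConfig <- function(config) {
  def <- defaultConfig()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(def, config)
  chkPos <- function(field) {
    if (any(!is.finite(cfg[[field]])) || any(cfg[[field]] <= 0))
      stop("configuration field '", field, "' must be positive",
           call. = FALSE)
  }
  for (f in c("frame_rate_hz", "check_size_um", "sta_window_ms",
              "density_mm2", "rf_diameter_um", "jitter_period_s",
              "delta_t_s", "jitter_window_um", "pixel_size_um", "n_trials",
              "duration_s", "letter_sizes_um", "softplus_beta"))
    chkPos(f)
  if (cfg$transfection_ratio <= 0 || cfg$transfection_ratio > 1)
    stop("transfection_ratio must be in (0, 1]", call. = FALSE)
  if (abs(cfg$reliability_threshold) > 1)
    stop("reliability_threshold must lie in [-1, 1]", call. = FALSE)
  if (!cfg$decoder_variant %in% c("eq1", "marginal"))
    stop("decoder_variant must be 'eq1' or 'marginal'", call. = FALSE)
  cfg$n_trials <- as.integer(cfg$n_trials)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Load a run configuration from YAML
#'
#' Missing fields take their defaults (an empty file yields the full
#' default configuration); unknown keys and out-of-range values are
#' rejected with a descriptive error.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
loadConfig <- function(path) {
  stopIfNot(file.exists(path), paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  validateConfig(cfg)
}

#' Save a configuration to YAML
#' @param config configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(validateConfig(config), path)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' Expects columns `cell_id` and `spike_time_s`. Times are sorted per cell
#' (unsorted input is tolerated); duplicate timestamps are preserved;
#' non-numeric times are reported with their row number.
#'
#' @param path CSV file path.
#' @param durationS recording duration; defaults to just past the last
#'   spike.
#' @return A [SpikeTrains-class] object (no cells for an empty file).
#' @export
readSpikesCSV <- function(path, durationS = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "spike_time_s")
  stopIfNot(all(need %in% names(df)),
            "spike CSV must have columns cell_id, spike_time_s")
  if (nrow(df) == 0L)
    return(spikeTrains(structure(list(), names = character(0)),
                       durationS = if (is.null(durationS)) 1 else durationS))
  t <- suppressWarnings(as.numeric(df$spike_time_s))
  if (any(is.na(t)))
    stop("malformed spike_time_s at data row(s): ",
         paste(utils::head(which(is.na(t)), 5), collapse = ", "),
         call. = FALSE)
  if (any(t < 0))
    warning("negative spike times present; kept as given")
  sp <- split(t, df$cell_id)
  if (is.null(durationS)) durationS <- max(t) + 1e-9
  spikeTrains(sp, durationS)
}

#' Write spike trains to CSV
#' @param spikes a [SpikeTrains-class] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpikesCSV <- function(spikes, path) {
  ids <- names(spikes@spikes)
  if (is.null(ids)) ids <- as.character(seq_along(spikes@spikes))
  df <- data.frame(
    cell_id = rep(ids, vapply(spikes@spikes, length, integer(1))),
    spike_time_s = unlist(spikes@spikes, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-cell receptive-field table
#'
#' Collects fitted receptive fields and quality-control measures into the
#' flat table written alongside results.
#'
#' @param fits named list of [GaussianRFFit-class] objects.
#' @param reliability named numeric vector of split-half reliabilities,
#'   aligned with `fits`.
#' @param threshold selection threshold on the reliability (default 0.5).
#' @return data.frame with one row per cell.
#' @export
rfTable <- function(fits, reliability, threshold = 0.5) {
  ids <- names(fits)
  if (is.null(ids)) ids <- as.character(seq_along(fits))
  df <- data.frame(
    cell_id = ids,
    center_x_um = vapply(fits, function(f) f@centerUm[1], numeric(1)),
    center_y_um = vapply(fits, function(f) f@centerUm[2], numeric(1)),
    sigma_x_um = vapply(fits, function(f) f@sigmaXUm, numeric(1)),
    sigma_y_um = vapply(fits, function(f) f@sigmaYUm, numeric(1)),
    diameter_um = vapply(fits, function(f) f@diameterUm, numeric(1)),
    diameter_se_um = vapply(fits, function(f) f@diameterSeUm, numeric(1)),
    rf_visible = vapply(fits, function(f) f@rfVisible, logical(1)),
    reliability_r = as.numeric(reliability[ids]),
    row.names = NULL)
  df$selected <- df$rf_visible & !is.na(df$reliability_r) &
    df$reliability_r > threshold
  df
}

#' Write acuity results to disk
#'
#' Writes `acuity_result.json` (acuity, Snellen string, trial counts, the
#' full configuration echo, seed and package version) and
#' `success_matrix.csv` (one row per letter size, one column per decoding
#' time) into `dir`.
#'
#' @param result an [AcuityResult-class] object.
#' @param dir output directory (created if needed).
#' @param config the configuration the run used (echoed verbatim).
#' @return named character vector of the files written, invisibly.
#' @export
writeResults <- function(result, dir, config = defaultConfig()) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  jsonPath <- file.path(dir, "acuity_result.json")
  csvPath <- file.path(dir, "success_matrix.csv")
  payload <- list(
    acuity_um = result@acuityUm,
    snellen = result@snellen,
    n_trials = result@nTrials,
    sizes_um = result@sizesUm,
    times_s = result@timesS,
    sd_over_repeats_um = result@sdOverRepeats,
    seed = result@seed,
    config = config,
    package_version = as.character(utils::packageVersion("retinacuity")))
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  m <- data.frame(size_um = result@sizesUm, result@success,
                  check.names = FALSE)
  utils::write.csv(m, csvPath, row.names = FALSE)
  invisible(c(json = jsonPath, csv = csvPath))
}
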