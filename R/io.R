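# Delimited schemas and JSON serialization binding the pipeline stages
# together. Sensor files are comma-separated with a leading metadata block
# of "# key: value" lines (individual_id, fs_hz, covariate_level,
# hemisphere); numeric round-trips are good to 1e-9 and missing samples are
# empty fields mapped to the validity mask on read.

fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write / read a sensor file
#'
#' @param sensors sensor tibble (`t_s`, `acc_x/y/z`, optional `mag_x/y/z`).
#' @param path file path.
#' @param individual_id,fs_hz,covariate_level,hemisphere metadata recorded
#'   in the header block.
#' @return `write_sensor_csv` returns the path invisibly;
#'   `read_sensor_csv` returns the sensor tibble (with a `valid` column
#'   where samples are incomplete) carrying the metadata as attribute
#'   `meta`.
#' @export
write_sensor_csv <- function(sensors, path, individual_id = "ind1",
                             fs_hz = NULL, covariate_level = NA,
                             hemisphere = "N") {
  if (is.null(fs_hz)) fs_hz <- infer_fs(sensors$t_s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# individual_id: %s", individual_id), con)
  writeLines(sprintf("# fs_hz: %.10g", fs_hz), con)
  writeLines(sprintf("# covariate_level: %s", covariate_level), con)
  writeLines(sprintf("# hemisphere: %s", hemisphere), con)
  cols <- intersect(c("t_s", "acc_x", "acc_y", "acc_z",
                      "mag_x", "mag_y", "mag_z"), names(sensors))
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(sensors[cols], fmt_num), list(sep = ",")))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  lines <- readLines(path, n = 20L)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  if (!is.null(meta$fs_hz)) meta$fs_hz <- as.numeric(meta$fs_hz)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = "numeric", check.names = FALSE)
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) {
    stop("malformed sensor file ", path, ": t_s not strictly increasing at ",
         "data line ", bad[1] + 1L, call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  sensor_cols <- setdiff(names(out), "t_s")
  out$valid <- stats::complete.cases(out[sensor_cols])
  attr(out, "meta") <- meta
  out
}

#' Write a simulated deployment to disk
#'
#' One sensor CSV per individual plus `truth.csv`
#' (`individual_id,window_index,true_state`).
#'
#' @param deployment a [simulate_deployment()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_deployment <- function(deployment, dir) {
  stopifnot(inherits(deployment, "soarhmm_deployment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(deployment$sensors)) {
    id <- names(deployment$sensors)[i]
    write_sensor_csv(
      deployment$sensors[[i]],
      file.path(dir, paste0(id, ".csv")),
      individual_id = id,
      fs_hz = deployment$config$fs_hz,
      covariate_level = deployment$meta$covariate_level[i],
      hemisphere = if (deployment$config$mag_field[3] < 0) "N" else "S"
    )
  }
  utils::write.csv(deployment$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write / read a feature table
#'
#' Plain CSV with the documented column schema; an optional config hash is
#' recorded as a leading comment and surfaced as attribute `config_hash`.
#'
#' @param features feature tibble.
#' @param path file path.
#' @param config_hash optional provenance string.
#' @export
write_feature_csv <- function(features, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) {
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  }
  utils::write.csv(features, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- if (grepl("^# config_hash:", first)) {
    trimws(sub("^# config_hash:", "", first))
  }
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  if ("missing" %in% names(out)) out$missing <- as.logical(out$missing)
  attr(out, "config_hash") <- hash
  out
}

#' Write / read decoded states
#'
#' CSV schema `individual_id,window_index,state_index,behavior_label`.
#' @param states decode tibble from [viterbi_decode()].
#' @param path file path.
#' @export
write_states_csv <- function(states, path) {
  out <- data.frame(
    individual_id = states$individual_id,
    window_index = states$window_index,
    state_index = states$state_index,
    behavior_label = states$state
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_states_csv
#' @export
read_states_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  names(out)[names(out) == "behavior_label"] <- "state"
  out
}

#' Serialize a magnetometer calibration as flat JSON
#'
#' @param calibration a [fit_mag_calibration()] result.
#' @param path file path.
#' @export
write_calibration_json <- function(calibration, path) {
  stopifnot(inherits(calibration, "soarhmm_calibration"))
  jsonlite::write_json(
    list(hard_iron = calibration$hard_iron,
         correction = as.numeric(t(calibration$correction)),
         reference_norm = calibration$reference_norm,
         norm_cv = calibration$norm_cv),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(hard_iron = j$hard_iron,
         correction = matrix(j$correction, 3, 3, byrow = TRUE),
         reference_norm = j$reference_norm, norm_cv = j$norm_cv),
    class = "soarhmm_calibration"
  )
}

#' Serialize a fitted HMM as JSON
#'
#' All scalars on the natural scale; the logit link and reference covariate
#' level are recorded so the object round-trips exactly.
#'
#' @param fit a [fit_hmm()] result.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "soarhmm_fit"))
  p <- fit$params
  jsonlite::write_json(
    list(
      n_states = p$n_states, features = p$features,
      state_names = p$state_names,
      shape = as.data.frame(p$shape), scale = as.data.frame(p$scale),
      transition_link = "multinomial-logit, diagonal reference",
      cov_levels = p$cov_levels, reference_level = p$cov_levels[1],
      beta = as.data.frame(p$beta), delta = p$delta,
      loglik = fit$loglik, aic = fit$aic, n_par = fit$n_par,
      n_obs = fit$n_obs, n_stable = fit$n_stable,
      restart_logliks = fit$restarts$loglik,
      feature_set = fit$feature_set, seed = fit$seed,
      data_hash = fit$data_hash
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- hmm_params(
    shape = as.matrix(j$shape), scale = as.matrix(j$scale),
    beta = as.matrix(j$beta), delta = j$delta,
    cov_levels = j$cov_levels, state_names = j$state_names,
    features = j$features
  )
  structure(
    list(params = params, loglik = j$loglik, aic = j$aic, n_par = j$n_par,
         n_obs = j$n_obs,
         restarts = tibble::tibble(restart = seq_along(j$restart_logliks),
                                   loglik = j$restart_logliks,
                                   converged = NA),
         n_stable = j$n_stable, feature_set = j$feature_set,
         covariate = if (length(j$cov_levels) > 1) "covariate",
         cov_levels = j$cov_levels, seed = j$seed, data_hash = j$data_hash),
    class = "soarhmm_fit"
  )
}

#' Pipeline run configuration
#'
#' Defaults for every stage parameter; unknown keys in a config file are
#' rejected.
#'
#' @return Named list of stage parameters.
#' @export
default_run_config <- function() {
  list(
    target_fs_hz = 25, window_s = 30,
    trim_start_s = 7200, trim_end_s = 0, median_window = 5,
    smooth_s = 2, peak_fraction = 0.05,
    feature_set = c("hf", "p5", "sh"),
    n_states = 3, n_restarts = 25, covariate = TRUE,
    feature_floor = 1e-6, max_missing_run = 10,
    correlation_threshold = 0.7, seed = 1
  )
}

#' @param path YAML file with a subset of the keys of
#'   [default_run_config()].
#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Short stable fingerprint of a configuration
#'
#' @param config any serializable list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
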