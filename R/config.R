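#' Load a JSON run configuration
#'
#' A run configuration is a JSON object with optional sections
#' `preprocess`, `beats`, `anatomy`, `hemodynamics`, `synth`, `io` and
#' `verbosity`. Each section overrides the corresponding settings
#' constructor's defaults; unknown sections or unknown keys within a section
#' are rejected. `anatomy` may carry a `segments` object (segment name to
#' `[a, b, c]`) overriding the default length model; `hemodynamics` accepts
#' `window_s` and `start_offset_s`.
#'
#' @param path Path to a JSON file, or `NULL` for all defaults.
#' @param overrides Optional named list merged over the file contents
#'   (used by command-line flag overrides).
#' @return Object of class `run_config`: list with constructed settings
#'   objects `preprocess`, `beats`, `model`, `hemodynamics`, `synth`, plus
#'   `io` and `verbosity`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  for (nm in names(overrides)) {
    raw[[nm]] <- utils::modifyList(
      if (is.null(raw[[nm]])) list() else as.list(raw[[nm]]),
      as.list(overrides[[nm]]))
  }
  known <- c("preprocess", "beats", "anatomy", "hemodynamics", "synth",
             "io", "verbosity")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  build <- function(section, ctor) {
    args <- if (is.null(raw[[section]])) list() else as.list(raw[[section]])
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad) > 0L) {
      stop("unknown key(s) in section '", section, "': ",
           paste(bad, collapse = ", "))
    }
    do.call(ctor, args)
  }
  model <- default_length_model()
  anat <- if (is.null(raw$anatomy)) list() else as.list(raw$anatomy)
  bad <- setdiff(names(anat), "segments")
  if (length(bad) > 0L) {
    stop("unknown key(s) in section 'anatomy': ", paste(bad, collapse = ", "))
  }
  if (!is.null(anat$segments)) {
    model <- length_model_from_json(
      as.character(jsonlite::toJSON(anat$segments, digits = NA)))
  }
  hemo <- if (is.null(raw$hemodynamics)) list() else as.list(raw$hemodynamics)
  bad <- setdiff(names(hemo), c("window_s", "start_offset_s"))
  if (length(bad) > 0L) {
    stop("unknown key(s) in section 'hemodynamics': ", paste(bad, collapse = ", "))
  }
  structure(list(
    preprocess = build("preprocess", filter_settings),
    beats = build("beats", detector_settings),
    model = model,
    hemodynamics = list(
      window_s = if (is.null(hemo$window_s)) 30 else hemo$window_s,
      start_offset_s = if (is.null(hemo$start_offset_s)) 0 else hemo$start_offset_s
    ),
    synth = build("synth", synth_settings),
    io = if (is.null(raw$io)) list() else as.list(raw$io),
    verbosity = if (is.null(raw$verbosity)) 1L else as.integer(raw$verbosity)
  ), class = "run_config")
}

#' Run the full per-side pipeline under a run configuration
#'
#' Convenience wrapper: applies the configuration's preprocessing, detection
#' and anatomy settings to a session.
#'
#' @param session A `recording_session`.
#' @param config A `run_config` (default: all defaults).
#' @return A `side_result`.
#' @export
process_with_config <- function(session, config = load_run_config()) {
  stopifnot(inherits(config, "run_config"))
  process_session(session,
                  filter = config$preprocess,
                  detector = config$beats,
                  model = config$model,
                  window_s = config$hemodynamics$window_s,
                  start_offset_s = config$hemodynamics$start_offset_s)
}
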