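#' Load a slice recording from disk
#'
#' The canonical interchange format is a plain CSV with a `time_s` column plus
#' one column per channel (headed by its role, e.g. `CA3_LFP`), and an optional
#' JSON sidecar `<file>.json` carrying the sampling rate, units, channel-role
#' mapping, cohort labels and epoch annotations. Without a sidecar the sampling
#' rate is inferred from the time column and column headers are taken as roles.
#' Axon Binary Format is not handled by this build; export ABF records to CSV
#' (e.g. via Clampfit or a Python reader) first.
#'
#' @param path Path to a `.csv` recording.
#' @param format Optional format hint, `"csv"` (default, inferred from the
#'   extension) or `"abf"`.
#' @return A [recording()].
#' @export
load_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (identical(format, "abf"))
    stop("ABF reading is not available in this build; convert to CSV + JSON sidecar")
  if (!identical(format, "csv"))
    stop(sprintf("unsupported recording format '%s'", format))

  dat <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(dat))
    stop("recording CSV must have a 'time_s' column")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()

  fs <- meta$fs
  if (is.null(fs)) {
    dt <- diff(dat$time_s[1:min(nrow(dat), 1000L)])
    if (!length(dt) || any(dt <= 0)) stop("cannot infer sampling rate from time column")
    fs <- 1 / stats::median(dt)
  }
  if (!is.finite(fs) || fs <= 0) stop("invalid sampling rate in metadata")

  unit_scale <- switch(tolower(meta$units %||% "uv"),
                       uv = 1, "µv" = 1, mv = 1e3, v = 1e6,
                       stop("unknown units in metadata"))
  roles <- meta$roles
  cols <- setdiff(names(dat), "time_s")
  if (is.null(roles)) roles <- stats::setNames(cols, cols)
  channels <- lapply(cols, function(cn) {
    x <- dat[[cn]] * unit_scale
    if (anyNA(x)) stop(sprintf("channel '%s' contains NA samples", cn))
    trace(x, fs, role = roles[[cn]] %||% cn, t0 = dat$time_s[1L])
  })
  epochs <- if (!is.null(meta$epochs)) as.data.frame(meta$epochs) else NULL
  recording(channels,
            subject_id = meta$subject_id %||% basename(path),
            genotype = meta$genotype %||% "control",
            age_group = meta$age_group %||% "young",
            drug = meta$drug %||% "none",
            epochs = epochs)
}

#' Save a recording as CSV plus JSON sidecar
#'
#' Writes samples at full double precision so that a load/save round trip is
#' bit-exact, together with a sidecar holding sampling rate, units, roles,
#' cohort labels and epoch annotations.
#'
#' @param rec A [recording()].
#' @param path Output `.csv` path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gp_recording"))
  fs <- rec$channels[[1L]]$fs
  n <- max(vapply(rec$channels, function(ch) length(ch$samples), integer(1)))
  t0 <- rec$channels[[1L]]$t0
  out <- data.frame(time_s = t0 + (seq_len(n) - 1L) / fs)
  roles <- character()
  for (ch in rec$channels) {
    nm <- ch$role
    k <- 1L
    while (nm %in% names(out)) { k <- k + 1L; nm <- paste0(ch$role, "_", k) }
    v <- rep(NA_real_, n)
    v[seq_along(ch$samples)] <- ch$samples
    out[[nm]] <- v
    roles[nm] <- ch$role
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # full precision so round trips are exact
  con <- file(path, "w")
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(out, format_c17), sep = ",")), con)
  close(con)
  meta <- list(fs = fs, units = "uV", roles = as.list(roles),
               subject_id = rec$subject_id, genotype = rec$genotype,
               age_group = rec$age_group, drug = rec$drug,
               epochs = rec$epochs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

format_c17 <- function(x) {
  if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write metrics tables with a provenance sidecar
#'
#' Writes each table as CSV and a single JSON sidecar echoing the analysis
#' configuration, package version and seed, so that deterministic stages of a
#' run can be reproduced bit-identically.
#'
#' @param tables Named list of non-empty data frames.
#' @param dir Output directory (created if needed).
#' @param config Optional [analysis_config()] echoed into the sidecar.
#' @param seed Optional seed echoed into the sidecar.
#' @return Character vector of written file paths, invisibly.
#' @export
save_results <- function(tables, dir, config = NULL, seed = NULL) {
  if (!is.list(tables) || !length(tables) || is.null(names(tables)) ||
      any(!nzchar(names(tables))))
    stop("'tables' must be a non-empty named list of data frames")
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]]) || !nrow(tables[[nm]]))
      stop(sprintf("table '%s' is empty", nm))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_df_c17(tables[[nm]]), p, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p)
  }
  prov <- list(package = "gammaphase",
               version = as.character(utils::packageVersion("gammaphase")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               seed = seed,
               config = if (!is.null(config)) unclass(config),
               tables = names(tables))
  pp <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, pp))
}

format_df_c17 <- function(df) {
  as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) sprintf("%.17g", col) else col),
    check.names = FALSE, stringsAsFactors = FALSE)
}
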