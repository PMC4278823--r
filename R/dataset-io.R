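#' Read and write temperature-gradient abundance datasets
#'
#' Datasets are stored as plain CSV with columns `temperature_C`,
#' `replicate`, `time_d`, `count`, `frac_samp` (temperatures in Celsius,
#' counts as non-negative integers, per-row sampling fractions in (0, 1],
#' which may vary within a series as in real microcosm data). An optional
#' JSON sidecar records the resolved design, simulation truth and seed so
#' that any simulated dataset can be regenerated.
#'
#' @param dataset an `ea_dataset` (see [simulate_design()]) or a list with
#'   a conforming `data` data frame.
#' @param path CSV file path.
#' @param meta_path optional path for the JSON metadata sidecar; defaults
#'   to `path` with extension `.json` when writing a simulated dataset.
#' @return `read_dataset()` returns an `ea_dataset`; `write_dataset()`
#'   returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path, meta_path = NULL) {
  d <- dataset$data
  stopifnot(is.data.frame(d))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (is.null(meta_path) && (!is.null(dataset$design) ||
                             !is.null(dataset$model))) {
    meta_path <- paste0(sub("\\.csv$", "", path), ".json")
  }
  if (!is.null(meta_path)) {
    meta <- list(format_version = 1L, seed = dataset$seed)
    if (!is.null(dataset$design)) meta$design <- unclass(dataset$design)
    if (!is.null(dataset$model)) {
      m <- dataset$model
      meta$model <- list(theta01 = m$theta01, theta02 = m$theta02,
                         theta03 = m$theta03, e_a = as.list(m$e_a),
                         N = m$N, t0 = m$t0)
    }
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, meta_path = NULL) {
  d <- read.csv(path)
  required <- c("temperature_C", "replicate", "time_d", "count", "frac_samp")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(d$count) | d$count < 0 | d$count != floor(d$count))
  if (length(bad)) {
    stop("counts must be non-negative integers; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(d$frac_samp) | d$frac_samp <= 0 | d$frac_samp > 1)
  if (length(bad)) {
    stop("frac_samp must lie in (0, 1]; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is.finite(d$time_d) | d$time_d < 0)
  if (length(bad)) {
    stop("time_d must be non-negative; offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- list(data = d, design = NULL, model = NULL, seed = NULL)
  if (is.null(meta_path)) {
    candidate <- paste0(sub("\\.csv$", "", path), ".json")
    if (file.exists(candidate)) meta_path <- candidate
  }
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    out$seed <- meta$seed
    if (!is.null(meta$design)) {
      out$design <- experimental_design(
        temperatures = as.numeric(meta$design$temperatures),
        reps = meta$design$reps,
        sample_times = as.numeric(meta$design$sample_times),
        frac_samp = meta$design$frac_samp,
        n0 = meta$design$n0, horizon = meta$design$horizon
      )
    }
    if (!is.null(meta$model)) {
      ea <- unlist(meta$model$e_a)
      out$model <- arrhenius_model(
        theta01 = meta$model$theta01, theta02 = meta$model$theta02,
        theta03 = meta$model$theta03, e_a = ea,
        N = meta$model$N, t0 = meta$model$t0
      )
    }
  }
  structure(out, class = "ea_dataset")
}
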