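#' Write and read per-trial CSV
#'
#' Per-trial tables are exchanged as UTF-8 CSV with a header row, one row
#' per trial. Floats are written in shortest round-trip representation, so
#' re-reading reproduces the values exactly.
#'
#' @param data A per-trial tibble (schedule, environment, or subject data).
#' @param path File path.
#' @return `write_trials_csv` returns `data` invisibly; `read_trials_csv`
#'   returns a tibble.
#' @export
write_trials_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(data)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a schedule configuration from YAML
#'
#' The YAML schema is a mapping with a `blocks` list of
#' `{n_trials, p_assoc}` entries plus optional `seed` and
#' `label_threshold`.
#'
#' @param path Path to the YAML file.
#' @return A list with `blocks` (tibble), `seed`, `label_threshold`.
#' @export
read_schedule_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  abort_if(is.null(cfg$blocks), "schedule config must contain 'blocks'")
  blocks <- purrr::map_dfr(cfg$blocks, function(b) {
    abort_if(is.null(b$n_trials) || is.null(b$p_assoc),
             "each block needs n_trials and p_assoc")
    tibble::tibble(n_trials = as.integer(b$n_trials),
                   p_assoc = as.numeric(b$p_assoc))
  })
  list(blocks = blocks,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       label_threshold = if (is.null(cfg$label_threshold)) 0.3
         else as.numeric(cfg$label_threshold))
}

#' Serialize fit results to JSON
#'
#' Writes per subject x model MAP estimates (native and unconstrained
#' space), log evidence and diagnostics, together with the package version
#' and seed, to a JSON file.
#'
#' @param fits A tibble with columns `subject`, `model`, `fit` (list of
#'   `hgfs_fit`), e.g. from [fit_cohort()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  require_columns(fits, c("subject", "model", "fit"), "fits")
  payload <- purrr::map(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    list(
      subject = fits$subject[i], model = f$model,
      estimates_native = f$estimates,
      estimates_unconstrained = as.list(f$theta),
      log_joint = f$log_joint, log_lik = f$log_lik,
      log_evidence = f$log_evidence, evidence_method = f$evidence_method,
      converged = f$converged, failed = f$failed,
      n_restarts_used = f$n_restarts_used, seed = f$seed
    )
  })
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("socialnoise")),
         fits = payload),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
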