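#' Read / write longitudinal network datasets
#'
#' The wide CSV format has columns `subject_id`, `age`,
#' `node_1..node_K` (plus optional covariates); the tidy format has
#' `subject_id`, `age`, `node`, `value`. Both round-trip losslessly and
#' convert to the same validated wide tibble.
#'
#' @param path CSV file path.
#' @param format `"wide"` (default) or `"tidy"`.
#' @return `read_course_data()` returns a validated wide tibble;
#'   `write_course_data()` returns `path` invisibly.
#' @export
read_course_data <- function(path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  if (format == "tidy") df <- course_widen(df)
  as_course_data(df)
}

#' @rdname read_course_data
#' @param data Dataset to write.
#' @export
write_course_data <- function(data, path, format = c("wide", "tidy")) {
  format <- match.arg(format)
  data <- as_course_data(data)
  if (format == "tidy") data <- course_lengthen(data)
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Convert between wide and tidy dataset layouts
#'
#' @param data A dataset in the other layout.
#' @return `course_lengthen()`: tidy tibble (`subject_id`, `age`, `node`,
#'   `value`); `course_widen()`: wide tibble with `node_<k>` columns.
#' @export
course_lengthen <- function(data) {
  out <- tidyr::pivot_longer(tibble::as_tibble(data),
                             dplyr::matches("^node_\\d+$"),
                             names_to = "node", values_to = "value")
  out$node <- as.integer(sub("node_", "", out$node))
  dplyr::arrange(out, .data$subject_id, .data$age, .data$node)
}

#' @rdname course_lengthen
#' @export
course_widen <- function(data) {
  stopifnot(all(c("node", "value") %in% names(data)))
  data <- dplyr::mutate(tibble::as_tibble(data),
                        node = paste0("node_", .data$node))
  tidyr::pivot_wider(data, names_from = "node", values_from = "value")
}

bundle_schema_version <- "1"

#' Serialize / restore population parameters as a JSON bundle
#'
#' The bundle carries a schema version, the package version, the full set
#' of population parameters and hyper-parameters, and an optional free-form
#' metadata list (e.g. the seed and config of the producing run). Reading a
#' bundle with a different schema version is an explicit error.
#'
#' @param params A `course_params`.
#' @param path Output JSON path.
#' @param meta Optional named list stored verbatim in the bundle.
#' @return `write_model_bundle()` returns `path` invisibly;
#'   `read_model_bundle()` returns the `course_params`.
#' @export
write_model_bundle <- function(params, path, meta = list()) {
  stopifnot(inherits(params, "course_params"))
  payload <- list(
    schema_version = bundle_schema_version,
    package = "netcourse",
    package_version = as.character(utils::packageVersion("netcourse")),
    meta = meta,
    dims = list(
      n_ctrl = length(params$p_ctrl),
      n_beta = length(params$beta)
    ),
    params = unclass(params)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(payload$schema_version), bundle_schema_version)) {
    abort(paste0(
      "Model-bundle schema version ", payload$schema_version,
      " does not match the supported version ", bundle_schema_version, "."
    ))
  }
  p <- payload$params
  need <- c("t0", "p_ctrl", "v_ctrl", "n_sources", "sigma_tau2", "sigma_xi2",
            "sigma2", "bandwidth")
  if (!all(need %in% names(p))) abort("Model bundle is missing required fields.")
  beta <- as.numeric(p$beta %||% numeric(0))
  dims <- payload$dims
  if (!is.null(dims)) {
    if (length(p$p_ctrl) != dims$n_ctrl || length(p$v_ctrl) != dims$n_ctrl ||
        length(beta) != dims$n_beta) {
      abort("Corrupt bundle: field lengths inconsistent with the recorded dimensions.")
    }
  }
  if (length(beta) %% max(p$n_sources, 1) != 0) {
    abort("Corrupt bundle: mixing-coefficient length inconsistent with n_sources.")
  }
  course_params(
    t0 = p$t0, p_ctrl = p$p_ctrl, v_ctrl = p$v_ctrl, beta = beta,
    n_sources = p$n_sources, sigma_tau2 = p$sigma_tau2,
    sigma_xi2 = p$sigma_xi2, sigma2 = p$sigma2, bandwidth = p$bandwidth,
    p_bar = p$p_bar, v_bar = p$v_bar,
    beta_bar = as.numeric(p$beta_bar %||% rep(0, length(beta))),
    sigma_p2 = p$sigma_p2, sigma_v2 = p$sigma_v2,
    sigma_beta2 = p$sigma_beta2
  )
}

#' Plain-text summary report of a fit
#'
#' Renders a markdown summary of a fitted model: data shape, final
#' parameters, acceptance rates, and - when a simulation truth is supplied -
#' a parameter-recovery table (estimate, truth, relative error). Content is
#' deterministic given the fit.
#'
#' @param fit A `course_fit`.
#' @param truth Optional named list/vector of true parameter values for the
#'   recovery table (names matching [tidy.course_fit()] terms).
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines, invisibly if `path` given.
#' @export
run_report <- function(fit, truth = NULL, path = NULL) {
  stopifnot(inherits(fit, "course_fit"))
  td <- tidy(fit)
  lines <- c(
    "# netcourse fit report",
    "",
    paste0("- package version: ",
           as.character(utils::packageVersion("netcourse"))),
    paste0("- seed: ", fit$control$seed %||% "none"),
    paste0("- subjects: ", length(fit$subjects), "; visits: ", fit$n_obs,
           "; nodes: ", n_nodes(fit$graph)),
    paste0("- iterations: ", fit$control$n_iter, " (burn-in ",
           fit$control$n_burn_in, ")"),
    paste0("- final log-likelihood term: ", format(fit$log_lik, digits = 8)),
    "",
    "## Parameter estimates",
    "",
    "| parameter | estimate |",
    "|---|---|",
    sprintf("| %s | %.6g |", td$term, td$estimate),
    "",
    "## Acceptance rates",
    "",
    "| block | adapted | sampling |",
    "|---|---|---|",
    sprintf("| %s | %.3f | %.3f |", fit$accept$block,
            fit$accept$rate_adapted, fit$accept$rate_sampling)
  )
  if (!is.null(truth)) {
    est <- setNames(td$estimate, td$term)
    rec <- recovery_score(est, truth)
    lines <- c(
      lines, "", "## Parameter recovery", "",
      "| parameter | estimate | truth | error | type |",
      "|---|---|---|---|---|",
      sprintf("| %s | %.6g | %.6g | %.3g | %s |", rec$parameter,
              rec$estimate, rec$truth, rec$error, rec$error_type)
    )
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
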