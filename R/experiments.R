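#' Read a tabular dataset for analysis
#'
#' CSV or TSV with a header row; the delimiter is inferred from the file
#' extension (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}

#' @keywords internal
read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("Config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path.",
                             call. = FALSE)
  if (is.null(config$response)) {
    stop("Config must name a `response` column.", call. = FALSE)
  }
  config$fixed <- as.character(config$fixed %||% character())
  rnd <- config$random %||% list()
  rnd$group <- rnd$group %||% "group"
  rnd$intercept <- rnd$intercept %||% TRUE
  rnd$slopes <- as.character(rnd$slopes %||% config$fixed)
  config$random <- rnd
  config$family <- config$family %||% "gaussian-identity"
  config$method <- config$method %||% "REML"
  config
}

#' @keywords internal
components_from_config <- function(data, config) {
  # pre-estimated parameters supplied directly: no fitting
  supplied <- config$components
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  for (cl in config$fixed) X <- cbind(X, data[[cl]])
  colnames(X) <- c("(Intercept)", config$fixed)
  term <- build_random_design(data, config$random$group,
                              intercept = isTRUE(config$random$intercept),
                              slope_columns = config$random$slopes)
  term$Sigma <- validate_covariance(
    matrix(unlist(supplied$Sigma), nrow = length(supplied$Sigma),
           byrow = TRUE))
  model_components(X = X, beta = as.numeric(unlist(supplied$beta)),
                   terms = list(term),
                   sigma2_e = as.numeric(supplied$sigma2_e %||% 0),
                   family_link = config$family)
}

#' Variance partition and R-squared for a dataset
#'
#' End-to-end: read the data, fit the Gaussian random-slopes model (or
#' build components from parameters supplied in the config for any
#' family), partition the variance, and optionally write a JSON report.
#'
#' @param data a data frame or a CSV/TSV path.
#' @param config a list or YAML path with keys `response`, `fixed`,
#'   `random` (`group`, `intercept`, `slopes`), `family`, `method`, and
#'   optionally `components` (`beta`, `Sigma` as list of rows, `sigma2_e`)
#'   to skip fitting.
#' @param out optional path for the JSON report.
#' @return the report as a list (invisibly if `out` is given): `family`,
#'   `method`, `partition`, `r2`, `fit` (diagnostics, or `NULL` when
#'   components were supplied).
#' @export
run_r2 <- function(data, config, out = NULL) {
  if (is.character(data)) data <- read_dataset(data)
  config <- read_config(config)
  if (!is.null(config$components)) {
    components <- components_from_config(data, config)
    fit_info <- NULL
  } else {
    if (config$family != "gaussian-identity") {
      stop("Only gaussian-identity models are fitted internally; for other ",
           "families supply `components` in the config.", call. = FALSE)
    }
    fit <- fit_lmm(data, config$response, fixed = config$fixed,
                   random = list(grouping = config$random$group,
                                 intercept = config$random$intercept,
                                 slopes = config$random$slopes),
                   method = config$method)
    components <- fit$components
    fit_info <- list(loglik = fit$loglik, method = fit$method,
                     converged = fit$converged, n_groups = fit$n_groups,
                     iterations = fit$iterations)
  }
  res <- r2_glmm(components)
  report <- list(
    family = components$family_link,
    method = if (is.null(fit_info)) "supplied" else fit_info$method,
    partition = list(
      sigma2_f = res$partition$sigma2_f,
      sigma2_terms = as.list(res$partition$sigma2_terms),
      sigma2_e = res$partition$sigma2_e,
      sigma2_d = res$partition$sigma2_d
    ),
    r2 = list(marginal = res$marginal, conditional = res$conditional),
    fit = fit_info
  )
  if (!is.null(out)) {
    write_report(report, out)
    return(invisible(report))
  }
  report
}

#' Write a JSON analysis report
#'
#' @param report a report list (see [run_r2()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Check a report against the shipped schema
#'
#' Structural validation of an analysis report against the JSON schema in
#' `inst/schema/report.schema.json`: required keys present, types correct,
#' R-squared values within their bounds.
#'
#' @param report a report list or a JSON file path.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(
    system.file("schema", "report.schema.json", package = "r2slopes"))
  check_node <- function(node, sch, path) {
    type <- sch$type
    if (identical(type, "object")) {
      if (!is.list(node)) stop("Report: ", path, " must be an object.",
                               call. = FALSE)
      for (key in unlist(sch$required)) {
        if (!key %in% names(node)) {
          stop("Report: missing required key ", path, ".", key, call. = FALSE)
        }
      }
      for (key in names(sch$properties)) {
        if (key %in% names(node) && !is.null(node[[key]])) {
          check_node(node[[key]], sch$properties[[key]],
                     paste0(path, ".", key))
        }
      }
    } else if (identical(type, "number")) {
      if (!is.numeric(node) || length(node) != 1L) {
        stop("Report: ", path, " must be a number.", call. = FALSE)
      }
      if (!is.null(sch$minimum) && node < sch$minimum) {
        stop("Report: ", path, " below minimum ", sch$minimum, ".",
             call. = FALSE)
      }
      if (!is.null(sch$maximum) && node > sch$maximum) {
        stop("Report: ", path, " above maximum ", sch$maximum, ".",
             call. = FALSE)
      }
    } else if (identical(type, "string")) {
      if (!is.character(node) || length(node) != 1L) {
        stop("Report: ", path, " must be a string.", call. = FALSE)
      }
    } else if (identical(type, "boolean")) {
      if (!is.logical(node) || length(node) != 1L) {
        stop("Report: ", path, " must be a boolean.", call. = FALSE)
      }
    }
    invisible(TRUE)
  }
  check_node(report, schema, "$")
  invisible(TRUE)
}

#' @keywords internal
scenario_spec <- function(scenario, seed, n_groups = 20L,
                          obs_per_group = 25L, dominant_fraction = 0.8) {
  total_n <- n_groups * obs_per_group
  if (scenario == "balanced") {
    simulation_spec(n_groups = n_groups, group_sizes = obs_per_group,
                    covariate_rule = "shared", seed = seed)
  } else {
    simulation_spec(
      n_groups = n_groups,
      group_sizes = make_unbalanced_design(n_groups, dominant_fraction,
                                           total_n),
      covariate_rule = "group-ranges", seed = seed)
  }
}

#' Balanced vs. unbalanced design experiment
#'
#' For each seed, simulates a dataset under the scenario, fits it twice —
#' as a random-intercepts model and as a random-slopes model — and records
#' marginal and conditional R-squared from both fits plus the analytic
#' true values. With balanced group sizes and matching covariate
#' distributions the random-intercepts approximation to marginal
#' R-squared is good; with a dominant group whose covariate range differs,
#' the global slope of the random-intercepts fit is pulled toward that
#' group and the two fits disagree more.
#'
#' @param scenario `"balanced"` or `"unbalanced"`.
#' @param seeds integer vector of simulation seeds (non-empty).
#' @param out_dir optional directory: per-seed table written as
#'   `<scenario>_results.csv`, summary as `<scenario>_summary.json`.
#' @param n_groups,obs_per_group,dominant_fraction design knobs; defaults
#'   20 groups x 25 observations, dominant group holding 80%.
#' @return list with `results` (per-seed data frame) and `summary` (mean
#'   absolute discrepancies between the two fits, and vs. the truth).
#' @export
run_experiment <- function(scenario = c("balanced", "unbalanced"), seeds,
                           out_dir = NULL, n_groups = 20L,
                           obs_per_group = 25L, dominant_fraction = 0.8) {
  scenario <- match.arg(scenario)
  if (length(seeds) == 0L) stop("`seeds` must be non-empty.", call. = FALSE)
  rows <- vector("list", length(seeds))
  failures <- 0L
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    spec <- scenario_spec(scenario, seed, n_groups, obs_per_group,
                          dominant_fraction)
    d <- simulate_dataset(spec)
    truth <- true_partition(spec, d$x)
    row <- tryCatch({
      fit_ri <- fit_lmm(d, "y", fixed = "x",
                        random = list(grouping = "group", intercept = TRUE,
                                      slopes = character()))
      fit_rs <- fit_lmm(d, "y", fixed = "x",
                        random = list(grouping = "group", intercept = TRUE,
                                      slopes = "x"))
      r2_ri <- r2_glmm(fit_ri$components)
      r2_rs <- r2_glmm(fit_rs$components)
      data.frame(
        scenario = scenario, seed = seed,
        r2m_intercepts = r2_ri$marginal, r2c_intercepts = r2_ri$conditional,
        r2m_slopes = r2_rs$marginal, r2c_slopes = r2_rs$conditional,
        r2m_true = r2_marginal(truth), r2c_true = r2_conditional(truth),
        sigma2e_intercepts = fit_ri$components$sigma2_e,
        sigma2e_slopes = fit_rs$components$sigma2_e
      )
    }, error = function(e) {
      warning("Seed ", seed, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(row)) failures <- failures + 1L else rows[[i]] <- row
  }
  if (failures == length(seeds)) {
    stop("Every seed failed to fit.", call. = FALSE)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary <- list(
    scenario = scenario,
    n_seeds = nrow(results),
    mean_abs_diff_r2m_fits = mean(abs(results$r2m_slopes -
                                        results$r2m_intercepts)),
    mean_abs_diff_r2c_fits = mean(abs(results$r2c_slopes -
                                        results$r2c_intercepts)),
    mean_abs_err_r2m_slopes = mean(abs(results$r2m_slopes -
                                         results$r2m_true)),
    mean_abs_err_r2c_slopes = mean(abs(results$r2c_slopes -
                                         results$r2c_true)),
    frac_sigma2e_lower_slopes = mean(results$sigma2e_slopes <=
                                       results$sigma2e_intercepts)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results,
                     file.path(out_dir, paste0(scenario, "_results.csv")),
                     row.names = FALSE)
    jsonlite::write_json(summary,
                         file.path(out_dir, paste0(scenario,
                                                   "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, summary = summary)
}

#' Conditioned-ICC curve for a dataset
#'
#' Fits the Gaussian random-slopes model (or uses supplied components) and
#' evaluates the between-group variance and intraclass correlation at each
#' requested covariate value.
#'
#' @inheritParams run_r2
#' @param values numeric vector of covariate values to condition on.
#' @param out optional CSV path for the curve.
#' @return data frame with columns `value`, `sigma2_alpha`, `icc`.
#' @export
run_icc <- function(data, config, values, out = NULL) {
  if (is.character(data)) data <- read_dataset(data)
  config <- read_config(config)
  if (!is.null(config$components)) {
    components <- components_from_config(data, config)
  } else {
    if (config$family != "gaussian-identity") {
      stop("Only gaussian-identity models are fitted internally; for other ",
           "families supply `components` in the config.", call. = FALSE)
    }
    components <- fit_lmm(data, config$response, fixed = config$fixed,
                          random = list(grouping = config$random$group,
                                        intercept = config$random$intercept,
                                        slopes = config$random$slopes),
                          method = config$method)$components
  }
  term <- components$terms[[1]]
  beta0 <- estimate_beta0(components$X, components$beta)
  sigma2_d <- distribution_specific_variance(components$family_link, beta0)
  n_slopes <- ncol(term$Z) - as.integer(term$intercept)
  if (n_slopes == 0L) {
    # intercept-only term: the ICC does not depend on the covariate
    s2a <- rep(term$Sigma[1, 1], length(values))
    icc <- s2a / (s2a + components$sigma2_e + sigma2_d)
  } else {
    s2a <- vapply(values, function(v) {
      row <- if (term$intercept) c(1, v) else v
      max(as.numeric(row %*% term$Sigma %*% row), 0)
    }, numeric(1))
    icc <- icc_conditional(term, components$sigma2_e, sigma2_d, values)
  }
  curve <- data.frame(value = values, sigma2_alpha = s2a, icc = icc)
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve, out, row.names = FALSE)
    return(invisible(curve))
  }
  curve
}
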