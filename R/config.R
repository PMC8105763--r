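# party-tagged structured logging; never prints patient-level values
vdra_log <- function(party, ...) {
  if (isTRUE(getOption("vdra.verbose", FALSE)))
    message(sprintf("[%s] %s", party, paste0(...)))
  invisible(NULL)
}

cohort_spec_from_list <- function(x) {
  cohort_spec(n_patients = x$n_patients,
              covariates = x$covariates,
              outcome_model = x$outcome_model %||% "linear",
              true_beta = unlist(x$true_beta),
              noise_sd = x$noise_sd %||% 1,
              outcome_name = x$outcome_name %||% "y",
              seed = x$seed %||% 1L)
}

partition_plan_from_list <- function(x) {
  partition_plan(column_assignment = unlist(x$column_assignment),
                 outcome_site = x$outcome_site,
                 outcome_name = x$outcome_name %||% "y",
                 site_ids = if (!is.null(x$site_ids)) unlist(x$site_ids))
}

#' Validate a run configuration
#'
#' Structural and cross-reference checks on a JSON run configuration
#' (cohort spec, partition plan, model, routing, convergence): every
#' violation found is listed; an empty list means the configuration is
#' runnable.
#'
#' @param config path to a JSON configuration, or an equivalent list.
#' @return list with `valid` (logical) and `violations` (character vector).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      vdra_error("vdra_io_error", sprintf("cannot read config '%s'", config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$cohort)) add("missing section: cohort")
  if (is.null(config$partition)) add("missing section: partition")
  spec <- NULL
  if (!is.null(config$cohort)) {
    spec <- tryCatch(cohort_spec_from_list(config$cohort),
                     vdra_error = function(e) { add(paste("cohort:", conditionMessage(e))); NULL },
                     error = function(e) { add(paste("cohort:", conditionMessage(e))); NULL })
  }
  plan <- NULL
  if (!is.null(config$partition)) {
    ca <- unlist(config$partition$column_assignment)
    oc <- config$partition$outcome_name %||% "y"
    if (!is.null(ca) && sum(names(ca) == oc) > 1L)
      add("partition: outcome assigned to more than one site")
    plan <- tryCatch(partition_plan_from_list(config$partition),
                     vdra_error = function(e) { add(paste("partition:", conditionMessage(e))); NULL },
                     error = function(e) { add(paste("partition:", conditionMessage(e))); NULL })
  }
  if (!is.null(spec) && !is.null(plan)) {
    covs <- vapply(spec$covariates, `[[`, character(1), "name")
    extra <- setdiff(names(plan$column_assignment),
                     c(covs, spec$outcome_name))
    if (length(extra))
      add(sprintf("partition assigns unknown column(s): %s",
                  paste(extra, collapse = ", ")))
    missing <- setdiff(covs, names(plan$column_assignment))
    if (length(missing))
      add(sprintf("covariate(s) not assigned to any site: %s",
                  paste(missing, collapse = ", ")))
    if (!identical(spec$outcome_name, plan$outcome_name))
      add("cohort and partition disagree on the outcome name")
  }
  model <- config$model %||% "linear"
  if (!model %in% c("linear", "logistic"))
    add(sprintf("unknown model type '%s'", model))
  routing <- config$routing %||% "direct"
  if (!routing %in% c("direct", "hub_and_spoke"))
    add(sprintf("unknown routing mode '%s'", routing))
  cv <- config$convergence
  if (!is.null(cv)) {
    if (!is.null(cv$tol) && cv$tol <= 0) add("convergence: tol must be positive")
    if (!is.null(cv$max_iter) && cv$max_iter < 1)
      add("convergence: max_iter must be >= 1")
  }
  if (!is.null(config$block_plan) && !is.null(spec)) {
    ok <- tryCatch({
      block_plan(config$block_plan, spec$n_patients); TRUE
    }, error = function(e) { add(paste("block_plan:", conditionMessage(e))); FALSE })
  }
  list(valid = length(v) == 0L, violations = v)
}

fit_to_list <- function(fit) {
  list(model = fit$model, source = fit$source,
       coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       cov_beta = unname(apply(fit$cov_beta, 1L, as.list)),
       fit = fit$fit, n = fit$n, p = fit$p,
       converged = fit$converged, n_iter = fit$n_iter,
       termination_reason = fit$termination_reason,
       column_order = fit$column_order)
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(x$coefficients)
  se <- unlist(x$se)
  cov <- do.call(rbind, lapply(x$cov_beta, unlist))
  dimnames(cov) <- list(names(beta), names(beta))
  new_vdra_fit(x$model, beta, se, cov, x$fit, x$n, x$p, x$converged,
               x$n_iter, x$termination_reason, x$source)
}

#' Run a complete seeded vDRA experiment end to end
#'
#' Generates the synthetic cohort, partitions it vertically, writes per-site
#' CSVs, stands up the trust-governed transfer network, executes the full
#' distributed workflow, fits the pooled patient-level oracle, compares the
#' two, and writes all artifacts (result, oracle, comparison, metrics JSON;
#' audit log in the run directory). Identical configuration and seed yield
#' identical artifacts: all clocks are logical and all randomness is seeded.
#'
#' @param config path to a JSON run configuration, or an equivalent list.
#'   Sections: `cohort`, `partition`, and optionally `model`, `routing`,
#'   `convergence`, `block_plan`, `g`, `trust_pairs` (list of allowed
#'   site-to-site pairs, or `"all"`), `seed`, `compare_tol`, `out_dir`.
#' @param out_dir output directory (overrides the config's).
#' @param seed seed override.
#' @return list with `status` (0 on success and comparison pass; 1 on
#'   termination or comparison failure), `result`, `oracle`, `comparison`,
#'   `metrics`, `terminated`, and artifact `paths`.
#' @export
run_end_to_end <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  chk <- validate_config(config)
  if (!chk$valid)
    vdra_error("vdra_config_error", paste(
      "invalid configuration:", paste(chk$violations, collapse = "; ")))
  out_dir <- out_dir %||% config$out_dir %||% tempfile("vdra-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(seed)) config$cohort$seed <- seed
  seed <- config$cohort$seed %||% 1L
  model <- config$model %||% "linear"
  spec <- cohort_spec_from_list(config$cohort)
  plan <- partition_plan_from_list(config$partition)
  vdra_log("simulator", "generating cohort of ", spec$n_patients, " patients")
  tab <- generate_cohort(spec)
  sites <- partition_vertical(tab, plan)
  site_dir <- file.path(out_dir, "sites")
  dir.create(site_dir, showWarnings = FALSE)
  for (s in sites)
    write_partition(s, file.path(site_dir, paste0(s$site_id, ".csv")))
  routing <- config$routing %||% "direct"
  net <- create_network(file.path(out_dir, "network"), plan$site_ids,
                        routing = routing)
  tp <- config$trust_pairs %||% "all"
  if (identical(tp, "all")) {
    for (a in plan$site_ids) for (b in setdiff(plan$site_ids, a))
      set_trust(net, a, b, TRUE, actor = center_id(net))
  } else {
    for (pr in tp)
      set_trust(net, pr[[1L]], pr[[2L]], TRUE, actor = center_id(net))
  }
  cv <- config$convergence %||% list()
  conv <- convergence_spec(tol = cv$tol %||% 1e-8,
                           max_iter = cv$max_iter %||% 25L,
                           criterion = cv$criterion %||% "max-abs-delta-beta")
  bp <- if (!is.null(config$block_plan))
    block_plan(config$block_plan, spec$n_patients)
  terminated <- FALSE
  run <- tryCatch(
    run_vdra_workflow(net, sites, outcome = spec$outcome_name, model = model,
                      conv = conv, g = config$g, seed = seed,
                      block_plan = bp),
    vdra_termination_error = function(e) {
      terminated <<- TRUE
      vdra_log(center_id(net), "run terminated: ", conditionMessage(e))
      NULL
    })
  paths <- list(audit = file.path(net$run_dir, "audit.jsonl"),
                metrics = file.path(out_dir, "metrics.json"))
  jsonlite::write_json(transfer_metrics(net), paths$metrics,
                       auto_unbox = TRUE, digits = NA)
  if (terminated)
    return(list(status = 1L, result = NULL, oracle = NULL, comparison = NULL,
                metrics = transfer_metrics(net), terminated = TRUE,
                paths = paths))
  covs <- vapply(spec$covariates, `[[`, character(1), "name")
  oracle <- pooled_oracle_fit(tab, model, covs, spec$outcome_name)
  tol <- config$compare_tol %||% if (model == "linear") 1e-12 else 1e-8
  cmp <- compare_results(run$result, oracle, tol = tol)
  paths$result <- write_fit_json(run$result, file.path(out_dir, "result.json"))
  paths$oracle <- write_fit_json(oracle, file.path(out_dir, "oracle.json"))
  jsonlite::write_json(
    cmp[c("beta_max_diff", "se_max_diff", "max_diff", "tol", "pass")],
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  paths$comparison <- file.path(out_dir, "comparison.json")
  list(status = if (cmp$pass) 0L else 1L, result = run$result,
       oracle = oracle, comparison = cmp, metrics = run$metrics,
       terminated = FALSE, paths = paths)
}
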