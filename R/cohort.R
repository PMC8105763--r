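#' Specify a synthetic cohort with known regression structure
#'
#' Defines the data-generating model for a synthetic patient cohort: a set of
#' continuous or binary covariates and a linear or logistic outcome with a
#' known coefficient vector. The generated cohort is the ground truth against
#' which distributed fits are verified.
#'
#' @param n_patients number of patients; must be at least
#'   `length(true_beta) + 2`.
#' @param covariates list of covariate definitions, each a list with elements
#'   `name`, `kind` (`"continuous"` or `"binary"`) and distribution
#'   parameters: `mean`/`sd` for continuous (defaults 0/1, i.e. standardized),
#'   `prob` for binary (default 0.5).
#' @param outcome_model `"linear"` or `"logistic"`.
#' @param true_beta numeric vector of coefficients, intercept first; length
#'   must be `1 + length(covariates)`.
#' @param noise_sd residual standard deviation for the linear model
#'   (ignored for logistic); must be nonnegative.
#' @param outcome_name name of the outcome column.
#' @param seed integer seed; each column is generated from its own child
#'   stream derived from this seed, so adding a covariate does not perturb
#'   previously generated columns.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, covariates, outcome_model = c("linear", "logistic"),
                        true_beta, noise_sd = 1, outcome_name = "y", seed = 1L) {
  outcome_model <- match.arg(outcome_model)
  if (!is.list(covariates) || length(covariates) == 0L)
    vdra_error("vdra_spec_error", "at least one covariate must be specified")
  covariates <- lapply(covariates, function(cv) {
    if (is.null(cv$name) || !nzchar(cv$name))
      vdra_error("vdra_spec_error", "every covariate needs a name")
    kind <- match.arg(cv$kind, c("continuous", "binary"))
    if (kind == "continuous") {
      cv$mean <- cv$mean %||% 0; cv$sd <- cv$sd %||% 1
      if (cv$sd <= 0) vdra_error("vdra_spec_error",
        sprintf("covariate '%s': sd must be positive", cv$name))
    } else {
      cv$prob <- cv$prob %||% 0.5
      if (cv$prob <= 0 || cv$prob >= 1) vdra_error("vdra_spec_error",
        sprintf("covariate '%s': prob must lie in (0, 1)", cv$name))
    }
    cv$kind <- kind
    cv
  })
  nm <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(nm)) vdra_error("vdra_spec_error", "duplicate covariate names")
  if (outcome_name %in% nm)
    vdra_error("vdra_spec_error", "outcome name collides with a covariate name")
  if (length(true_beta) != 1L + length(covariates))
    vdra_error("vdra_spec_error",
      "length(true_beta) must equal 1 + number of covariates")
  if (noise_sd < 0) vdra_error("vdra_spec_error", "noise_sd must be nonnegative")
  if (n_patients < length(true_beta) + 2L)
    vdra_error("vdra_spec_error", "n_patients too small for the model")
  structure(list(
    n_patients = as.integer(n_patients), covariates = covariates,
    outcome_model = outcome_model, true_beta = as.numeric(true_beta),
    noise_sd = as.numeric(noise_sd), outcome_name = outcome_name,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate the pooled patient-level table for a cohort specification
#'
#' Draws covariates column by column from per-column seeded streams, then the
#' outcome: `y = X beta + N(0, noise_sd^2)` for the linear model,
#' `y ~ Bernoulli(expit(X beta))` for the logistic model (`X` includes the
#' intercept). Deterministic given the spec's seed. The returned pooled table
#' exists only inside the simulator and the oracle fits; the distributed
#' machinery never sees it.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` with a `patient_id` first column, one column per
#'   covariate, and the outcome column, rows in canonical (sorted-ID) order.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  cols <- lapply(spec$covariates, function(cv) {
    set.seed(child_seed(spec$seed, "cov", cv$name))
    if (cv$kind == "continuous") rnorm(n, cv$mean, cv$sd)
    else as.numeric(rbinom(n, 1L, cv$prob))
  })
  names(cols) <- vapply(spec$covariates, `[[`, character(1), "name")
  X <- cbind(1, do.call(cbind, cols))
  eta <- drop(X %*% spec$true_beta)
  set.seed(child_seed(spec$seed, "outcome"))
  y <- if (spec$outcome_model == "linear") {
    eta + if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
  } else {
    as.numeric(rbinom(n, 1L, plogis(eta)))
  }
  out <- data.frame(patient_id = seq_len(n), cols, check.names = FALSE)
  out[[spec$outcome_name]] <- y
  out
}

#' Plan a vertical (column-wise) partition of a cohort across sites
#'
#' @param column_assignment named character vector mapping each non-ID column
#'   name to the site that holds it.
#' @param outcome_site site holding the outcome column.
#' @param outcome_name name of the outcome column.
#' @param site_ids ordered site identifiers; defaults to the sites appearing
#'   in `column_assignment`, in order of first appearance.
#' @return an object of class `partition_plan`.
#' @export
partition_plan <- function(column_assignment, outcome_site, outcome_name = "y",
                           site_ids = NULL) {
  if (is.null(names(column_assignment)) || any(!nzchar(names(column_assignment))))
    vdra_error("vdra_plan_error", "column_assignment must be a named vector")
  site_ids <- site_ids %||% unique(unname(column_assignment))
  if (length(site_ids) < 2L)
    vdra_error("vdra_plan_error", "a vertical partition needs at least 2 sites")
  if (!all(column_assignment %in% site_ids))
    vdra_error("vdra_plan_error", "column assigned to an unknown site")
  if (!all(site_ids %in% column_assignment))
    vdra_error("vdra_plan_error", "every site must hold at least one column")
  if (!outcome_site %in% site_ids)
    vdra_error("vdra_plan_error", "outcome_site is not among site_ids")
  if (!outcome_name %in% names(column_assignment) ||
      column_assignment[[outcome_name]] != outcome_site)
    vdra_error("vdra_plan_error",
      "the outcome column must be assigned to outcome_site")
  structure(list(
    site_ids = site_ids, column_assignment = column_assignment,
    outcome_site = outcome_site, outcome_name = outcome_name
  ), class = "partition_plan")
}

new_site_partition <- function(site_id, patient_id, data) {
  if (anyDuplicated(patient_id))
    vdra_error("vdra_format_error", "duplicate patient_id values")
  if (anyNA(patient_id) || anyNA(data))
    vdra_error("vdra_format_error", "missing values are not supported")
  structure(list(
    site_id = site_id, patient_id = patient_id,
    data = as.data.frame(data, check.names = FALSE),
    n = length(patient_id)
  ), class = "site_partition")
}

#' @export
print.site_partition <- function(x, ...) {
  cat(sprintf("<site_partition> site '%s': %d patients x %d columns (%s)\n",
              x$site_id, x$n, ncol(x$data),
              paste(names(x$data), collapse = ", ")))
  invisible(x)
}

# numeric matrix of a site's local columns, in a given (or local) order
partition_matrix <- function(partition, columns = NULL) {
  columns <- columns %||% names(partition$data)
  missing <- setdiff(columns, names(partition$data))
  if (length(missing))
    vdra_error("vdra_spec_error", sprintf(
      "site '%s' does not hold column(s): %s",
      partition$site_id, paste(missing, collapse = ", ")))
  as.matrix(partition$data[columns])
}

#' Split a pooled table column-wise into per-site partitions
#'
#' Every site receives the shared `patient_id` column plus its assigned data
#' columns; all partitions share the canonical row order (sorted by patient
#' ID), so re-joining on `patient_id` reproduces the input exactly.
#'
#' @param table pooled patient-level `data.frame` with a `patient_id` column.
#' @param plan a [partition_plan()].
#' @return named list of `site_partition` objects, one per site in plan order.
#' @export
partition_vertical <- function(table, plan) {
  stopifnot(inherits(plan, "partition_plan"))
  if (!"patient_id" %in% names(table))
    vdra_error("vdra_format_error", "table has no patient_id column")
  data_cols <- setdiff(names(table), "patient_id")
  missing <- setdiff(names(plan$column_assignment), names(table))
  if (length(missing))
    vdra_error("vdra_plan_error", sprintf(
      "plan assigns nonexistent column(s): %s", paste(missing, collapse = ", ")))
  unassigned <- setdiff(data_cols, names(plan$column_assignment))
  if (length(unassigned))
    vdra_error("vdra_plan_error", sprintf(
      "column(s) not assigned to any site: %s", paste(unassigned, collapse = ", ")))
  table <- table[order(table$patient_id), , drop = FALSE]
  out <- lapply(plan$site_ids, function(s) {
    cols <- names(plan$column_assignment)[plan$column_assignment == s]
    cols <- intersect(names(table), cols)  # keep table column order
    new_site_partition(s, table$patient_id, table[cols])
  })
  names(out) <- plan$site_ids
  out
}

#' Plan a horizontal (row-wise) blocking of a cohort
#'
#' Divide-and-conquer blocking: row blocks are half-open, 0-based index
#' ranges that must be contiguous, disjoint, and cover all rows. All sites
#' apply the identical plan so blocks stay row-aligned.
#'
#' @param boundaries list of integer pairs `c(start, end)` (half-open, 0-based).
#' @param n_rows total number of rows the plan must cover.
#' @return an object of class `block_plan`.
#' @export
block_plan <- function(boundaries, n_rows) {
  b <- lapply(boundaries, function(r) as.integer(r))
  if (!length(b)) vdra_error("vdra_plan_error", "block plan is empty")
  if (any(vapply(b, length, 1L) != 2L))
    vdra_error("vdra_plan_error", "each block boundary must be a (start, end) pair")
  starts <- vapply(b, `[`, 1L, 1L); ends <- vapply(b, `[`, 1L, 2L)
  if (any(ends <= starts))
    vdra_error("vdra_plan_error", "empty or inverted block range")
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (starts[1L] != 0L || ends[length(ends)] != n_rows ||
      (length(b) > 1L && any(starts[-1L] != ends[-length(ends)])))
    vdra_error("vdra_plan_error",
      "block ranges must be contiguous, disjoint, and cover [0, n_rows)")
  structure(list(boundaries = Map(c, starts, ends), n_rows = as.integer(n_rows)),
            class = "block_plan")
}

#' Slice one site's partition into row blocks
#'
#' @param partition a `site_partition`.
#' @param plan a [block_plan()] for the partition's row count.
#' @return list of `site_partition` objects, one per block, in row order;
#'   row-wise concatenation restores the input.
#' @export
partition_blocks <- function(partition, plan) {
  stopifnot(inherits(partition, "site_partition"), inherits(plan, "block_plan"))
  if (plan$n_rows != partition$n)
    vdra_error("vdra_plan_error", "block plan does not cover the partition's rows")
  lapply(plan$boundaries, function(r) {
    idx <- seq.int(r[1L] + 1L, r[2L])
    new_site_partition(partition$site_id, partition$patient_id[idx],
                       partition$data[idx, , drop = FALSE])
  })
}

#' Write / read a site partition as CSV
#'
#' RFC-4180 CSV with a header row and `patient_id` as the first column.
#' `read_partition` restores canonical row order by sorting on patient ID and
#' rejects duplicate IDs and missing values.
#'
#' @param partition a `site_partition`.
#' @param path CSV file path.
#' @param site_id site identifier to attach on read (defaults to the file
#'   name without extension).
#' @return `read_partition` returns a `site_partition`; `write_partition`
#'   returns `path` invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "site_partition"))
  df <- cbind(data.frame(patient_id = partition$patient_id), partition$data)
  data.table::fwrite(df, path, col.names = TRUE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, site_id = NULL) {
  df <- as.data.frame(data.table::fread(path))
  if (!"patient_id" %in% names(df) || names(df)[1L] != "patient_id")
    vdra_error("vdra_format_error", "patient_id must be the first CSV column")
  if (anyDuplicated(df$patient_id))
    vdra_error("vdra_format_error", "duplicate patient_id values in file")
  if (anyNA(df))
    vdra_error("vdra_format_error", "missing values in partition file")
  df <- df[order(df$patient_id), , drop = FALSE]
  rownames(df) <- NULL
  new_site_partition(site_id %||% sub("\\.[^.]*$", "", basename(path)),
                     df$patient_id, df[setdiff(names(df), "patient_id")])
}

# assert that all partitions of one cohort agree on the patient_id sequence
check_row_alignment <- function(sites) {
  ids <- sites[[1L]]$patient_id
  for (s in sites[-1L]) {
    if (!identical(s$patient_id, ids))
      vdra_error("vdra_alignment_error", sprintf(
        "site '%s' rows are not aligned with site '%s'",
        s$site_id, sites[[1L]]$site_id))
  }
  invisible(TRUE)
}
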