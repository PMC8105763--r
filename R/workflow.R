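# global layout of a vertically partitioned cohort: which site holds the
# outcome, and the global covariate order (sites in list order, columns in
# each site's declared order); the intercept is owned by the analysis center
site_layout <- function(sites, outcome) {
  holders <- names(sites)[vapply(sites, function(s)
    outcome %in% names(s$data), logical(1))]
  if (length(holders) != 1L)
    vdra_error("vdra_plan_error", sprintf(
      "outcome '%s' must live at exactly one site (found at %d)",
      outcome, length(holders)))
  site_columns <- lapply(sites, function(s) setdiff(names(s$data), outcome))
  covariates <- unlist(site_columns, use.names = FALSE)
  if (anyDuplicated(covariates))
    vdra_error("vdra_plan_error", "covariate held by more than one site")
  list(outcome_site = holders, site_columns = site_columns,
       covariates = covariates,
       cov_sites = names(sites)[vapply(site_columns, length, 1L) > 0L])
}

# compute all diagonal and cross-site Gram blocks plus column sums, optionally
# weighted, optionally block-wise (divide and conquer), optionally through the
# audited transfer fabric; returns summed blocks keyed implicitly by dimnames
aggregate_gram <- function(sites, site_columns, weights = NULL, g = NULL,
                           seed = 1L, network = NULL, block_plan = NULL,
                           label = "gram") {
  n <- sites[[1L]]$n
  if (!is.null(block_plan)) {
    site_blocks <- lapply(sites, partition_blocks, plan = block_plan)
    pieces <- lapply(seq_along(block_plan$boundaries), function(b) {
      r <- block_plan$boundaries[[b]]
      idx <- seq.int(r[1L] + 1L, r[2L])
      aggregate_gram(lapply(site_blocks, `[[`, b), site_columns,
                     weights = if (is.null(weights)) NULL else weights[idx],
                     g = g, seed = child_seed(seed, "block", b),
                     network = network, block_plan = NULL,
                     label = sprintf("%s-b%d", label, b))
    })
    blocks <- pieces[[1L]]$blocks
    for (k in seq_along(blocks))
      for (pc in pieces[-1L])
        blocks[[k]]$block <- blocks[[k]]$block + pc$blocks[[k]]$block
    for (k in seq_along(blocks))
      blocks[[k]]$n_rows <- n
    return(list(
      blocks = blocks,
      column_sums = Reduce(`+`, lapply(pieces, `[[`, "column_sums")),
      n0 = sum(vapply(pieces, `[[`, numeric(1), "n0"))))
  }
  active <- names(sites)[vapply(site_columns, length, 1L) > 0L]
  blocks <- list()
  column_sums <- numeric(0)
  for (s in active) {
    cols <- site_columns[[s]]
    blk <- gram_self(sites[[s]], cols, weights = weights)
    X <- partition_matrix(sites[[s]], cols)
    cs <- if (is.null(weights)) colSums(X) else colSums(X * weights)
    names(cs) <- cols
    if (!is.null(network)) {
      # one manifest carrying both summaries: a multi-file batch
      out <- outbox(network, s)
      files <- c(
        write_payload(blk$block, out, sprintf("%s-self-%s", label, s), s,
                      "gram-block"),
        write_payload(rbind(cs), out, sprintf("%s-sums-%s", label, s), s,
                      "column-sums"))
      route(network, s, center_id(network), files)
    }
    blocks[[length(blocks) + 1L]] <- blk
    column_sums <- c(column_sums, cs)
  }
  if (length(active) > 1L) {
    for (i in seq_len(length(active) - 1L)) {
      for (j in seq.int(i + 1L, length(active))) {
        a <- active[i]; b <- active[j]
        blk <- secure_cross_product(
          sites[[a]], sites[[b]], g = g,
          seed = child_seed(seed, "pair", a, b),
          columns_a = site_columns[[a]], columns_b = site_columns[[b]],
          weights = weights, network = network,
          label = sprintf("%s-%s-%s", label, a, b))
        if (!is.null(network))
          send_block(network, a, center_id(network), blk,
                     sprintf("%s-cross-%s-%s", label, a, b))
        blocks[[length(blocks) + 1L]] <- blk
      }
    }
  }
  list(blocks = blocks, column_sums = column_sums,
       n0 = if (is.null(weights)) n else sum(weights))
}

# split augmented blocks (covariates + outcome column) into covariate-only
# blocks, per-covariate X'y entries, and y'y
split_outcome_blocks <- function(blocks, covariates, outcome) {
  cov_blocks <- list()
  y_vec <- numeric(0)
  yty <- NA_real_
  for (b in blocks) {
    ri <- rownames(b$block); ci <- colnames(b$block)
    rc <- intersect(ri, covariates); cc <- intersect(ci, covariates)
    if (length(rc) && length(cc))
      cov_blocks[[length(cov_blocks) + 1L]] <-
        new_gram_block(b$site_i, b$site_j,
                       b$block[rc, cc, drop = FALSE], b$n_rows)
    if (outcome %in% ci && length(rc)) {
      v <- b$block[rc, outcome]
      y_vec <- c(y_vec, setNames(v, rc))
    }
    if (outcome %in% ri && length(cc)) {
      v <- b$block[outcome, cc]
      y_vec <- c(y_vec, setNames(v, cc))
    }
    if (outcome %in% ri && outcome %in% ci)
      yty <- b$block[outcome, outcome]
  }
  list(cov_blocks = cov_blocks, y_vec = y_vec[!duplicated(names(y_vec))],
       yty = yty)
}

#' Fit a regression model across vertically partitioned sites
#'
#' The central fitting function: given one cohort's column-wise partitions,
#' computes the distributed fit without ever pooling patient-level columns.
#' Sites compute their own Gram blocks; cross-site blocks come from the
#' sequential secure masking protocol; the analysis center assembles the
#' global covariance matrix and solves the (iteratively reweighted, for
#' logistic) normal equations. With a `network`, every inter-party message
#' travels as files through the audited, trust-governed transfer fabric.
#'
#' @param sites named list of row-aligned `site_partition`s (e.g. from
#'   [partition_vertical()]).
#' @param outcome outcome column name (held by exactly one site).
#' @param model `"linear"` or `"logistic"`.
#' @param conv a [convergence_spec()] (logistic only).
#' @param g mask dimension for the secure protocol; default
#'   `floor((n - p_a)/2)` per exchange.
#' @param seed integer seed driving all protocol randomness.
#' @param network optional `vdra_network` carrying the messages.
#' @param block_plan optional [block_plan()] for divide-and-conquer row
#'   blocking.
#' @param beta_start starting coefficients for the logistic iteration
#'   (default all zeros).
#' @return an object of class `vdra_fit`.
#' @examples
#' spec <- cohort_spec(200, list(
#'   list(name = "surgery", kind = "binary", prob = 0.4),
#'   list(name = "sex", kind = "binary", prob = 0.5),
#'   list(name = "race", kind = "binary", prob = 0.3)),
#'   outcome_model = "linear", true_beta = c(25, -1.5, 0.5, 1),
#'   noise_sd = 2, outcome_name = "bmi", seed = 7)
#' tab <- generate_cohort(spec)
#' plan <- partition_plan(
#'   c(surgery = "site1", sex = "site1", race = "site1", bmi = "site2"),
#'   outcome_site = "site2", outcome_name = "bmi")
#' sites <- partition_vertical(tab, plan)
#' fit <- fit_distributed(sites, outcome = "bmi", seed = 7)
#' summary(fit)
#' @export
fit_distributed <- function(sites, outcome, model = c("linear", "logistic"),
                            conv = convergence_spec(), g = NULL, seed = 1L,
                            network = NULL, block_plan = NULL,
                            beta_start = NULL) {
  model <- match.arg(model)
  check_row_alignment(sites)
  if (model == "logistic")
    return(fit_logistic_distributed(sites, outcome, conv = conv, g = g,
                                    seed = seed, network = network,
                                    block_plan = block_plan,
                                    beta_start = beta_start))
  lay <- site_layout(sites, outcome)
  cols_aug <- lay$site_columns
  cols_aug[[lay$outcome_site]] <- c(cols_aug[[lay$outcome_site]], outcome)
  agg <- aggregate_gram(sites, cols_aug, g = g, seed = seed,
                        network = network, block_plan = block_plan)
  sp <- split_outcome_blocks(agg$blocks, lay$covariates, outcome)
  gram <- assemble_global_gram(
    sp$cov_blocks, lay$covariates, n = sites[[1L]]$n,
    column_sums = agg$column_sums[lay$covariates],
    y_blocks = sp$y_vec, sum_y = agg$column_sums[[outcome]], yty = sp$yty)
  fit_linear_distributed(gram)
}

#' Run the full distributed-regression workflow over a transfer network
#'
#' End-to-end execution of the automatable workflow: site-local blocks and
#' column sums are uploaded (as multi-file batches), cross-site blocks run
#' through the sequential secure protocol routed per the network's mode
#' (direct or hub-and-spoke), the analysis center assembles and fits, and
#' the run's transfer metrics and audit trail are returned with the result.
#' Any trust violation terminates the run and propagates.
#'
#' @inheritParams fit_distributed
#' @param network a `vdra_network` (required here).
#' @return an object of class `vdra_run`: list with `result` (a
#'   `vdra_fit`), `metrics` ([transfer_metrics()]), `audit`
#'   ([audit_log()]), and the `network`.
#' @export
run_vdra_workflow <- function(network, sites, outcome,
                              model = c("linear", "logistic"),
                              conv = convergence_spec(), g = NULL, seed = 1L,
                              block_plan = NULL) {
  stopifnot(inherits(network, "vdra_network"))
  result <- fit_distributed(sites, outcome, model = model, conv = conv,
                            g = g, seed = seed, network = network,
                            block_plan = block_plan)
  structure(list(result = result, metrics = transfer_metrics(network),
                 audit = audit_log(network), network = network),
            class = "vdra_run")
}

#' @export
print.vdra_run <- function(x, ...) {
  cat(sprintf("<vdra_run> %s routing: %d legs, %.0f bytes, %d site-site exchange(s)\n",
              x$network$routing, x$metrics$legs, x$metrics$bytes,
              x$metrics$site_exchanges))
  print(x$result)
  invisible(x)
}
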