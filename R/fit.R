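#' Assemble the global covariance matrix from site blocks
#'
#' The analysis center aggregates the intermediate statistics: site-local
#' Gram blocks go on the diagonal, secure cross-site blocks off the diagonal
#' (and their transposes), and the intercept row/column is built from `n` and
#' the per-site column sums — no site ever owns an intercept column. The
#' outcome enters through per-site `X_k' y` blocks, `sum(y)` and `y'y`, all
#' of which the outcome site computes (directly or via the secure protocol).
#'
#' @param blocks list of `gram_block`s covering every diagonal and every
#'   unordered site pair once; entries are placed by the column names on
#'   each block.
#' @param column_order global covariate order (intercept excluded — it is
#'   prepended automatically).
#' @param n number of patients.
#' @param column_sums named vector of column sums over all covariates.
#' @param y_blocks named vector (or list of per-site named vectors) of
#'   `X' y` entries covering every covariate.
#' @param sum_y sum of the outcome.
#' @param yty sum of squared outcome.
#' @return an object of class `global_gram` with elements `column_order`
#'   (intercept first), `G`, `Xty`, `yty`, `n`.
#' @export
assemble_global_gram <- function(blocks, column_order, n, column_sums,
                                 y_blocks, sum_y, yty) {
  full <- build_full_gram(blocks, column_order, n, column_sums)
  if (is.list(y_blocks)) y_blocks <- do.call(c, unname(y_blocks))
  if (!all(column_order %in% names(y_blocks)))
    vdra_error("vdra_incomplete_error", "X'y blocks do not cover all covariates")
  nm <- c("(Intercept)", column_order)
  Xty <- setNames(c(sum_y, y_blocks[column_order]), nm)
  structure(list(column_order = nm, G = full, Xty = Xty,
                 yty = as.numeric(yty), n = as.integer(n)),
            class = "global_gram")
}

# place named blocks into the p x p covariate Gram, then border with the
# intercept row/column built from n0 (row count, or sum of weights) and the
# (possibly weighted) column sums
build_full_gram <- function(blocks, column_order, n0, column_sums) {
  p <- length(column_order)
  G <- matrix(NA_real_, p, p, dimnames = list(column_order, column_order))
  for (b in blocks) {
    stopifnot(inherits(b, "gram_block"))
    ri <- rownames(b$block); ci <- colnames(b$block)
    if (length(ri) == 0L || length(ci) == 0L) next
    if (is.null(ri) || is.null(ci) || !all(ri %in% column_order) ||
        !all(ci %in% column_order))
      vdra_error("vdra_assembly_error", sprintf(
        "block (%s, %s) has columns outside the global order", b$site_i, b$site_j))
    G[ri, ci] <- b$block
    G[ci, ri] <- t(b$block)
  }
  if (anyNA(G)) {
    bad <- which(is.na(G), arr.ind = TRUE)[1L, ]
    vdra_error("vdra_incomplete_error", sprintf(
      "missing Gram block covering columns ('%s', '%s')",
      column_order[bad[1L]], column_order[bad[2L]]))
  }
  if (!all(column_order %in% names(column_sums)))
    vdra_error("vdra_incomplete_error", "column sums do not cover all covariates")
  cs <- column_sums[column_order]
  full <- rbind(c(n0, cs), cbind(cs, G))
  nm <- c("(Intercept)", column_order)
  dimnames(full) <- list(nm, nm)
  full
}

# build an augmented global_gram directly from pooled data (test/oracle path)
global_gram_pooled <- function(table, covariates, outcome) {
  X <- as.matrix(table[covariates])
  y <- table[[outcome]]
  A <- cbind(`(Intercept)` = 1, X)
  structure(list(column_order = colnames(A), G = crossprod(A),
                 Xty = drop(crossprod(A, y)), yty = sum(y * y),
                 n = nrow(X)), class = "global_gram")
}

new_vdra_fit <- function(model, beta, se, cov_beta, fit, n, p, converged = TRUE,
                         n_iter = 0L, termination_reason = "converged",
                         source = "distributed") {
  structure(list(
    model = model, coefficients = beta, se = se, cov_beta = cov_beta,
    fit = fit, n = n, p = p, converged = converged, n_iter = n_iter,
    termination_reason = termination_reason, source = source,
    column_order = names(beta)
  ), class = "vdra_fit")
}

solve_spd <- function(G, rhs, kappa_max = 1e12) {
  kap <- kappa(G, exact = TRUE)
  if (!is.finite(kap) || kap > kappa_max)
    vdra_error("vdra_collinearity_error", sprintf(
      "global covariance matrix is (near-)singular: condition number %.3g", kap))
  R <- chol(G)
  list(x = backsolve(R, forwardsolve(t(R), rhs)), Ginv = chol2inv(R))
}

#' Fit the linear model at the analysis center from summary statistics alone
#'
#' Solves the normal equations `G beta = X'y` built from the assembled global
#' covariance matrix. Everything — coefficients, residual variance
#' `sigma^2 = (y'y - 2 beta'X'y + beta'G beta)/(n - p - 1)`, the coefficient
#' covariance `sigma^2 G^{-1}`, and R-squared — is computed from
#' `{G, X'y, y'y, n}`; no patient-level data is touched.
#'
#' @param gram a [global_gram][assemble_global_gram] (intercept included).
#' @param kappa_max condition-number threshold above which the fit aborts
#'   with a collinearity error.
#' @return an object of class `vdra_fit`.
#' @export
fit_linear_distributed <- function(gram, kappa_max = 1e12) {
  stopifnot(inherits(gram, "global_gram"))
  n <- gram$n; p <- length(gram$column_order) - 1L
  sol <- solve_spd(gram$G, gram$Xty, kappa_max)
  beta <- setNames(drop(sol$x), gram$column_order)
  sse <- max(0, gram$yty - 2 * sum(beta * gram$Xty) +
               drop(crossprod(beta, gram$G %*% beta)))
  sigma2 <- sse / (n - p - 1L)
  cov_beta <- sigma2 * sol$Ginv
  dimnames(cov_beta) <- list(gram$column_order, gram$column_order)
  sst <- gram$yty - gram$Xty[["(Intercept)"]]^2 / n
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  new_vdra_fit("linear", beta, setNames(sqrt(diag(cov_beta)), gram$column_order),
               cov_beta,
               fit = list(sigma2 = sigma2, r_squared = r2,
                          adj_r_squared = if (is.na(r2)) NA_real_ else
                            1 - (1 - r2) * (n - 1) / (n - p - 1)),
               n = n, p = p)
}

#' Decide whether the iterative loop should stop
#'
#' Applies the prespecified convergence criterion: either the maximum
#' absolute coefficient change or the relative deviance change, compared to
#' `tol` with strict inequality; the iteration cap wins over non-convergence.
#'
#' @param state_prev,state_new lists with elements `beta` and (for the
#'   deviance criterion) `deviance`; `state_new` also carries `iter_index`.
#' @param conv a [convergence_spec()].
#' @return one of `"continue"`, `"converged"`, `"max-iter-reached"`.
#' @export
convergence_check <- function(state_prev, state_new, conv) {
  if (length(state_prev$beta) != length(state_new$beta))
    vdra_error("vdra_dimension_error", "coefficient vectors are not comparable")
  delta <- switch(conv$criterion,
    "max-abs-delta-beta" = max(abs(state_new$beta - state_prev$beta)),
    "relative-deviance-change" =
      abs(state_new$deviance - state_prev$deviance) /
        (abs(state_prev$deviance) + 0.1))
  if (delta < conv$tol) return("converged")
  if (state_new$iter_index >= conv$max_iter) return("max-iter-reached")
  "continue"
}

#' Convergence specification for iterative distributed fits
#'
#' @param tol positive convergence tolerance (strict inequality at the
#'   boundary: a change exactly equal to `tol` continues).
#' @param max_iter iteration cap.
#' @param criterion `"max-abs-delta-beta"` or `"relative-deviance-change"`.
#' @return an object of class `convergence_spec`.
#' @export
convergence_spec <- function(tol = 1e-8, max_iter = 25L,
                             criterion = c("max-abs-delta-beta",
                                           "relative-deviance-change")) {
  criterion <- match.arg(criterion)
  if (tol <= 0) vdra_error("vdra_spec_error", "tol must be positive")
  if (max_iter < 1L) vdra_error("vdra_spec_error", "max_iter must be >= 1")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 criterion = criterion), class = "convergence_spec")
}

#' Distributed logistic regression by iteratively reweighted least squares
#'
#' Runs the iterative two-process loop: each site sends its partial linear
#' predictor `eta_k = X_k beta_k` (an n-vector) to the analysis center; the
#' center forms the full predictor, computes `mu = expit(eta)` and IRLS
#' weights `w = mu(1 - mu)`, and sends `eta, mu, w` to the outcome site,
#' which alone holds `y` and computes the working response
#' `z = eta + (y - mu)/w` and the deviance. The weighted global Gram over
#' the covariates and `z` is then rebuilt — diagonal blocks locally, cross-
#' site blocks via the secure weighted protocol — and the center solves the
#' weighted normal equations. The loop ends when the prespecified criterion
#' is met or the iteration cap is reached; `cov_beta = (X'WX)^{-1}` at the
#' final iterate.
#'
#' @param sites named list of row-aligned `site_partition`s.
#' @param outcome name of the binary outcome column (must live at exactly
#'   one site).
#' @param conv a [convergence_spec()].
#' @param g mask dimension for the secure protocol (default
#'   `floor((n - p_a)/2)` per exchange).
#' @param seed integer seed; per-iteration, per-pair protocol seeds are
#'   derived from it.
#' @param network optional `vdra_network`; when supplied every inter-party
#'   message (partial predictors, weights, protocol payloads, blocks)
#'   travels through the audited transfer fabric.
#' @param beta_start optional starting coefficients (default all zeros).
#' @param block_plan optional [block_plan()]: cross-products are computed
#'   block-wise and summed (divide-and-conquer).
#' @return an object of class `vdra_fit` with a convergence record.
#' @export
fit_logistic_distributed <- function(sites, outcome, conv = convergence_spec(),
                                     g = NULL, seed = 1L, network = NULL,
                                     beta_start = NULL, block_plan = NULL) {
  check_row_alignment(sites)
  lay <- site_layout(sites, outcome)
  y <- sites[[lay$outcome_site]]$data[[outcome]]
  if (!all(y %in% c(0, 1)))
    vdra_error("vdra_domain_error", "logistic outcome must be binary 0/1")
  n <- length(y); p <- length(lay$covariates)
  nm <- c("(Intercept)", lay$covariates)
  beta <- beta_start %||% setNames(numeric(p + 1L), nm)

  # one IRLS round at the current beta: sites share partial predictors, the
  # center forms mu and w, the outcome site forms the working response, and
  # the weighted global Gram over (covariates, z) is rebuilt
  irls_round <- function(beta, tag) {
    eta <- rep(beta[["(Intercept)"]], n)
    for (s in lay$cov_sites) {
      cols <- lay$site_columns[[s]]
      eta_k <- drop(partition_matrix(sites[[s]], cols) %*% beta[cols])
      if (!is.null(network))
        send_vector(network, s, center_id(network), eta_k,
                    sprintf("eta-%s-%s", s, tag), "partial-predictor")
      eta <- eta + eta_k
    }
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < .Machine$double.eps) || any(!is.finite(beta)))
      vdra_error("vdra_separation_error",
        "weights underflow: (quasi-)complete separation suspected")
    if (!is.null(network))
      send_vector(network, center_id(network), lay$outcome_site,
                  cbind(eta, mu, w), sprintf("irls-state-%s", tag),
                  "irls-state")
    z <- eta + (y - mu) / w
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    zsite <- sites[[lay$outcome_site]]
    zsite$data[[".z"]] <- z
    sites_z <- sites
    sites_z[[lay$outcome_site]] <- zsite
    cols_z <- lay$site_columns
    cols_z[[lay$outcome_site]] <- c(cols_z[[lay$outcome_site]], ".z")
    agg <- aggregate_gram(sites_z, cols_z, weights = w, g = g,
                          seed = child_seed(seed, "irls", tag),
                          network = network, block_plan = block_plan,
                          label = tag)
    full <- build_full_gram(agg$blocks, c(lay$covariates, ".z"),
                            n0 = agg$n0, column_sums = agg$column_sums)
    list(Gw = full[nm, nm], rhs = full[nm, ".z"], deviance = dev)
  }

  state <- list(beta = beta, deviance = Inf, iter_index = 0L)
  repeat {
    it <- state$iter_index + 1L
    rd <- irls_round(beta, sprintf("it%d", it))
    beta_new <- setNames(drop(solve_spd(rd$Gw, rd$rhs)$x), nm)
    new_state <- list(beta = beta_new, deviance = rd$deviance, iter_index = it)
    status <- convergence_check(state, new_state, conv)
    state <- new_state
    beta <- beta_new
    if (status != "continue") break
  }
  # covariance (X'WX)^{-1} and deviance are evaluated at the final iterate
  rd <- irls_round(beta, "final")
  cov_beta <- solve_spd(rd$Gw, diag(p + 1L))$Ginv
  dimnames(cov_beta) <- list(nm, nm)
  new_vdra_fit("logistic", beta, setNames(sqrt(diag(cov_beta)), nm), cov_beta,
               fit = list(deviance = rd$deviance,
                          aic = rd$deviance + 2 * (p + 1L)),
               n = n, p = p,
               converged = status == "converged", n_iter = state$iter_index,
               termination_reason = status)
}

#' Pooled patient-level oracle fit
#'
#' The verification standard: an ordinary least-squares or maximum-likelihood
#' logistic fit on the physically pooled patient-level table, using the
#' standard in-memory routines. Distributed results are required to match
#' this oracle (linear: within 1e-12; logistic: within 1e-8 after
#' convergence).
#'
#' @param table pooled patient-level `data.frame`.
#' @param model `"linear"` or `"logistic"`.
#' @param covariates covariate column names, in the global order of the
#'   distributed fit.
#' @param outcome outcome column name.
#' @return an object of class `vdra_fit` (source `"pooled-oracle"`).
#' @export
pooled_oracle_fit <- function(table, model = c("linear", "logistic"),
                              covariates, outcome) {
  model <- match.arg(model)
  fml <- stats::reformulate(sprintf("`%s`", covariates),
                            response = sprintf("`%s`", outcome))
  if (model == "linear") {
    f <- stats::lm(fml, data = table)
    sm <- summary(f)
    cov_beta <- vcov(f)
    fit <- list(sigma2 = sm$sigma^2, r_squared = sm$r.squared,
                adj_r_squared = sm$adj.r.squared)
    conv <- list(converged = TRUE, n_iter = 0L, reason = "converged")
  } else {
    f <- stats::glm(fml, data = table, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 50))
    # model-based covariance (X'WX)^{-1} evaluated at the MLE itself (glm's
    # vcov uses the weights of its penultimate iterate)
    X <- stats::model.matrix(f)
    mu <- f$fitted.values
    cov_beta <- chol2inv(chol(crossprod(X, X * (mu * (1 - mu)))))
    fit <- list(deviance = f$deviance, aic = f$aic)
    conv <- list(converged = f$converged, n_iter = f$iter,
                 reason = if (f$converged) "converged" else "max-iter-reached")
  }
  nm <- c("(Intercept)", covariates)
  beta <- setNames(coef(f), nm)
  dimnames(cov_beta) <- list(nm, nm)
  new_vdra_fit(model, beta, setNames(sqrt(diag(cov_beta)), nm), cov_beta, fit,
               n = nrow(table), p = length(covariates),
               converged = conv$converged, n_iter = conv$n_iter,
               termination_reason = conv$reason, source = "pooled-oracle")
}

#' Compare two regression results coordinate by coordinate
#'
#' Reports element-wise maximum absolute differences in coefficients,
#' standard errors and shared fit statistics, with pass/fail against a
#' stated tolerance. The operational form of the equivalence standard: a
#' distributed fit is accepted when it matches the pooled oracle below
#' 1e-12 (linear) or 1e-8 (logistic, after convergence).
#'
#' @param a,b `vdra_fit` objects with the same model and column order.
#' @param tol acceptance tolerance for the maximum difference.
#' @return list of class `vdra_comparison`: per-quantity max differences,
#'   `max_diff`, `pass`, and the name of the worst coordinate.
#' @export
compare_results <- function(a, b, tol = 1e-12) {
  stopifnot(inherits(a, "vdra_fit"), inherits(b, "vdra_fit"))
  if (!identical(a$model, b$model))
    vdra_error("vdra_comparison_error", "results fit different model types")
  if (!identical(a$column_order, b$column_order))
    vdra_error("vdra_comparison_error", "column orders differ; not comparable")
  d_beta <- abs(a$coefficients - b$coefficients)
  d_se <- abs(a$se - b$se)
  shared <- intersect(names(a$fit), names(b$fit))
  d_fit <- vapply(shared, function(k)
    abs(a$fit[[k]] - b$fit[[k]]), numeric(1))
  worst <- which.max(c(d_beta, d_se))
  worst_name <- c(paste0("beta:", names(d_beta)),
                  paste0("se:", names(d_se)))[worst]
  md <- max(d_beta, d_se)
  structure(list(
    beta_max_diff = max(d_beta), se_max_diff = max(d_se),
    fit_diffs = as.list(d_fit), max_diff = md, tol = tol,
    pass = md <= tol, worst_coordinate = worst_name
  ), class = "vdra_comparison")
}

#' @export
print.vdra_comparison <- function(x, ...) {
  cat(sprintf("Regression-result comparison (tol = %g): %s\n", x$tol,
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  max |delta beta| = %.3g   max |delta se| = %.3g\n",
              x$beta_max_diff, x$se_max_diff))
  if (!x$pass)
    cat(sprintf("  worst coordinate: %s\n", x$worst_coordinate))
  invisible(x)
}

# ---- vdra_fit methods -------------------------------------------------------

#' @export
print.vdra_fit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat(sprintf("Distributed %s regression (%s), n = %d, p = %d\n",
              x$model, x$source, x$n, x$p))
  if (x$model == "logistic")
    cat(sprintf("  %s after %d iteration(s)\n", x$termination_reason, x$n_iter))
  cat("\nCoefficients:\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.vdra_fit <- function(object, ...) object$coefficients

#' @export
vcov.vdra_fit <- function(object, ...) object$cov_beta

#' Summarize a distributed regression fit
#'
#' @param object a `vdra_fit`.
#' @param ... unused.
#' @return a `summary.vdra_fit` with a coefficient table (estimate, standard
#'   error, t or z statistic, two-sided p value) and fit statistics.
#' @export
summary.vdra_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  stat <- est / se
  if (object$model == "linear") {
    df <- object$n - object$p - 1L
    pval <- 2 * pt(abs(stat), df, lower.tail = FALSE)
    statname <- "t value"
  } else {
    pval <- 2 * pnorm(abs(stat), lower.tail = FALSE)
    statname <- "z value"
  }
  tab <- cbind(Estimate = est, `Std. Error` = se, stat, `Pr(>|stat|)` = pval)
  colnames(tab)[3L] <- statname
  structure(list(model = object$model, source = object$source,
                 coefficients = tab, fit = object$fit, n = object$n,
                 p = object$p, converged = object$converged,
                 n_iter = object$n_iter,
                 termination_reason = object$termination_reason),
            class = "summary.vdra_fit")
}

#' @export
print.summary.vdra_fit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat(sprintf("Distributed %s regression (%s), n = %d\n\n", x$model, x$source, x$n))
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\n")
  if (x$model == "linear")
    cat(sprintf("Residual variance: %.6g   R-squared: %.4f (adj. %.4f)\n",
                x$fit$sigma2, x$fit$r_squared, x$fit$adj_r_squared))
  else
    cat(sprintf("Deviance: %.4f   AIC: %.4f   (%s in %d iterations)\n",
                x$fit$deviance, x$fit$aic, x$termination_reason, x$n_iter))
  invisible(x)
}

#' @export
confint.vdra_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  if (missing(parm)) parm <- names(est)
  a <- (1 - level) / 2
  q <- if (object$model == "linear")
    qt(1 - a, object$n - object$p - 1L) else qnorm(1 - a)
  out <- cbind(est[parm] - q * object$se[parm], est[parm] + q * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  out
}

#' @export
predict.vdra_fit <- function(object, newdata,
                             type = c("link", "response"), ...) {
  type <- match.arg(type)
  covs <- setdiff(object$column_order, "(Intercept)")
  X <- cbind(1, as.matrix(newdata[covs]))
  eta <- drop(X %*% object$coefficients)
  if (object$model == "logistic" && type == "response") plogis(eta) else eta
}
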