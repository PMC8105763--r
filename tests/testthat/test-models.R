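test_that("global Gram assembly matches the pooled cross-product", {
  fx <- make_linear_fixture(n = 40, p = 3, split = c(2, 1))
  lay <- vdra:::site_layout(fx$sites, "y")
  cols_aug <- lay$site_columns
  cols_aug$site2 <- c(cols_aug$site2, "y")
  agg <- vdra:::aggregate_gram(fx$sites, cols_aug, seed = 2)
  sp <- vdra:::split_outcome_blocks(agg$blocks, fx$covariates, "y")
  gram <- assemble_global_gram(sp$cov_blocks, fx$covariates, n = 40,
                               column_sums = agg$column_sums[fx$covariates],
                               y_blocks = sp$y_vec,
                               sum_y = agg$column_sums[["y"]], yty = sp$yty)
  A <- cbind(1, as.matrix(fx$tab[fx$covariates]))
  expect_lte(max(abs(gram$G - crossprod(A))), 1e-9)
  expect_lte(max(abs(gram$Xty - drop(crossprod(A, fx$tab$y)))), 1e-9)
  expect_equal(gram$G[1, 1], 40)
  expect_equal(gram$yty, sum(fx$tab$y^2))

  # Fig-2 shape: 3 covariates at site 1, outcome at site 2 -> 5x5 with intercept
  spec <- cohort_spec(30, list(list(name = "surgery", kind = "binary"),
                               list(name = "sex", kind = "binary"),
                               list(name = "race", kind = "binary")),
                      outcome_model = "linear", true_beta = c(25, -1, 1, 0.5),
                      noise_sd = 2, outcome_name = "bmi", seed = 4)
  tab2 <- generate_cohort(spec)
  sites2 <- partition_vertical(tab2, partition_plan(
    c(surgery = "site1", sex = "site1", race = "site1", bmi = "site2"),
    outcome_site = "site2", outcome_name = "bmi"))
  lay2 <- vdra:::site_layout(sites2, "bmi")
  agg2 <- vdra:::aggregate_gram(sites2, list(site1 = lay2$site_columns$site1,
                                             site2 = "bmi"), seed = 2)
  sp2 <- vdra:::split_outcome_blocks(agg2$blocks, lay2$covariates, "bmi")
  gram2 <- assemble_global_gram(sp2$cov_blocks, lay2$covariates, 30,
                                agg2$column_sums[lay2$covariates],
                                sp2$y_vec, agg2$column_sums[["bmi"]], sp2$yty)
  expect_identical(dim(gram2$G), c(4L, 4L))
  expect_identical(length(gram2$Xty) + 1L, 5L)

  # missing block is named
  expect_error(assemble_global_gram(sp$cov_blocks[-1], fx$covariates, 40,
                                    agg$column_sums[fx$covariates],
                                    sp$y_vec, agg$column_sums[["y"]], sp$yty),
               class = "vdra_incomplete_error")
})

test_that("single-site degenerate assembly reduces to the pooled Gram", {
  fx <- make_linear_fixture(n = 25, p = 2)
  pooled <- vdra:::new_site_partition("solo", fx$tab$patient_id,
                                      fx$tab[c("x1", "x2")])
  blocks <- list(gram_self(pooled))
  X <- as.matrix(fx$tab[c("x1", "x2")])
  gram <- assemble_global_gram(blocks, c("x1", "x2"), 25, colSums(X),
                               drop(crossprod(X, fx$tab$y)),
                               sum(fx$tab$y), sum(fx$tab$y^2))
  expect_equal(gram$G, crossprod(cbind(`(Intercept)` = 1, X)))
})

test_that("distributed linear fit is exact on noiseless data and flags collinearity", {
  spec <- cohort_spec(30, list(list(name = "x", kind = "continuous")),
                      outcome_model = "linear", true_beta = c(0, 2),
                      noise_sd = 0, seed = 6)
  tab <- generate_cohort(spec)
  sites <- partition_vertical(tab, partition_plan(
    c(x = "s1", y = "s2"), "s2", site_ids = c("s1", "s2")))
  f <- fit_distributed(sites, "y", seed = 1)
  expect_equal(unname(coef(f)), c(0, 2), tolerance = 1e-10)
  expect_lt(f$fit$sigma2, 1e-10)

  # a covariate duplicated across sites makes G singular
  tab2 <- tab; tab2$x2 <- tab$x
  sites2 <- partition_vertical(tab2, partition_plan(
    c(x = "s1", x2 = "s2", y = "s2"), "s2"))
  expect_error(fit_distributed(sites2, "y", seed = 1),
               class = "vdra_collinearity_error")
})

test_that("distributed linear fit matches the pooled oracle below 1e-12", {
  for (sd in c(123, 456)) {
    fx <- make_linear_fixture(n = 500, p = 6, seed = sd, split = c(3, 3))
    f <- fit_distributed(fx$sites, "y", seed = sd)
    o <- pooled_oracle_fit(fx$tab, "linear", fx$covariates, "y")
    cmp <- compare_results(f, o, tol = 1e-12)
    expect_true(cmp$pass)
    expect_lte(abs(f$fit$sigma2 - o$fit$sigma2), 1e-10)
    expect_lte(abs(f$fit$r_squared - o$fit$r_squared), 1e-12)
  }
})

test_that("convergence decisions use strict inequality and the iteration cap", {
  conv <- convergence_spec(tol = 1e-8, max_iter = 10)
  st <- function(beta, it, dev = 0) list(beta = beta, iter_index = it,
                                         deviance = dev)
  expect_identical(convergence_check(st(c(0, 0), 0), st(c(1e-9, 0), 1), conv),
                   "converged")
  expect_identical(convergence_check(st(c(0, 0), 9), st(c(1e-3, 0), 10), conv),
                   "max-iter-reached")
  # boundary: a change exactly equal to tol continues
  expect_identical(convergence_check(st(c(0, 0), 1), st(c(1e-8, 0), 2), conv),
                   "continue")
  expect_error(convergence_spec(tol = 0), "tol")
  expect_error(convergence_spec(max_iter = 0), "max_iter")
})

test_that("distributed IRLS converges to the pooled logistic oracle", {
  fx <- make_logistic_fixture(n = 400, seed = 5)
  f <- fit_distributed(fx$sites, "y", model = "logistic", seed = 2)
  o <- pooled_oracle_fit(fx$tab, "logistic", fx$covariates, "y")
  cmp <- compare_results(f, o, tol = 1e-8)
  expect_true(cmp$pass)
  expect_true(f$converged)
  expect_lte(abs(f$fit$deviance - o$fit$deviance), 1e-6)

  # warm start at the solution converges immediately
  f2 <- fit_distributed(fx$sites, "y", model = "logistic", seed = 2,
                        conv = convergence_spec(tol = 1e-6),
                        beta_start = coef(o))
  expect_lte(f2$n_iter, 2)

  # iteration cap is honored and recorded
  f3 <- fit_distributed(fx$sites, "y", model = "logistic", seed = 2,
                        conv = convergence_spec(tol = 1e-300, max_iter = 1))
  expect_false(f3$converged)
  expect_identical(f3$termination_reason, "max-iter-reached")
  expect_identical(f3$n_iter, 1L)

  # non-binary outcome refused
  fx2 <- make_linear_fixture(n = 50, p = 2)
  expect_error(fit_distributed(fx2$sites, "y", model = "logistic"),
               class = "vdra_domain_error")
})

test_that("deviance is non-increasing across IRLS iterations", {
  fx <- make_logistic_fixture(n = 300, seed = 9)
  devs <- c()
  for (k in 1:6) {
    f <- fit_distributed(fx$sites, "y", model = "logistic", seed = 2,
                         conv = convergence_spec(tol = 1e-300, max_iter = k))
    devs <- c(devs, f$fit$deviance)
  }
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("result comparison reports the offending coordinate", {
  fx <- make_linear_fixture(n = 60, p = 2)
  o <- pooled_oracle_fit(fx$tab, "linear", fx$covariates, "y")
  same <- compare_results(o, o, tol = 1e-12)
  expect_true(same$pass)
  expect_equal(same$max_diff, 0)

  shifted <- o
  shifted$coefficients["x1"] <- shifted$coefficients["x1"] + 1e-6
  cmp <- compare_results(shifted, o, tol = 1e-12)
  expect_false(cmp$pass)
  expect_identical(cmp$worst_coordinate, "beta:x1")

  reordered <- o
  reordered$column_order <- rev(o$column_order)
  expect_error(compare_results(reordered, o), class = "vdra_comparison_error")
})

test_that("vdra_fit behaves like a standard model object", {
  fx <- make_linear_fixture(n = 200, p = 3, seed = 31)
  f <- fit_distributed(fx$sites, "y", seed = 3)
  o <- pooled_oracle_fit(fx$tab, "linear", fx$covariates, "y")
  expect_named(coef(f), c("(Intercept)", fx$covariates))
  expect_equal(unname(sqrt(diag(vcov(f)))), unname(f$se))
  ci <- confint(f)
  expect_true(all(ci[, 1] < coef(f) & coef(f) < ci[, 2]))
  sm <- summary(f)
  expect_s3_class(sm, "summary.vdra_fit")
  expect_identical(rownames(sm$coefficients), f$column_order)
  expect_output(print(sm), "R-squared")
  expect_output(print(f), "Coefficients")
  # predictions agree with the pooled lm on the training table
  expect_equal(predict(f, fx$tab),
               unname(stats::predict(stats::lm(
                 stats::reformulate(fx$covariates, "y"), fx$tab))),
               tolerance = 1e-10, ignore_attr = TRUE)
  # logistic response predictions lie in (0, 1)
  lx <- make_logistic_fixture(n = 150, seed = 13)
  lf <- fit_distributed(lx$sites, "y", model = "logistic", seed = 4)
  pr <- predict(lf, lx$tab, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_output(print(summary(lf)), "Deviance")
})

test_that("oracle fit statistics are well formed", {
  fx <- make_linear_fixture(n = 80, p = 2, seed = 77)
  o <- pooled_oracle_fit(fx$tab, "linear", fx$covariates, "y")
  expect_gte(o$fit$r_squared, 0)
  expect_lte(o$fit$r_squared, 1)
  # noiseless cohort: oracle recovers truth exactly
  spec <- cohort_spec(40, list(list(name = "x", kind = "continuous")),
                      outcome_model = "linear", true_beta = c(1, 3),
                      noise_sd = 0, seed = 2)
  tabz <- generate_cohort(spec)
  oz <- suppressWarnings(pooled_oracle_fit(tabz, "linear", "x", "y"))
  expect_equal(unname(coef(oz)), c(1, 3), tolerance = 1e-12)
})
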