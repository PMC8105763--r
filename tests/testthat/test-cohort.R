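test_that("cohort generation is deterministic and honors the linear map", {
  spec <- cohort_spec(50, list(list(name = "x", kind = "continuous")),
                      outcome_model = "linear", true_beta = c(0, 2),
                      noise_sd = 0, seed = 3)
  tab <- generate_cohort(spec)
  expect_equal(tab$y, 2 * tab$x)                 # noiseless linear map
  expect_identical(tab, generate_cohort(spec))   # same spec + seed, same table

  # per-column seed streams: appending a covariate leaves earlier columns alone
  spec2 <- cohort_spec(50, list(list(name = "x", kind = "continuous"),
                                list(name = "w", kind = "binary")),
                       outcome_model = "linear", true_beta = c(0, 2, 0),
                       noise_sd = 0, seed = 3)
  expect_identical(generate_cohort(spec2)$x, tab$x)
})

test_that("invalid cohort specifications are rejected", {
  cv <- list(list(name = "x", kind = "continuous"))
  expect_error(cohort_spec(50, cv, true_beta = c(0, 1, 1)), "true_beta")
  expect_error(cohort_spec(50, cv, true_beta = c(0, 1), noise_sd = -1),
               "noise_sd")
  expect_error(cohort_spec(3, cv, true_beta = c(0, 1)), "too small")
  expect_error(cohort_spec(50, list(list(name = "x", kind = "continuous",
                                         sd = -2)), true_beta = c(0, 1)),
               "sd must be positive")
  expect_error(cohort_spec(50, list(list(name = "x", kind = "binary",
                                         prob = 1.4)), true_beta = c(0, 1)),
               "prob")
})

test_that("pooled OLS on a generated cohort recovers the truth", {
  spec <- cohort_spec(5000, list(list(name = "x1", kind = "continuous"),
                                 list(name = "x2", kind = "continuous")),
                      outcome_model = "linear", true_beta = c(0, 1, -1),
                      noise_sd = 1, seed = 99)
  tab <- generate_cohort(spec)
  f <- pooled_oracle_fit(tab, "linear", c("x1", "x2"), "y")
  expect_lt(max(abs(coef(f) - c(0, 1, -1)) / f$se), 3)
})

test_that("mean estimate over replicates stays within 3 Monte-Carlo SEs", {
  R <- 200
  est <- t(vapply(seq_len(R), function(r) {
    spec <- cohort_spec(2000, list(list(name = "x1", kind = "continuous"),
                                   list(name = "x2", kind = "binary")),
                        outcome_model = "linear", true_beta = c(0.5, 1, -1),
                        noise_sd = 1, seed = 1000 + r)
    tab <- generate_cohort(spec)
    coef(stats::lm(y ~ x1 + x2, tab))
  }, numeric(3)))
  mc_se <- apply(est, 2, stats::sd) / sqrt(R)
  expect_true(all(abs(colMeans(est) - c(0.5, 1, -1)) < 3 * mc_se))
})

test_that("vertical partition splits columns disjointly and reconstructs", {
  fx <- make_linear_fixture(n = 40, p = 4)
  sites <- fx$sites
  cols <- lapply(sites, function(s) names(s$data))
  expect_length(intersect(cols$site1, cols$site2), 0)
  expect_setequal(unlist(cols), c(fx$covariates, "y"))
  # identical patient_id sequence at every site
  expect_identical(sites$site1$patient_id, sites$site2$patient_id)
  # ID-join reproduces the original table
  joined <- cbind(data.frame(patient_id = sites$site1$patient_id),
                  sites$site1$data, sites$site2$data)
  expect_equal(joined[names(fx$tab)], fx$tab, ignore_attr = TRUE)
})

test_that("Fig-2-style partition puts three independents at one site", {
  spec <- cohort_spec(30, list(list(name = "surgery", kind = "binary"),
                               list(name = "sex", kind = "binary"),
                               list(name = "race", kind = "binary")),
                      outcome_model = "linear", true_beta = c(25, -1, 1, 0.5),
                      noise_sd = 2, outcome_name = "bmi", seed = 1)
  tab <- generate_cohort(spec)
  plan <- partition_plan(c(surgery = "site1", sex = "site1", race = "site1",
                           bmi = "site2"),
                         outcome_site = "site2", outcome_name = "bmi")
  sites <- partition_vertical(tab, plan)
  expect_length(names(sites$site1$data), 3)
  expect_identical(names(sites$site2$data), "bmi")
})

test_that("bad partition plans are rejected", {
  fx <- make_linear_fixture(n = 20, p = 2)
  expect_error(partition_plan(c(x1 = "s1"), "s1"), "at least 2 sites")
  expect_error(partition_plan(c(x1 = "s1", y = "s2"), "s1"),
               "assigned to outcome_site")
  bad <- partition_plan(c(x1 = "s1", nope = "s2", y = "s2"), "s2")
  expect_error(partition_vertical(fx$tab, bad), "nonexistent")
  partial <- partition_plan(c(x1 = "s1", y = "s2"), "s2")
  expect_error(partition_vertical(fx$tab, partial), "not assigned")
})

test_that("row blocking is exact: identity, reassembly, additive Gram", {
  fx <- make_linear_fixture(n = 10, p = 2)
  s1 <- fx$sites$site1
  bp <- block_plan(list(c(0, 5), c(5, 10)), 10)
  parts <- partition_blocks(s1, bp)
  expect_length(parts, 2)
  expect_equal(vapply(parts, function(p) p$n, 1L), c(5L, 5L))
  expect_equal(do.call(rbind, lapply(parts, function(p) p$data)), s1$data,
               ignore_attr = TRUE)
  # single block is the identity
  one <- partition_blocks(s1, block_plan(list(c(0, 10)), 10))
  expect_equal(one[[1L]]$data, s1$data)
  # block-wise X'X sums to the full X'X
  full <- gram_self(s1)$block
  summed <- Reduce(`+`, lapply(parts, function(p) gram_self(p)$block))
  expect_equal(summed, full, tolerance = 1e-12)
  # invalid plans
  expect_error(block_plan(list(c(0, 4), c(5, 10)), 10), "contiguous")
  expect_error(block_plan(list(c(0, 6), c(5, 10)), 10), "contiguous")
  expect_error(block_plan(list(c(3, 3)), 3), "empty or inverted")
})

test_that("partition CSV round-trip is lossless and canonicalizes order", {
  fx <- make_linear_fixture(n = 25, p = 3)
  s <- fx$sites$site1
  path <- withr::local_tempfile(fileext = ".csv")
  write_partition(s, path)
  r <- read_partition(path, site_id = "site1")
  expect_equal(r$data, s$data, ignore_attr = TRUE)
  expect_identical(r$patient_id, s$patient_id)

  # shuffled rows on disk are restored to canonical sorted-ID order
  df <- utils::read.csv(path)
  df <- df[sample.int(nrow(df)), ]
  utils::write.csv(df, path, row.names = FALSE)
  r2 <- read_partition(path, site_id = "site1")
  expect_identical(r2$patient_id, s$patient_id)
  expect_equal(r2$data, s$data, ignore_attr = TRUE)

  # duplicate IDs rejected
  df$patient_id <- rep(1L, nrow(df))
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_partition(path), "duplicate patient_id")
})
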