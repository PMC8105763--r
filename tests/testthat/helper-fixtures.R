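# fixture builders shared across test files; everything is generated in code

# small linear cohort split over two sites (covariates x1..x_p, outcome y)
make_linear_fixture <- function(n = 120, p = 4, seed = 11, noise_sd = 1,
                                split = NULL) {
  covs <- lapply(seq_len(p), function(i)
    list(name = paste0("x", i), kind = "continuous"))
  beta <- c(0.5, rep_len(c(0.4, -0.4), p))
  spec <- cohort_spec(n, covs, outcome_model = "linear", true_beta = beta,
                      noise_sd = noise_sd, seed = seed)
  tab <- generate_cohort(spec)
  split <- split %||% c(ceiling(p / 2), floor(p / 2))
  asg <- c(setNames(rep(c("site1", "site2"), split), paste0("x", seq_len(p))),
           y = "site2")
  plan <- partition_plan(asg, outcome_site = "site2")
  list(spec = spec, tab = tab, plan = plan,
       sites = partition_vertical(tab, plan),
       covariates = paste0("x", seq_len(p)), beta = beta)
}

make_logistic_fixture <- function(n = 400, seed = 5) {
  spec <- cohort_spec(n, list(
    list(name = "x1", kind = "continuous"),
    list(name = "x2", kind = "continuous"),
    list(name = "x3", kind = "binary", prob = 0.4)),
    outcome_model = "logistic", true_beta = c(0.2, 0.5, -0.5, 0.4),
    seed = seed)
  tab <- generate_cohort(spec)
  plan <- partition_plan(c(x1 = "site1", x2 = "site1", x3 = "site2",
                           y = "site2"), outcome_site = "site2")
  list(spec = spec, tab = tab, plan = plan,
       sites = partition_vertical(tab, plan),
       covariates = c("x1", "x2", "x3"))
}

# a network over tempdir with all site-to-site routes enabled
make_open_network <- function(sites = c("site1", "site2"),
                              routing = "direct") {
  net <- create_network(withr::local_tempdir(.local_envir = parent.frame()),
                        sites, routing = routing)
  for (a in sites) for (b in setdiff(sites, a))
    set_trust(net, a, b, TRUE, actor = "center")
  net
}

# random row-aligned site pair for protocol property tests
make_random_pair <- function(n, pa, pb, seed) {
  set.seed(seed)
  ids <- seq_len(n)
  a <- vdra:::new_site_partition("A", ids,
    as.data.frame(matrix(rnorm(n * pa), n, pa,
                         dimnames = list(NULL, paste0("a", seq_len(pa))))))
  b <- vdra:::new_site_partition("B", ids,
    as.data.frame(matrix(rnorm(n * pb), n, pb,
                         dimnames = list(NULL, paste0("b", seq_len(pb))))))
  list(a = a, b = b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
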