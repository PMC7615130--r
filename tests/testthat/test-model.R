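# Bayesian logistic model: likelihood, priors, sampler contract, summaries

test_that("log_likelihood matches closed forms and is stable", {
  X1 <- matrix(0, 1, 1, dimnames = list(NULL, "x"))
  expect_equal(log_likelihood(list(alpha = 0, beta = c(x = 0)), X1, 1)$total,
               log(0.5))
  expect_equal(log_likelihood(list(alpha = 2, beta = c(x = 0)), X1, 1)$total,
               -log(1 + exp(-2)))
  # pointwise additivity on a random problem
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(20, 1, 0.5)
  ll <- log_likelihood(list(alpha = 0.3, beta = c(a = 1, b = -2, c = 0.5)),
                       X, y)
  expect_equal(sum(ll$pointwise), ll$total, tolerance = 1e-10)
  # no overflow at |eta| = 700
  big <- log_likelihood(list(alpha = 700, beta = c(x = 0)), X1, 0)
  expect_true(is.finite(big$total))
  expect_equal(big$total, -700)
  expect_error(log_likelihood(list(alpha = 0, beta = c(x = 0)), X1, 2),
               "binary")
})

test_that("log_prior matches the stated families", {
  spec <- model_spec(prior_scale = 0.98)
  k <- 5
  p0 <- list(alpha = 0, beta = rep(0, k))
  expect_equal(log_prior(p0, spec),
               (k + 1) * dnorm(0, 0, 0.98, log = TRUE))
  # lasso: density ratio at 0 vs b is exp(|b|/s)
  lspec <- model_spec("lasso", prior_scale = 0.98)
  s <- 0.98 / sqrt(2)
  b <- 0.7
  d0 <- log_prior(list(alpha = 0, beta = 0), lspec)
  db <- log_prior(list(alpha = 0, beta = b), lspec)
  expect_equal(exp(d0 - db), exp(abs(b) / s), tolerance = 1e-12)
  # half-Cauchy tail falls like -2 log sigma
  re <- model_spec(random_effects = TRUE, re_sd_prior_scale = 1)
  tail_at <- function(sv) log_prior(list(alpha = 0, beta = 0, V = numeric(0),
                                         sigma_v = sv), re)
  expect_equal(tail_at(1e5) - tail_at(1e4), -2 * log(10), tolerance = 1e-3)
  # sigma_v <= 0 is a rejected state, not an exception
  expect_identical(log_prior(list(alpha = 0, beta = 0, V = 0, sigma_v = -1),
                             re), -Inf)
  # ridge requires a positive precision
  rspec <- model_spec("ridge")
  expect_identical(log_prior(list(alpha = 0, beta = 0, lambda = 0), rspec),
                   -Inf)
  expect_true(is.finite(log_prior(list(alpha = 0, beta = 0, lambda = 2),
                                  rspec)))
})

test_that("prior_or_interval reproduces the printed interval", {
  expect_equal(signif(unname(prior_or_interval(0.98)), 2), c(0.15, 6.8))
  expect_equal(unname(prior_or_interval(1e-9)), c(1, 1), tolerance = 1e-6)
  expect_equal(unname(prior_or_interval(log(2) / 1.96)), c(0.5, 2),
               tolerance = 1e-12)
  expect_error(prior_or_interval(0), "positive")
  expect_error(prior_or_interval(-1), "positive")
})

test_that("fit is deterministic under a fixed seed", {
  set.seed(10)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(100, 1, plogis(X[, 1]))
  spec <- model_spec(n_iter = 200, burn_in = 100, n_chains = 2, seed = 5)
  f1 <- fit(spec, X, y)
  f2 <- fit(spec, X, y)
  expect_identical(f1$draws, f2$draws)
  spec2 <- spec; spec2$seed <- 6L
  expect_false(identical(fit(spec2, X, y)$draws, f1$draws))
})

test_that("the prior regularizes completely separable data", {
  # x = y on 20 points: the MLE diverges, the posterior must not
  X <- matrix(rep(0:1, each = 10), 20, 1, dimnames = list(NULL, "x"))
  y <- X[, 1]
  spec <- model_spec(n_iter = 2000, burn_in = 500, n_chains = 2, seed = 2)
  f <- fit(spec, X, y)
  bhat <- mean(f$draws[, "x"])
  expect_lt(abs(bhat), 10)
  # oracle: dense numerical integration of the 2-parameter posterior
  grid <- seq(-8, 8, by = 0.04)
  lp <- outer(grid, grid, function(a, b) {
    vapply(seq_along(a), function(i) {
      eta <- a[i] + b[i] * X[, 1]
      sum(y * eta - log1p(exp(eta))) +
        dnorm(a[i], 0, 0.98, log = TRUE) + dnorm(b[i], 0, 0.98, log = TRUE)
    }, 0)
  })
  w <- exp(lp - max(lp))
  oracle_mean_b <- sum(w * matrix(grid, length(grid), length(grid),
                                  byrow = TRUE)) / sum(w)
  expect_equal(bhat, oracle_mean_b, tolerance = 0.05)
})

test_that("with a wide prior the posterior tracks the ML fit", {
  set.seed(11)
  n <- 600
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(0.3 + 0.9 * X[, 1] - 0.6 * X[, 2]))
  spec <- model_spec(prior_scale = 25, n_iter = 1500, burn_in = 500,
                     n_chains = 2, seed = 4)
  f <- fit(spec, X, y)
  ml <- glm(y ~ X, family = binomial())   # independent Newton/IRLS solver
  expect_equal(unname(colMeans(f$draws[, c("alpha", "a", "b")])),
               unname(coef(ml)), tolerance = 0.15)
})

test_that("lasso concentrates a truly-zero coefficient at least as much", {
  set.seed(12)
  n <- 400
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "zz")))
  y <- rbinom(n, 1, plogis(1.2 * X[, 1] - 0.8 * X[, 2]))
  base <- model_spec(n_iter = 1500, burn_in = 500, n_chains = 2, seed = 9)
  las <- model_spec("lasso", n_iter = 1500, burn_in = 500, n_chains = 2,
                    seed = 9)
  pn <- mean(abs(fit(base, X, y)$draws[, "zz"]) < 0.05)
  pl <- mean(abs(fit(las, X, y)$draws[, "zz"]) < 0.05)
  expect_gte(pl, pn - 0.02)   # small slack for Monte-Carlo noise
})

test_that("ridge fit samples the precision and behaves like shrinkage", {
  set.seed(13)
  n <- 300
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(n, 1, plogis(X[, 1]))
  spec <- model_spec("ridge", n_iter = 800, burn_in = 400, n_chains = 2,
                     seed = 3)
  f <- fit(spec, X, y)
  expect_true("lambda" %in% colnames(f$draws))
  expect_true(all(f$draws[, "lambda"] > 0))
  expect_equal(mean(f$draws[, "a"]), 1, tolerance = 0.35)
})

test_that("sigma_v concentrates near zero on exchangeable data", {
  set.seed(14)
  mkdata <- function(n) {
    X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
    list(X = X, y = rbinom(n, 1, plogis(0.8 * X[, 1])),
         nb = rep(sprintf("g%02d", 1:20), length.out = n))
  }
  spec <- model_spec(random_effects = TRUE, n_iter = 800, burn_in = 400,
                     n_chains = 2, seed = 6)
  q95 <- function(n) {
    d <- mkdata(n)
    # small draw budgets mix sigma_v slowly; the quantile ordering is all
    # this test needs, so the R-hat warning is expected noise here
    f <- suppressWarnings(fit(spec, d$X, d$y, d$nb))
    quantile(f$draws[, "sigma_v"], 0.95)
  }
  small <- q95(150); large <- q95(1200)
  expect_lt(large, small)        # upper quantile shrinks as n grows
  expect_lt(large, 0.8)
})

test_that("summarize_or transforms draws correctly", {
  draws <- cbind(alpha = rep(0, 50), a = rep(0, 50), b = rep(log(2), 50))
  f <- manual_fit(draws)
  s <- summarize_or(f)
  expect_equal(s$or[s$term == "a"], 1.0)
  expect_equal(s$lo[s$term == "a"], 1.0)
  expect_equal(s$hi[s$term == "a"], 1.0)
  expect_equal(s$or[s$term == "b"], 2.0)
  # equivariance: adding c to draws multiplies all three outputs by e^c
  f2 <- manual_fit(draws + 0.5)
  s2 <- summarize_or(f2)
  expect_equal(s2$or, s$or * exp(0.5), tolerance = 1e-12)
  expect_equal(s2$lo, s$lo * exp(0.5), tolerance = 1e-12)
  expect_equal(s2$hi, s$hi * exp(0.5), tolerance = 1e-12)
})

test_that("draws persist and restore through CSV + manifest", {
  set.seed(15)
  X <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(50, 1, 0.4)
  f <- fit(model_spec(n_iter = 100, burn_in = 50, n_chains = 2, seed = 1),
           X, y)
  path <- file.path(withr::local_tempdir(), "draws.csv")
  write_draws(f, path)
  f2 <- read_draws(path)
  expect_equal(f2$draws, f$draws, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f2$param_names, f$param_names)
  expect_equal(f2$spec$prior_family, f$spec$prior_family)
})
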