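#' Bayesian logistic model specification
#'
#' Prior families for the coefficient vector: `"normal"` — independent
#' `N(0, prior_scale^2)` (the headline specification with
#' `prior_scale = 0.98`, i.e. a 95% prior odds-ratio interval of
#' `exp(±1.96 x 0.98) = [0.15, 6.8]`); `"lasso"` — double-exponential with
#' scale `prior_scale / sqrt(2)` (variance matched to the normal prior);
#' `"ridge"` — `N(0, 1/lambda)` with the precision `lambda` given a flat
#' `InvGamma(ridge_shape, ridge_rate)` hyperprior. The intercept always
#' gets `N(0, prior_scale^2)`. With `random_effects = TRUE`, independent
#' neighbourhood effects `V_j ~ N(0, sigma_v^2)` are added, with a
#' half-Cauchy(`re_sd_prior_scale`) prior on `sigma_v`.
#'
#' @param prior_family one of `"normal"`, `"lasso"`, `"ridge"`
#' @param prior_scale prior SD (normal) / variance-matched scale (lasso);
#'   default 0.98
#' @param random_effects include neighbourhood random effects (Model 2)
#' @param re_sd_prior_scale half-Cauchy scale for the random-effect SD
#' @param ridge_shape,ridge_rate inverse-gamma hyperprior parameters
#' @param n_iter kept draws per chain after burn-in (default 20000)
#' @param burn_in burn-in iterations per chain (default 5000)
#' @param n_chains number of chains (default 4)
#' @param thin keep every `thin`-th post-burn-in draw
#' @param seed integer seed
#' @return a `model_spec` list
#' @export
model_spec <- function(prior_family = c("normal", "lasso", "ridge"),
                       prior_scale = 0.98, random_effects = FALSE,
                       re_sd_prior_scale = 1, ridge_shape = 0.01,
                       ridge_rate = 0.01, n_iter = 20000, burn_in = 5000,
                       n_chains = 4, thin = 1, seed = 1) {
  prior_family <- match.arg(prior_family)
  stopifnot(prior_scale > 0, re_sd_prior_scale > 0, n_iter >= 1,
            burn_in >= 1, n_chains >= 1, thin >= 1)
  structure(list(prior_family = prior_family, prior_scale = prior_scale,
                 random_effects = isTRUE(random_effects),
                 re_sd_prior_scale = re_sd_prior_scale,
                 ridge_shape = ridge_shape, ridge_rate = ridge_rate,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' 95% prior odds-ratio interval implied by a normal coefficient prior
#'
#' `exp(±1.96 sd)`; with `sd = 0.98` this is `[0.15, 6.8]` to two
#' significant figures.
#'
#' @param sd prior standard deviation (> 0)
#' @return numeric vector `c(lower, upper)`
#' @export
prior_or_interval <- function(sd) {
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0)
    stop("prior_or_interval: sd must be a positive scalar")
  c(lower = exp(-1.96 * sd), upper = exp(1.96 * sd))
}

# numerically stable Bernoulli-logit log density terms; safe for |eta| up
# to the double range
log1p_exp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 18
  lo <- x < -37
  mid <- !hi & !lo
  out[hi] <- x[hi] + exp(-x[hi])
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

#' Bernoulli-logit log-likelihood
#'
#' `sum_i [ y_i eta_i - log(1 + e^{eta_i}) ]` with
#' `eta = alpha + X beta (+ V_j)`, evaluated stably (no overflow for large
#' `|eta|`).
#'
#' @param params list with `alpha` (scalar), `beta` (named or positional
#'   vector matching `X` columns), and optionally `V` (named by
#'   neighbourhood level)
#' @param X predictor matrix
#' @param y 0/1 outcome vector
#' @param neighbourhoods optional factor/character of neighbourhood ids
#'   (required when `params$V` is present)
#' @return list `total` (scalar) and `pointwise` (per-observation vector)
#' @export
log_likelihood <- function(params, X, y, neighbourhoods = NULL) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("log_likelihood: y must be binary 0/1")
  X <- as.matrix(X)
  beta <- params$beta
  if (!is.null(names(beta)) && !is.null(colnames(X)))
    beta <- beta[colnames(X)]
  eta <- as.numeric(params$alpha + X %*% beta)
  if (!is.null(params$V)) {
    if (is.null(neighbourhoods))
      stop("log_likelihood: neighbourhoods required when V is present")
    eta <- eta + params$V[as.character(neighbourhoods)]
  }
  pw <- y * eta - log1p_exp(eta)
  list(total = sum(pw), pointwise = pw)
}

#' Log prior density of a parameter state
#'
#' Sums the log prior of the intercept and coefficients under the
#' specification's family, the `N(0, sigma_v^2)` terms for random effects
#' plus the half-Cauchy density of `sigma_v`, and for ridge the
#' inverse-gamma hyperprior on the precision `lambda`. A non-positive
#' `sigma_v` yields `-Inf` (a rejected state), not an error.
#'
#' @param params list with `alpha`, `beta`, optionally `V`, `sigma_v`,
#'   `lambda`
#' @param spec a [model_spec()]
#' @return scalar log density (up to additive constants in none of the
#'   terms: all normalizing constants are included)
#' @export
log_prior <- function(params, spec) {
  lp <- dnorm(params$alpha, 0, spec$prior_scale, log = TRUE)
  b <- params$beta
  lp <- lp + switch(spec$prior_family,
    normal = sum(dnorm(b, 0, spec$prior_scale, log = TRUE)),
    lasso = {
      s <- spec$prior_scale / sqrt(2)
      sum(-abs(b) / s - log(2 * s))
    },
    ridge = {
      lam <- params$lambda
      if (is.null(lam) || lam <= 0) return(-Inf)
      a0 <- spec$ridge_shape; b0 <- spec$ridge_rate
      sum(dnorm(b, 0, 1 / sqrt(lam), log = TRUE)) +
        a0 * log(b0) - lgamma(a0) - (a0 + 1) * log(lam) - b0 / lam
    })
  if (spec$random_effects || !is.null(params$V)) {
    sv <- params$sigma_v
    if (is.null(sv) || sv <= 0) return(-Inf)
    A <- spec$re_sd_prior_scale
    lp <- lp + sum(dnorm(params$V, 0, sv, log = TRUE)) +
      log(2 / (pi * A)) - log1p((sv / A)^2)
  }
  lp
}

#' Fit a Bayesian logistic deprivation model by MCMC
#'
#' Samples the posterior with a univariate slice sampler (stepping-out and
#' shrinkage) sweeping the intercept, each coefficient, each neighbourhood
#' effect, the random-effect SD (on the log scale) and, for ridge, the
#' prior precision. Chains are deterministic given `spec$seed`. Split
#' R-hat and effective sample sizes are computed for every parameter; a
#' warning is issued when any R-hat exceeds 1.05.
#'
#' @param spec a [model_spec()]
#' @param X predictor matrix (standardize continuous columns, or document
#'   their scale: a common prior SD is only meaningful on a common scale)
#' @param y 0/1 outcomes
#' @param neighbourhoods neighbourhood ids per row; required iff
#'   `spec$random_effects`
#' @param store_loglik keep the kept-draw x observation pointwise
#'   log-likelihood matrix (needed for [waic()])
#' @return object of class `depriv_fit`: `draws` (kept draws x parameters),
#'   `chain` (chain index per draw), `spec`, `param_names`, `re_levels`,
#'   `loglik`, `diagnostics` (R-hat / ESS per parameter), `scaling`
#' @export
fit <- function(spec, X, y, neighbourhoods = NULL, store_loglik = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("fit: y must be binary 0/1")
  if (nrow(X) != length(y)) stop("fit: X and y lengths differ")
  if (any(!is.finite(X)))
    stop("fit: non-finite values in X; standardize/clean predictors first")
  if (spec$random_effects && is.null(neighbourhoods))
    stop("fit: neighbourhoods required when random_effects = TRUE")
  nbf <- NULL; nb_codes <- integer(0); J <- 0L
  if (spec$random_effects) {
    nbf <- factor(neighbourhoods)
    nb_codes <- as.integer(nbf) - 1L
    J <- nlevels(nbf)
  }
  fam <- match(spec$prior_family, c("normal", "lasso", "ridge")) - 1L
  scale <- if (spec$prior_family == "lasso") spec$prior_scale / sqrt(2) else
    spec$prior_scale
  chains <- vector("list", spec$n_chains)
  ll <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    res <- cpp_fit_chain(X, as.integer(y),
                         if (J > 0) nb_codes else integer(0), J,
                         fam, scale, spec$prior_scale,
                         spec$re_sd_prior_scale, spec$ridge_shape,
                         spec$ridge_rate, spec$n_iter, spec$burn_in,
                         spec$thin,
                         as.numeric(spec$seed) * 1000003 + ch * 7919,
                         store_loglik)
    chains[[ch]] <- res$draws
    if (store_loglik) ll[[ch]] <- res$loglik
  }
  pn <- c("alpha", colnames(X))
  if (J > 0) pn <- c(pn, paste0("V[", levels(nbf), "]"), "sigma_v")
  if (spec$prior_family == "ridge") pn <- c(pn, "lambda")
  draws <- do.call(rbind, chains)
  colnames(draws) <- pn
  diag <- chain_diagnostics(chains, pn)
  if (any(diag$rhat > 1.05, na.rm = TRUE))
    warning("fit: split R-hat > 1.05 for: ",
            paste(diag$param[which(diag$rhat > 1.05)], collapse = ", "),
            " - inspect convergence")
  structure(list(draws = draws,
                 chain = rep(seq_len(spec$n_chains),
                             each = nrow(chains[[1]])),
                 spec = spec, param_names = pn,
                 re_levels = if (J > 0) levels(nbf) else NULL,
                 loglik = if (store_loglik) do.call(rbind, ll) else NULL,
                 diagnostics = diag,
                 scaling = attr(X, "scaling")),
            class = "depriv_fit")
}

#' @export
print.depriv_fit <- function(x, ...) {
  cat("<depriv_fit> ", x$spec$prior_family, " prior",
      if (x$spec$random_effects) " + neighbourhood random effects", "; ",
      nrow(x$draws), " kept draws (", x$spec$n_chains, " chains)\n",
      "max split R-hat: ", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      ", min ESS: ", round(min(x$diagnostics$ess, na.rm = TRUE), 1), "\n",
      sep = "")
  invisible(x)
}

# split R-hat and a Geyer-style initial-positive-sequence ESS, per column
chain_diagnostics <- function(chains, pn) {
  half <- lapply(chains, function(m) {
    h <- nrow(m) %/% 2
    list(m[seq_len(h), , drop = FALSE],
         m[(nrow(m) - h + 1):nrow(m), , drop = FALSE])
  })
  splits <- unlist(half, recursive = FALSE)
  P <- ncol(chains[[1]])
  rhat <- ess <- numeric(P)
  for (p in seq_len(P)) {
    mats <- vapply(splits, function(s) s[, p], numeric(nrow(splits[[1]])))
    m <- ncol(mats); nn <- nrow(mats)
    mu <- colMeans(mats); vv <- apply(mats, 2, var)
    W <- mean(vv); B <- nn * var(mu)
    rhat[p] <- if (W <= 0) NA_real_ else
      sqrt(((nn - 1) / nn * W + B / nn) / W)
    ess[p] <- sum(vapply(chains, function(ch) ess_one(ch[, p]), 0))
  }
  data.frame(param = pn, rhat = rhat, ess = ess, stringsAsFactors = FALSE)
}

ess_one <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Posterior odds ratios with 95% credible intervals
#'
#' `exp` of the posterior mean and of the 2.5 / 97.5 percentiles of each
#' predictor coefficient.
#'
#' @param d a `depriv_fit`
#' @return data.frame `term`, `or`, `lo`, `hi`
#' @export
summarize_or <- function(d) {
  stopifnot(inherits(d, "depriv_fit"), nrow(d$draws) > 0)
  keep <- setdiff(d$param_names,
                  c("alpha", "sigma_v", "lambda",
                    grep("^V\\[", d$param_names, value = TRUE)))
  qs <- apply(d$draws[, keep, drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  data.frame(term = keep,
             or = exp(colMeans(d$draws[, keep, drop = FALSE])),
             lo = exp(qs[1, ]), hi = exp(qs[2, ]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist / restore posterior draws as CSV + JSON manifest
#' @param d a `depriv_fit`
#' @param path CSV path for the draws (manifest at `<path>.json`)
#' @export
write_draws <- function(d, path) {
  df <- data.frame(chain = d$chain, as.data.frame(d$draws),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(d$spec), param_names = d$param_names,
         re_levels = d$re_levels, diagnostics = d$diagnostics,
         scaling = d$scaling),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sp <- meta$spec
  spec <- model_spec(prior_family = sp$prior_family,
                     prior_scale = sp$prior_scale,
                     random_effects = sp$random_effects,
                     re_sd_prior_scale = sp$re_sd_prior_scale,
                     ridge_shape = sp$ridge_shape, ridge_rate = sp$ridge_rate,
                     n_iter = sp$n_iter, burn_in = sp$burn_in,
                     n_chains = sp$n_chains, thin = sp$thin, seed = sp$seed)
  draws <- as.matrix(df[, setdiff(names(df), "chain"), drop = FALSE])
  re_levels <- meta$re_levels
  if (length(re_levels) == 0) re_levels <- NULL
  structure(list(draws = draws, chain = df$chain, spec = spec,
                 param_names = meta$param_names,
                 re_levels = re_levels, loglik = NULL,
                 diagnostics = meta$diagnostics, scaling = meta$scaling),
            class = "depriv_fit")
}
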