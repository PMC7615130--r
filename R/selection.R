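#' Mean squared error
#' @param pred predicted probabilities
#' @param ref reference values (binary labels or probabilities)
#' @return scalar mean of squared differences
#' @export
mse <- function(pred, ref) {
  if (length(pred) == 0 || length(pred) != length(ref))
    stop("mse: inputs must be nonempty and of equal length")
  mean((pred - ref)^2)
}

#' Watanabe-Akaike information criterion from pointwise log-likelihoods
#'
#' `lppd = sum_i log mean_s exp(ll_si)` (via log-sum-exp),
#' `p_waic = sum_i var_s(ll_si)` (sample variance over draws),
#' `waic = -2 (lppd - p_waic)`.
#'
#' @param pointwise_loglik draws x observations matrix of log-likelihood
#'   values
#' @return list `waic`, `lppd`, `p_waic`
#' @export
waic <- function(pointwise_loglik) {
  m <- as.matrix(pointwise_loglik)
  if (any(!is.finite(m))) stop("waic: non-finite log-likelihood entries")
  S <- nrow(m)
  if (S < 2) {
    warning("waic: a single draw gives p_waic = 0")
    lppd <- sum(m[1, ])
    return(list(waic = -2 * lppd, lppd = lppd, p_waic = 0))
  }
  mx <- apply(m, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(m, 2, mx)))))
  p_waic <- sum(apply(m, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' The seven hold-out fractions used for model comparison
#' @export
default_cv_fractions <- function() c(0.025, 0.037, 0.05, 0.062, 0.075,
                                     0.087, 0.10)

#' Hold-out cross-validation of a deprivation model
#'
#' For each fraction: a seeded random sample of EAs is held out, the model
#' is refitted on the remainder, posterior-predictive probabilities are
#' computed for the held-out EAs, and the mean squared error is reported
#' against (a) the observed binary labels (a Brier score; the default
#' headline number) and (b) the full-data fitted probabilities (the
#' alternative reading of "compared against their fitted probability
#' values"). With `repeats > 1`, each fraction is averaged over that many
#' independent partitions.
#'
#' @param spec a [model_spec()] (use a reduced draw budget for speed; the
#'   refits use it as-is)
#' @param X predictor matrix
#' @param y 0/1 labels
#' @param neighbourhoods neighbourhood ids (required for random-effects
#'   specs)
#' @param fractions hold-out fractions in (0, 0.5); default the canonical
#'   seven, 2.5% to 10%
#' @param seed partition seed (fan-out per fraction/repeat is derived)
#' @param repeats partitions per fraction (default 1)
#' @return list of class `cv_report`: one element per fraction with
#'   `fraction`, `held_out_ids`, `pred`, `observed`, `fitted_full`,
#'   `mse_labels`, `mse_fitted`, `seed`
#' @export
holdout_cv <- function(spec, X, y, neighbourhoods = NULL,
                       fractions = default_cv_fractions(), seed = 1,
                       repeats = 1) {
  stopifnot(all(fractions > 0), all(fractions < 0.5))
  X <- as.matrix(X)
  n <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(n))
  full <- fit(spec, X, y, neighbourhoods, store_loglik = FALSE)
  fitted_full <- posterior_predict(full, X, neighbourhoods)$p_mean
  reports <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    k <- round(f * n)
    if (k < 1) stop("holdout_cv: fraction ", f, " holds out zero EAs")
    accL <- accF <- 0
    held <- pred <- obs <- NULL
    for (r in seq_len(repeats)) {
      pseed <- derive_seed(seed, paste0("cv", fi, "_", r))
      hold <- with_seed(pseed, sample.int(n, k))
      sub_spec <- spec
      sub_spec$seed <- pseed
      ft <- fit(sub_spec, X[-hold, , drop = FALSE], y[-hold],
                if (!is.null(neighbourhoods)) neighbourhoods[-hold],
                store_loglik = FALSE)
      pp <- posterior_predict(ft, X[hold, , drop = FALSE],
                              if (!is.null(neighbourhoods))
                                neighbourhoods[hold],
                              seed = pseed)
      accL <- accL + mse(pp$p_mean, y[hold])
      accF <- accF + mse(pp$p_mean, fitted_full[hold])
      if (r == 1) { held <- ids[hold]; pred <- pp$p_mean; obs <- y[hold] }
    }
    list(fraction = f, held_out_ids = held, pred = pred, observed = obs,
         fitted_full = fitted_full[match(held, ids)],
         mse_labels = accL / repeats, mse_fitted = accF / repeats,
         seed = seed)
  })
  structure(reports, class = "cv_report")
}

#' Summarize a CV report as a data frame
#' @param report a `cv_report` from [holdout_cv()]
#' @return data.frame with one row per fraction
#' @export
cv_summary <- function(report) {
  data.frame(fraction = vapply(report, `[[`, 0, "fraction"),
             n_held_out = vapply(report, function(r)
               length(r$held_out_ids), 0L),
             mse_labels = vapply(report, `[[`, 0, "mse_labels"),
             mse_fitted = vapply(report, `[[`, 0, "mse_fitted"))
}
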