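quintile_levels <- c("<0.20", "0.20-0.40", "0.40-0.60", "0.60-0.80",
                     ">=0.80")

# lower-closed bins [0,.2), [.2,.4), [.4,.6), [.6,.8), [.8, 1]
quintile_bin <- function(p) {
  cut(p, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf), right = FALSE,
      labels = quintile_levels)
}

#' Posterior-predictive deprivation probabilities
#'
#' For each EA, the posterior mean and 2.5 / 97.5 percentiles of
#' `plogis(alpha + beta' x (+ V))` over the kept draws. For
#' random-effects fits, rows whose neighbourhood was seen in training use
#' its sampled effect; unseen neighbourhoods either draw a fresh
#' `V ~ N(0, sigma_v)` per posterior draw (`policy = "marginalize"`, the
#' correct predictive distribution) or set `V = 0` (`policy = "zero"`).
#'
#' @param d a `depriv_fit`
#' @param X_new predictor matrix with exactly the training columns (apply
#'   the stored standardization via [build_matrix()]'s `scaling` argument)
#' @param neighbourhoods neighbourhood ids for `X_new` rows (random-effects
#'   fits only)
#' @param policy `"marginalize"` or `"zero"` for unseen neighbourhoods
#' @param threshold classification cut-off on the posterior mean
#' @param seed seed for the marginalization draws
#' @return data.frame `ea_id`, `p_mean`, `p_low`, `p_high`,
#'   `quintile_bin`, `deprived`
#' @export
posterior_predict <- function(d, X_new, neighbourhoods = NULL,
                              policy = c("marginalize", "zero"),
                              threshold = 0.80, seed = 1) {
  stopifnot(inherits(d, "depriv_fit"))
  policy <- match.arg(policy)
  X_new <- as.matrix(X_new)
  want <- setdiff(d$param_names,
                  c("alpha", "sigma_v", "lambda",
                    grep("^V\\[", d$param_names, value = TRUE)))
  extra <- setdiff(colnames(X_new), want)
  missing_ <- setdiff(want, colnames(X_new))
  if (length(extra) || length(missing_))
    stop("posterior_predict: column mismatch with training matrix; ",
         if (length(missing_)) paste("missing:",
                                     paste(missing_, collapse = ", ")),
         if (length(extra)) paste(" unexpected:",
                                  paste(extra, collapse = ", ")))
  S <- nrow(d$draws)
  n <- nrow(X_new)
  a <- d$draws[, "alpha"]
  B <- d$draws[, want, drop = FALSE]
  has_re <- !is.null(d$re_levels)
  Vdraw <- NULL
  if (has_re) {
    if (is.null(neighbourhoods))
      stop("posterior_predict: neighbourhoods required for a ",
           "random-effects fit")
    nbc <- as.character(neighbourhoods)
    known <- nbc %in% d$re_levels
    Vmat <- d$draws[, paste0("V[", d$re_levels, "]"), drop = FALSE]
    sv <- d$draws[, "sigma_v"]
    Vnew <- if (policy == "marginalize")
      with_seed(derive_seed(seed, "predict"), rnorm(S, 0, sv)) else
        numeric(S)
    Vdraw <- matrix(0, S, n)
    if (any(known))
      Vdraw[, known] <- Vmat[, match(nbc[known], d$re_levels), drop = FALSE]
    if (any(!known)) Vdraw[, !known] <- Vnew
  }
  p_mean <- p_lo <- p_hi <- numeric(n)
  chunk <- max(1L, as.integer(2e6 / S))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    eta <- a + tcrossprod(B, X_new[s:e, , drop = FALSE]) # S x chunk
    if (has_re) eta <- eta + Vdraw[, s:e, drop = FALSE]
    P <- plogis(eta)
    p_mean[s:e] <- colMeans(P)
    qs <- apply(P, 2, quantile, probs = c(0.025, 0.975))
    p_lo[s:e] <- qs[1, ]; p_hi[s:e] <- qs[2, ]
  }
  data.frame(ea_id = rownames(X_new) %||% as.character(seq_len(n)),
             p_mean = p_mean, p_low = p_lo, p_high = p_hi,
             quintile_bin = quintile_bin(p_mean),
             deprived = p_mean >= threshold,
             stringsAsFactors = FALSE)
}

#' Flag EAs as deprived by posterior-mean probability
#'
#' Inclusive threshold: `p_mean >= threshold` (the conservative headline
#' cut-off is 0.80; 0.50 gives a superset).
#'
#' @param p a [posterior_predict()] result
#' @param threshold probability cut-off in (0, 1)
#' @return the result with its `deprived` column recomputed
#' @export
classify <- function(p, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  p$deprived <- p$p_mean >= threshold
  p
}

#' Quintile summary of predicted probabilities with population shares
#'
#' Counts of EAs and sums of resident populations per probability bin
#' (`[0, .2), [.2, .4), [.4, .6), [.6, .8), [.8, 1]`), with percentages
#' and a total row.
#'
#' @param p a [posterior_predict()] result
#' @param frame the matching [ea_frame()] (for populations)
#' @return data.frame `bin`, `n_eas`, `pct_eas`, `population`, `pct_pop`
#' @export
quintile_table <- function(p, frame) {
  pop <- frame$population[match(p$ea_id, frame$ea_id)]
  if (any(is.na(pop))) {
    warning("quintile_table: missing population for ",
            sum(is.na(pop)), " EAs; excluded: ",
            paste(head(p$ea_id[is.na(pop)], 5), collapse = ", "))
    keep <- !is.na(pop)
    p <- p[keep, , drop = FALSE]; pop <- pop[keep]
  }
  b <- quintile_bin(p$p_mean)
  n_eas <- as.integer(table(b))
  pops <- as.numeric(tapply(pop, b, sum, default = 0))
  out <- data.frame(bin = quintile_levels, n_eas = n_eas,
                    pct_eas = 100 * n_eas / sum(n_eas),
                    population = pops,
                    pct_pop = 100 * pops / sum(pops),
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(bin = "Total", n_eas = sum(n_eas), pct_eas = 100,
                        population = sum(pops), pct_pop = 100))
}

#' Contiguous clusters of deprived EAs
#'
#' Connected components (queen contiguity: shared edge or vertex) of the
#' adjacency graph restricted to flagged EAs; components of at least
#' `min_size` members are returned with their member ids and a
#' representative centroid.
#'
#' @param frame an [ea_frame()]
#' @param deprived_flags logical vector aligned with the frame rows
#' @param min_size minimum component size (default 3)
#' @return list of clusters, each `list(ids, size, centroid)`
#' @export
find_clusters <- function(frame, deprived_flags, min_size = 3) {
  stopifnot(length(deprived_flags) == nrow(frame))
  nb <- queen_adjacency(frame)
  n <- nrow(frame)
  comp <- integer(n)          # 0 = unvisited / not deprived
  cid <- 0L
  for (s in which(deprived_flags)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {    # breadth-first flood fill
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (deprived_flags[w] && comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  cents <- ea_centroids(frame)
  out <- list()
  for (g in seq_len(cid)) {
    members <- which(comp == g)
    if (length(members) >= min_size) {
      out[[length(out) + 1]] <- list(
        ids = frame$ea_id[members], size = length(members),
        centroid = colMeans(cents[members, , drop = FALSE]))
    }
  }
  out
}
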