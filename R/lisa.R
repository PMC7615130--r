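#' Spatial weights
#'
#' A `weights_matrix` stores neighbour lists and row-standardized weights:
#' every non-isolated unit's weights sum to one; isolates are flagged. The
#' underlying adjacency is symmetric.
#'
#' @param nb list of integer neighbour vectors (1-based, symmetric)
#' @return object of class `weights_matrix`
#' @export
make_weights <- function(nb) {
  n <- length(nb)
  for (i in seq_len(n)) for (j in nb[[i]]) {
    if (!(i %in% nb[[j]]))
      stop("make_weights: adjacency is not symmetric (", i, " ~ ", j, ")")
  }
  w <- lapply(nb, function(x)
    if (length(x)) rep(1 / length(x), length(x)) else numeric(0))
  structure(list(n = n, neighbours = nb, weights = w,
                 isolates = which(lengths(nb) == 0)),
            class = "weights_matrix")
}

#' @export
print.weights_matrix <- function(x, ...) {
  cat("<weights_matrix> ", x$n, " units, avg ",
      round(mean(lengths(x$neighbours)), 2), " neighbours, ",
      length(x$isolates), " isolates\n", sep = "")
  invisible(x)
}

#' Queen-contiguity weights from EA polygons
#'
#' Polygons are neighbours iff they share at least one boundary point
#' (edge or vertex); weights are row-standardized.
#'
#' @param frame an [ea_frame()]
#' @param tol touching tolerance in metres
#' @return a [make_weights()] object
#' @export
queen_weights <- function(frame, tol = 1e-6) {
  make_weights(queen_adjacency(frame, tol))
}

#' Contiguity weights on a regular lattice
#'
#' Convenience constructor for `nr x nc` grids: `"rook"` joins cells
#' sharing an edge, `"queen"` also joins diagonals. Cells are numbered
#' row-major.
#'
#' @param nr,nc lattice dimensions
#' @param type `"rook"` or `"queen"`
#' @return a [make_weights()] object
#' @export
lattice_weights <- function(nr, nc, type = c("rook", "queen")) {
  type <- match.arg(type)
  at <- function(r, c) (r - 1) * nc + c
  nb <- vector("list", nr * nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- if (type == "rook") list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)) else
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
           c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    v <- integer(0)
    for (dd in d) {
      rr <- r + dd[1]; cc <- c + dd[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) v <- c(v, at(rr, cc))
    }
    nb[[at(r, c)]] <- sort(v)
  }
  make_weights(nb)
}

# flatten a weights_matrix to edge vectors (i, j, w)
weights_edges <- function(w) {
  i <- rep(seq_len(w$n), lengths(w$neighbours))
  j <- unlist(w$neighbours, use.names = FALSE)
  list(i = i, j = j %||% integer(0),
       w = unlist(w$weights, use.names = FALSE) %||% numeric(0))
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' variable and `S0` the total weight. The pseudo p-value counts random
#' relabellings of the units whose `|I|` is at least the observed `|I|`:
#' `(hits + 1) / (n_perm + 1)`. Under the permutation null the expectation
#' of `I` is `-1 / (n - 1)`.
#'
#' @param x numeric variable (positive variance required)
#' @param w a [make_weights()] object
#' @param n_perm number of permutations (default 999)
#' @param seed permutation seed
#' @return list `I`, `pseudo_p`, `perm` (the permuted values)
#' @export
global_morans_i <- function(x, w, n_perm = 999, seed = 1) {
  n <- w$n
  stopifnot(length(x) == n, n >= 3)
  if (var(x) == 0) stop("global_morans_i: x has zero variance")
  z <- x - mean(x)
  ed <- weights_edges(w)
  S0 <- sum(ed$w)
  denom <- sum(z^2)
  I_of <- function(zz) (n / S0) * sum(ed$w * zz[ed$i] * zz[ed$j]) / denom
  I <- I_of(z)
  perm <- with_seed(derive_seed(seed, "lisa"), {
    vapply(seq_len(n_perm), function(p) I_of(z[sample.int(n)]), 0)
  })
  list(I = I, pseudo_p = (sum(abs(perm) >= abs(I)) + 1) / (n_perm + 1),
       perm = perm)
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' `I_i = z_i * sum_j w_ij z_j / m2`, `m2 = sum_k z_k^2 / n`. Under these
#' definitions the mean of `I_i` over non-isolates equals global `I`.
#' Significance uses conditional permutation: the focal value is held
#' fixed and the remaining `n - 1` values are randomly assigned to its
#' neighbour slots `n_perm` times; the two-sided pseudo p-value counts
#' permuted `|I_i|` at least as large as observed. Significant units are
#' typed by the quadrant of `(z_i, lag_i)`: high-high, low-low, high-low,
#' low-high; others are `"not-significant"`; units without neighbours are
#' `"isolate"` (local I undefined).
#'
#' @param x numeric variable
#' @param w a [make_weights()] object
#' @param n_perm permutations (default 999)
#' @param alpha significance level for typing (default 0.05)
#' @param seed permutation seed
#' @return object of class `lisa_result`: data.frame `local_i`,
#'   `pseudo_p`, `class`, plus attributes `global_i`, `global_pseudo_p`,
#'   `n_permutations`, `seed`
#' @export
local_morans_i <- function(x, w, n_perm = 999, alpha = 0.05, seed = 1) {
  n <- w$n
  stopifnot(length(x) == n, n >= 3)
  if (var(x) == 0) stop("local_morans_i: x has zero variance")
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  off <- c(0L, cumsum(lengths(w$neighbours)))
  ed <- weights_edges(w)
  res <- cpp_local_moran_perm(z, ed$j - 1L, ed$w, off, m2, n_perm,
                              derive_seed(seed, "lisa"))
  lag <- vapply(seq_len(n), function(i) {
    if (length(w$neighbours[[i]]) == 0) return(NA_real_)
    sum(w$weights[[i]] * z[w$neighbours[[i]]])
  }, 0)
  cls <- rep("not-significant", n)
  sig <- !is.na(res$pseudo_p) & res$pseudo_p < alpha
  cls[sig & z >= 0 & lag >= 0] <- "HH"
  cls[sig & z < 0 & lag < 0] <- "LL"
  cls[sig & z >= 0 & lag < 0] <- "HL"
  cls[sig & z < 0 & lag >= 0] <- "LH"
  cls[lengths(w$neighbours) == 0] <- "isolate"
  g <- global_morans_i(x, w, n_perm = n_perm, seed = seed)
  structure(data.frame(local_i = res$local_i, pseudo_p = res$pseudo_p,
                       class = cls, stringsAsFactors = FALSE),
            global_i = g$I, global_pseudo_p = g$pseudo_p,
            n_permutations = n_perm, seed = seed,
            class = c("lisa_result", "data.frame"))
}
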