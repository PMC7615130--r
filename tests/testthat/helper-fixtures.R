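# shared fixtures, built in code and cached for the duration of the run

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# the committed fixture world: 4 neighbourhoods x 25 EAs, seed 42
fixture_world <- function() {
  cached("world100", {
    gen_world(synthetic_config(seed = 42, raster_resolution_m = 60))
  })
}

# a bare 16-EA frame for geometry/pipeline plumbing tests
tiny_frame <- function(seed = 3) {
  gen_landscape(synthetic_config(n_neighbourhoods = 2,
                                 eas_per_neighbourhood = 8, seed = seed))
}

# rectangle helper (unclosed ring, counter-clockwise)
rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# minimal hand-built frame from rectangles
frame_of_rects <- function(rects, population = NULL) {
  n <- length(rects)
  ea_frame(data.frame(ea_id = sprintf("E%02d", seq_len(n)),
                      neighbourhood = "N1",
                      population = population %||% rep(100, n),
                      urban = TRUE, stringsAsFactors = FALSE),
           rects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap a draws matrix as a depriv_fit (for prediction/summary unit tests)
manual_fit <- function(draws, re_levels = NULL) {
  structure(list(draws = draws, chain = rep(1L, nrow(draws)),
                 spec = model_spec(n_iter = nrow(draws), burn_in = 1,
                                   n_chains = 1),
                 param_names = colnames(draws), re_levels = re_levels,
                 loglik = NULL,
                 diagnostics = data.frame(param = colnames(draws),
                                          rhat = 1, ess = nrow(draws)),
                 scaling = NULL),
            class = "depriv_fit")
}
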