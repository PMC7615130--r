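#' Synthetic-world configuration
#'
#' Describes a synthetic urban landscape: a rectangular lattice of square
#' EAs grouped into contiguous neighbourhoods, lognormal EA populations
#' calibrated to a median of 689 and IQR 486-940, smooth DEM / band
#' rasters, household microdata driven by a latent per-EA deprivation
#' score, and binary deprived labels drawn from the logistic model
#' `logit(p_ij) = alpha + beta' x_ij + V_j` with `V_j ~ N(0, v_sd^2)`
#' (`v_sd = 0` gives the pure fixed-effects generative process).
#'
#' @param n_neighbourhoods number of contiguous neighbourhood blocks
#' @param eas_per_neighbourhood EAs per neighbourhood block
#' @param cell_size_km EA edge length in km (default 0.2236 km, i.e. the
#'   0.05 km^2 median urban EA footprint)
#' @param true_alpha generating intercept (log-odds)
#' @param true_beta named generating coefficient vector; names must match
#'   the predictor columns the generator emits (default
#'   [default_true_beta()])
#' @param v_sd SD of neighbourhood random effects (0 disables them)
#' @param raster_resolution_m raster cell size in metres (default 30)
#' @param margin_km raster margin beyond the EA extent (>= 5 km so 5-km
#'   buffer differencing never runs off the edge)
#' @param sample_frac fraction of households enumerated per EA (census
#'   microdata emulate a 10% sample)
#' @param seed integer seed; every generator stage derives its own stream
#'   from it
#' @param constant_fields if TRUE, rasters are spatially constant
#'   (`dem_const`, `red_const`, `nir_const`) - used for analytic tests
#' @param dem_const,red_const,nir_const constants used when
#'   `constant_fields` is TRUE
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_neighbourhoods = 4,
                             eas_per_neighbourhood = 25,
                             cell_size_km = 0.2236,
                             true_alpha = -1,
                             true_beta = default_true_beta(),
                             v_sd = 0,
                             raster_resolution_m = 30,
                             margin_km = 5.2,
                             sample_frac = 0.10,
                             seed = 1,
                             constant_fields = FALSE,
                             dem_const = 50, red_const = 0.2,
                             nir_const = 0.4) {
  if (n_neighbourhoods < 1 || eas_per_neighbourhood < 1 ||
      n_neighbourhoods * eas_per_neighbourhood < 2)
    stop("synthetic_config: need at least 2 EAs")
  if (cell_size_km <= 0 || raster_resolution_m <= 0)
    stop("synthetic_config: non-positive dimensions")
  if (v_sd < 0) stop("synthetic_config: v_sd must be >= 0")
  if (margin_km < 5)
    stop("synthetic_config: margin_km must be >= 5 (buffer differencing)")
  structure(list(n_neighbourhoods = as.integer(n_neighbourhoods),
                 eas_per_neighbourhood = as.integer(eas_per_neighbourhood),
                 cell_size_km = cell_size_km, true_alpha = true_alpha,
                 true_beta = true_beta, v_sd = v_sd,
                 raster_resolution_m = raster_resolution_m,
                 margin_km = margin_km, sample_frac = sample_frac,
                 seed = as.integer(seed),
                 constant_fields = isTRUE(constant_fields),
                 dem_const = dem_const, red_const = red_const,
                 nir_const = nir_const),
            class = "synthetic_config")
}

#' Default generating coefficients for the synthetic world
#'
#' A fixed 18-vector on the scale of the default predictor matrix
#' (proportions in `[0,1]`; continuous columns standardized): moderate
#' effects on well-identified columns, several exact zeros, signs matching
#' the qualitative pattern found in deprived-area regressions (density up,
#' greenness/elevation/improved services down).
#'
#' @return named numeric vector of length 18
#' @export
default_true_beta <- function() {
  c(indoor_piped = -1.0, sachet_bottled = 0, flush_toilet = -0.8,
    pit_latrine = 0, owned = -0.6, rent_free = 0,
    less_durable_wall = 0.8, metal_sheet_roof = 0.6,
    unfinished_floor = 0, clean_fuel = 0.7, public_dump = -0.6,
    other_disposal = 0, compound_house = 0.5, improvised_dwelling = 0,
    crowding = 0.6, pop_density = 0.9, ndvi_mean = -0.8, elev_diff = -0.5)
}

# near-square factorization a*b = n with a <= b
near_square <- function(n) {
  a <- max(which(n %% seq_len(floor(sqrt(n))) == 0))
  c(a, n %/% a)
}

#' Generate the EA lattice
#'
#' Square EA polygons tiling a rectangle, partitioned into contiguous
#' rectangular neighbourhood blocks. Populations are lognormal
#' (median 689, IQR approximately 486-940); all EAs are flagged urban.
#'
#' @param cfg a [synthetic_config()]
#' @return an [ea_frame()]
#' @export
gen_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nb_dim <- near_square(cfg$n_neighbourhoods)
  ea_dim <- near_square(cfg$eas_per_neighbourhood)
  ncx <- nb_dim[2] * ea_dim[2]  # columns of EAs
  ncy <- nb_dim[1] * ea_dim[1]  # rows of EAs
  cs <- cfg$cell_size_km * 1000
  x0 <- 1e5; y0 <- 1e5        # arbitrary positive planar origin
  n <- ncx * ncy
  col <- rep(seq_len(ncx), times = ncy)
  row <- rep(seq_len(ncy), each = ncx)
  nb_col <- (col - 1) %/% ea_dim[2]
  nb_row <- (row - 1) %/% ea_dim[1]
  nb_id <- nb_row * nb_dim[2] + nb_col + 1
  geometry <- lapply(seq_len(n), function(i) {
    xa <- x0 + (col[i] - 1) * cs; ya <- y0 + (row[i] - 1) * cs
    cbind(c(xa, xa + cs, xa + cs, xa), c(ya, ya, ya + cs, ya + cs))
  })
  pop <- with_seed(derive_seed(cfg$seed, "landscape"), {
    # sdlog from matching the printed quartiles: mean of log(940/689) and
    # log(689/486), divided by the normal quartile 0.6745
    pmax(1, round(rlnorm(n, meanlog = log(689), sdlog = 0.4889)))
  })
  df <- data.frame(ea_id = sprintf("EA%05d", seq_len(n)),
                   neighbourhood = sprintf("NB%03d", nb_id),
                   population = pop, urban = TRUE,
                   stringsAsFactors = FALSE)
  ea_frame(df, geometry)
}

# standardized smooth random field: a few low-frequency plane waves
smooth_field <- function(xc, yc, n_waves = 6, wl_km = c(1.5, 8)) {
  XC <- outer(rep(1, length(yc)), xc)
  YC <- outer(yc, rep(1, length(xc)))
  f <- 0
  for (w in seq_len(n_waves)) {
    wl <- runif(1, wl_km[1], wl_km[2]) * 1000
    th <- runif(1, 0, 2 * pi)
    ph <- runif(1, 0, 2 * pi)
    f <- f + sin(2 * pi * (XC * cos(th) + YC * sin(th)) / wl + ph)
  }
  (f - mean(f)) / sd(as.numeric(f))
}

#' Generate DEM and band rasters for a landscape
#'
#' Rasters cover the EA extent plus `margin_km` on every side. The DEM is
#' a smooth low-frequency field plus white noise; red and near-infrared
#' reflectance fields are smooth and positive, so the derived NDVI is
#' always inside `(-1, 1)`.
#'
#' @param frame an [ea_frame()]
#' @param cfg a [synthetic_config()]
#' @return list with [raster_grid()]s `dem`, `ndvi`, `red`, `nir`
#' @export
gen_rasters <- function(frame, cfg) {
  if (!crs_is_planar(frame)) stop("gen_rasters: frame must have a planar CRS")
  bb <- frame_bbox(frame)
  m <- cfg$margin_km * 1000
  res <- cfg$raster_resolution_m
  xll <- bb[1] - m; yll <- bb[2] - m
  ncols <- ceiling((bb[3] + m - xll) / res)
  nrows <- ceiling((bb[4] + m - yll) / res)
  xc <- xll + (seq_len(ncols) - 0.5) * res
  yc <- yll + (nrows - seq_len(nrows) + 0.5) * res
  mk <- function(v) raster_grid(v, xll, yll, res)
  if (cfg$constant_fields) {
    one <- matrix(1, nrows, ncols)
    dem <- mk(one * cfg$dem_const)
    red <- mk(one * cfg$red_const)
    nir <- mk(one * cfg$nir_const)
  } else {
    with_seed(derive_seed(cfg$seed, "rasters"), {
      f1 <- smooth_field(xc, yc)
      f2 <- smooth_field(xc, yc)
      f3 <- smooth_field(xc, yc)
      dem <- mk(60 + 22 * f1 + matrix(rnorm(nrows * ncols, sd = 1.2),
                                      nrows, ncols))
      red <- mk(pmin(pmax(0.10 + 0.06 * f2 +
                            matrix(rnorm(nrows * ncols, sd = 0.01),
                                   nrows, ncols), 0.01), 0.9))
      nir <- mk(pmin(pmax(0.32 + 0.14 * f3 +
                            matrix(rnorm(nrows * ncols, sd = 0.015),
                                   nrows, ncols), 0.01), 0.9))
    })
  }
  list(dem = dem, ndvi = ndvi(red, nir), red = red, nir = nir)
}

# two-profile category distributions over the analysis categories of
# default_category_map(): a household samples from the deprived profile
# with probability plogis(latent score), else from the non-deprived one.
household_profiles <- function() {
  list(
    water_source = list(non = c(outdoor_or_public_tap = 0.08,
                                indoor_piped = 0.70, sachet_bottled = 0.22),
                        dep = c(outdoor_or_public_tap = 0.82,
                                indoor_piped = 0.04, sachet_bottled = 0.14)),
    toilet  = list(non = c(public_toilet = 0.06, flush_toilet = 0.82,
                           pit_latrine = 0.12),
                   dep = c(public_toilet = 0.80, flush_toilet = 0.04,
                           pit_latrine = 0.16)),
    tenure  = list(non = c(rent_perch_squat = 0.15, owned = 0.62,
                           rent_free = 0.23),
                   dep = c(rent_perch_squat = 0.85, owned = 0.07,
                           rent_free = 0.08)),
    wall    = list(non = c(durable_wall = 0.94, less_durable_wall = 0.06),
                   dep = c(durable_wall = 0.15, less_durable_wall = 0.85)),
    roof    = list(non = c(other_roof = 0.70, metal_sheet_roof = 0.30),
                   dep = c(other_roof = 0.06, metal_sheet_roof = 0.94)),
    floor   = list(non = c(finished_floor = 0.94, unfinished_floor = 0.06),
                   dep = c(finished_floor = 0.20, unfinished_floor = 0.80)),
    fuel    = list(non = c(solid_fuel = 0.72, clean_fuel = 0.28),
                   dep = c(solid_fuel = 0.14, clean_fuel = 0.86)),
    rubbish = list(non = c(collected = 0.78, public_dump = 0.14,
                           other_disposal = 0.08),
                   dep = c(collected = 0.06, public_dump = 0.84,
                           other_disposal = 0.10)),
    dwelling = list(non = c(separate_house = 0.68, compound_house = 0.28,
                            improvised_dwelling = 0.04),
                    dep = c(separate_house = 0.04, compound_house = 0.76,
                            improvised_dwelling = 0.20))
  )
}

#' Generate household microdata for a landscape
#'
#' Emulates a 10% household sample of the census. Each EA carries a latent
#' deprivation score `u_i` (a neighbourhood-level normal effect plus EA
#' noise); each household independently draws its categories from a
#' "deprived" profile with probability `plogis` of a group-specific blend
#' of `u_i`, and from a "non-deprived" profile otherwise. Household size
#' and bedroom counts follow shifted Poisson draws whose rates depend on
#' the same score, so crowding co-varies with the category signal.
#' Categories are emitted under *raw* census names, exercising the
#' category-map recode downstream.
#'
#' @param frame an [ea_frame()]
#' @param cfg a [synthetic_config()]
#' @param latent optional numeric vector overriding the latent score per EA
#'   (`-Inf` forces the non-deprived profile everywhere)
#' @return data.frame of households (`ea_id`, one column per variable
#'   group, `household_size`, `bedrooms`) with attributes `latent` (the
#'   score used) and `gen_prob` (per-group generating category
#'   probabilities per EA, for oracle tests)
#' @export
gen_households <- function(frame, cfg, latent = NULL) {
  stopifnot(nrow(frame) > 0)
  n <- nrow(frame)
  prof <- household_profiles()
  cmap <- default_category_map()
  # latent-score geometry: a neighbourhood effect plus EA noise gives the
  # shared deprivation score; each variable group blends it with its own
  # idiosyncratic component (rho) so group proportions correlate with the
  # score without being collinear with each other - coefficients must stay
  # individually identifiable for parameter-recovery checks
  rho <- 0.45
  with_seed(derive_seed(cfg$seed, "households"), {
    if (is.null(latent)) {
      nb <- factor(frame$neighbourhood)
      b <- rnorm(nlevels(nb), sd = 1.4)[as.integer(nb)]
      u <- b + rnorm(n, sd = 1.0)
    } else {
      stopifnot(length(latent) == n)
      u <- latent
    }
    sd_u <- 1.72  # nominal scale of the latent score
    n_hh <- pmax(1L, as.integer(round(cfg$sample_frac * frame$population / 4.2)))
    total <- sum(n_hh)
    ea_idx <- rep(seq_len(n), n_hh)
    out <- data.frame(ea_id = frame$ea_id[ea_idx], stringsAsFactors = FALSE)
    gen_prob <- list()
    for (g in names(prof)) {
      zg <- rnorm(n, sd = sd_u)
      ug <- rho * u + sqrt(1 - rho^2) * zg
      ug[is.infinite(u)] <- u[is.infinite(u)]   # keep -Inf/-+Inf overrides exact
      pi_g <- plogis(ug)
      pn <- prof[[g]]$non; pd <- prof[[g]]$dep
      cats <- names(pn)
      pm <- outer(1 - pi_g, pn) + outer(pi_g, pd)  # n x cats generating probs
      colnames(pm) <- cats
      gen_prob[[g]] <- pm
      phh <- pm[ea_idx, , drop = FALSE]
      ut <- upper.tri(diag(length(cats)), diag = TRUE) * 1
      cum <- phh %*% ut
      cum[, length(cats)] <- 1
      draw <- runif(total)
      pick <- cats[max.col(cum >= draw, ties.method = "first")]
      # emit a raw census name mapping to the drawn analysis category
      raws <- lapply(cats, function(a)
        names(cmap[[g]]$categories)[cmap[[g]]$categories == a])
      names(raws) <- cats
      out[[g]] <- vapply(pick, function(a) {
        r <- raws[[a]]
        if (length(r) == 1) r else r[sample.int(length(r), 1)]
      }, "", USE.NAMES = FALSE)
    }
    pi0 <- plogis(u)[ea_idx]
    pi0[is.nan(pi0)] <- 0
    out$household_size <- 1L + rpois(total, 2.0 + 2.4 * pi0)
    out$bedrooms <- 1L + rpois(total, pmax(0.05, 1.3 - 1.0 * pi0))
    attr(out, "latent") <- u
    attr(out, "gen_prob") <- gen_prob
    out
  })
}

#' Draw deprived labels from the logistic generative model
#'
#' `logit(p_ij) = alpha + beta' x_ij + V_j`, `V_j ~ N(0, v_sd^2)`,
#' `Y_ij ~ Bernoulli(p_ij)`. With `v_sd = 0` this is exactly the
#' fixed-effects model.
#'
#' @param X predictor matrix, rows aligned with `frame`; must contain every
#'   name of `cfg$true_beta`
#' @param frame an [ea_frame()]
#' @param cfg a [synthetic_config()]
#' @return list with `y` (0/1 labels), `p` (true probabilities), `V`
#'   (named neighbourhood effects) and `eta` (linear predictor)
#' @export
gen_labels <- function(X, frame, cfg) {
  stopifnot(nrow(X) == nrow(frame))
  beta <- cfg$true_beta
  miss <- setdiff(names(beta), colnames(X))
  if (length(miss))
    stop("gen_labels: true_beta names not in X: ", paste(miss, collapse = ", "))
  with_seed(derive_seed(cfg$seed, "labels"), {
    nb <- factor(frame$neighbourhood)
    V <- rnorm(nlevels(nb), sd = cfg$v_sd)
    names(V) <- levels(nb)
    eta <- as.numeric(cfg$true_alpha + X[, names(beta), drop = FALSE] %*% beta +
                        V[as.integer(nb)])
    p <- plogis(eta)
    y <- rbinom(length(p), 1, p)
    list(y = y, p = p, V = V, eta = eta)
  })
}

#' Generate a complete synthetic world
#'
#' Runs the full generator: landscape, rasters, households, predictor
#' matrix (continuous columns standardized) and labels; the labels are
#' attached to the frame as a `deprived` column.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `frame`, `rasters`, `households`, `X` (predictor
#'   matrix), `labels` (full [gen_labels()] output) and `cfg`
#' @export
gen_world <- function(cfg = synthetic_config()) {
  frame <- gen_landscape(cfg)
  rasters <- gen_rasters(frame, cfg)
  hh <- gen_households(frame, cfg)
  X <- build_matrix(frame, hh, default_category_map(),
                    dem = rasters$dem, ndvi_raster = rasters$ndvi,
                    standardize = TRUE)
  labels <- gen_labels(X, frame, cfg)
  frame$deprived <- labels$y
  list(frame = frame, rasters = rasters, households = hh, X = X,
       labels = labels, cfg = cfg)
}

#' Write a synthetic bundle to disk
#'
#' Emits the artifacts the real pipeline would consume: EA polygons as
#' GeoJSON, households as CSV, DEM and NDVI as ESRI ASCII grids, and the
#' generating truth as JSON.
#'
#' @param world output of [gen_world()]
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of file paths written
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    eas = file.path(dir, "eas.geojson"),
    households = file.path(dir, "households.csv"),
    dem = file.path(dir, "dem.asc"),
    ndvi = file.path(dir, "ndvi.asc"),
    truth = file.path(dir, "truth.json"))
  write_ea_geojson(world$frame, paths["eas"])
  hh <- world$households
  attributes(hh)[c("latent", "gen_prob")] <- NULL
  write.csv(hh, paths["households"], row.names = FALSE)
  write_asc(world$rasters$dem, paths["dem"])
  write_asc(world$rasters$ndvi, paths["ndvi"])
  jsonlite::write_json(list(true_alpha = world$cfg$true_alpha,
                            true_beta = as.list(world$cfg$true_beta),
                            v_sd = world$cfg$v_sd,
                            seed = world$cfg$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
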