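# synthetic-data generator: lattice, rasters, households, labels

test_that("gen_landscape tiles a rectangle with contiguous neighbourhoods", {
  cfg <- synthetic_config(n_neighbourhoods = 4, eas_per_neighbourhood = 25,
                          seed = 9)
  fr <- gen_landscape(cfg)
  expect_equal(nrow(fr), 100)
  expect_length(unique(fr$neighbourhood), 4)
  expect_false(any(duplicated(fr$ea_id)))
  expect_true(all(fr$urban))
  # areas sum to the bounding rectangle => tiling with no overlap
  bb <- deprivmap:::frame_bbox(fr)
  expect_equal(sum(ea_areas_km2(fr)) * 1e6,
               (bb[3] - bb[1]) * (bb[4] - bb[2]), tolerance = 1e-9)
  # each EA has the stated footprint
  expect_equal(ea_areas_km2(fr), rep(cfg$cell_size_km^2, 100),
               tolerance = 1e-6, ignore_attr = TRUE)
  # neighbourhood blocks are spatially contiguous (queen-connected)
  nb <- deprivmap:::queen_adjacency(fr)
  for (g in unique(fr$neighbourhood)) {
    members <- which(fr$neighbourhood == g)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(nb[frontier]), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(seen, members)
  }
  expect_error(synthetic_config(n_neighbourhoods = 0), "at least 2")
  expect_error(synthetic_config(cell_size_km = -1), "non-positive")
})

test_that("EA populations match the printed median within sampling error", {
  fr <- gen_landscape(synthetic_config(n_neighbourhoods = 400,
                                       eas_per_neighbourhood = 25, seed = 5))
  expect_equal(nrow(fr), 10000)
  med <- median(fr$population)
  expect_gt(med, 650)
  expect_lt(med, 730)
  # quartiles in the right neighbourhood of the printed IQR
  q <- quantile(fr$population, c(0.25, 0.75))
  expect_gt(q[1], 420)
  expect_lt(q[2], 1050)
})

test_that("the generator is deterministic under a fixed config", {
  cfg <- synthetic_config(n_neighbourhoods = 2, eas_per_neighbourhood = 8,
                          raster_resolution_m = 200, seed = 77)
  w1 <- gen_world(cfg)
  w2 <- gen_world(cfg)
  expect_identical(w1$frame, w2$frame)
  expect_identical(w1$rasters$dem$values, w2$rasters$dem$values)
  expect_identical(w1$households, w2$households)
  expect_identical(w1$labels$y, w2$labels$y)
})

test_that("gen_rasters covers the EA extent plus the 5-km margin", {
  cfg <- synthetic_config(n_neighbourhoods = 2, eas_per_neighbourhood = 8,
                          raster_resolution_m = 100, seed = 4)
  fr <- gen_landscape(cfg)
  ras <- gen_rasters(fr, cfg)
  # independent bounds from the polygon coordinates themselves
  allxy <- do.call(rbind, fr$geometry)
  for (r in list(ras$dem, ras$ndvi)) {
    rb <- deprivmap:::raster_bbox(r)
    expect_lte(rb[1], min(allxy[, 1]) - 5000)
    expect_lte(rb[2], min(allxy[, 2]) - 5000)
    expect_gte(rb[3], max(allxy[, 1]) + 5000)
    expect_gte(rb[4], max(allxy[, 2]) + 5000)
  }
  v <- ras$ndvi$values[ras$ndvi$values != ras$ndvi$nodata]
  expect_gte(min(v), -1)
  expect_lte(max(v), 1)
})

test_that("constant raster fields give constant zonal means", {
  cfg <- synthetic_config(n_neighbourhoods = 2, eas_per_neighbourhood = 8,
                          raster_resolution_m = 100, seed = 4,
                          constant_fields = TRUE, dem_const = 123,
                          red_const = 0.2, nir_const = 0.6)
  fr <- gen_landscape(cfg)
  ras <- gen_rasters(fr, cfg)
  expect_true(all(ras$dem$values == 123))
  expect_equal(zonal_mean(ras$dem, fr), rep(123, nrow(fr)))
  # NDVI of constant bands: (0.6 - 0.2) / 0.8 = 0.5 everywhere
  expect_equal(zonal_mean(ras$ndvi, fr), rep(0.5, nrow(fr)))
  expect_equal(elevation_diff(ras$dem, fr), rep(0, nrow(fr)))
})

test_that("households: support constraints and degenerate latent", {
  cfg <- synthetic_config(seed = 21)
  fr <- fixture_world()$frame
  hh <- gen_households(fr, cfg)
  expect_true(all(hh$bedrooms >= 1))
  expect_true(all(hh$household_size >= 1))
  expect_true(all(hh$ea_id %in% fr$ea_id))
  # latent -Inf => every household from the non-deprived profile
  hh0 <- gen_households(fr, cfg, latent = rep(-Inf, nrow(fr)))
  agg <- aggregate_census(hh0)
  prof <- deprivmap:::household_profiles()
  # baseline rates of two deprived-leaning categories (pooled binomial
  # error ~ 0.006 at ~1600 households; allow ~4 sd)
  expect_lt(abs(weighted.mean(agg$unfinished_floor, agg$n_households) -
                  prof$floor$non[["unfinished_floor"]]), 0.025)
  expect_lt(abs(weighted.mean(agg$less_durable_wall, agg$n_households) -
                  prof$wall$non[["less_durable_wall"]]), 0.025)
})

test_that("EA category proportions track their generating probabilities", {
  # binomial sampling-error oracle over 1,000 EAs
  cfg <- synthetic_config(n_neighbourhoods = 40, eas_per_neighbourhood = 25,
                          seed = 31)
  fr <- gen_landscape(cfg)
  hh <- gen_households(fr, cfg)
  gp <- attr(hh, "gen_prob")
  agg <- aggregate_census(hh)
  expect_equal(agg$ea_id, fr$ea_id)
  mean_hh <- mean(agg$n_households)
  for (case in list(c("toilet", "flush_toilet"),
                    c("wall", "less_durable_wall"),
                    c("dwelling", "compound_house"))) {
    mad <- mean(abs(agg[[case[2]]] - gp[[case[1]]][, case[2]]))
    expect_lt(mad, 3 / sqrt(mean_hh))
  }
})

test_that("gen_labels follows the stated logistic generative model", {
  fr <- gen_landscape(synthetic_config(n_neighbourhoods = 400,
                                       eas_per_neighbourhood = 25, seed = 2))
  X <- matrix(0, nrow(fr), 1, dimnames = list(fr$ea_id, "z"))
  null_cfg <- function(a, v = 0, seed = 8)
    synthetic_config(n_neighbourhoods = 400, eas_per_neighbourhood = 25,
                     true_alpha = a, true_beta = c(z = 0), v_sd = v,
                     seed = seed)
  # null model: p = 0.5 exactly
  lab <- gen_labels(X, fr, null_cfg(0))
  expect_true(all(lab$p == 0.5))
  expect_gt(mean(lab$y), 0.48)
  expect_lt(mean(lab$y), 0.52)
  # closed-form prevalence at alpha = -2
  lab2 <- gen_labels(X, fr, null_cfg(-2))
  expect_equal(mean(lab2$y), plogis(-2),
               tolerance = 3 * sqrt(0.119 * 0.881 / 1e4) / plogis(-2))
  # v_sd = 1: SD of neighbourhood-mean logits ~ 1 over 400 neighbourhoods
  lab3 <- gen_labels(X, fr, null_cfg(0, v = 1))
  nb_logit <- tapply(qlogis(lab3$p), fr$neighbourhood, mean)
  expect_equal(sd(nb_logit), 1, tolerance = 0.15)
  expect_equal(sd(lab3$V), 1, tolerance = 0.15)
  # dimension error
  bad <- synthetic_config(true_beta = c(nope = 1))
  expect_error(gen_labels(X, fr, bad), "not in X")
})

test_that("generator density matches the model likelihood on its own draws", {
  w <- fixture_world()
  tr <- w$labels
  ll <- log_likelihood(list(alpha = w$cfg$true_alpha, beta = w$cfg$true_beta,
                            V = tr$V),
                       w$X[, names(w$cfg$true_beta)], tr$y,
                       w$frame$neighbourhood)
  direct <- sum(tr$y * log(tr$p) + (1 - tr$y) * log(1 - tr$p))
  expect_equal(ll$total, direct, tolerance = 1e-10)
})

test_that("world writers emit readable artifacts", {
  w <- fixture_world()
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  fr2 <- read_ea_geojson(paths["eas"])
  expect_equal(fr2$ea_id, w$frame$ea_id)
  expect_equal(fr2$population, w$frame$population)
  expect_equal(fr2$geometry[[5]], w$frame$geometry[[5]])
  dem2 <- read_asc(paths["dem"])
  expect_equal(dem2$values, w$rasters$dem$values, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(dem2$cellsize, w$rasters$dem$cellsize)
})
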