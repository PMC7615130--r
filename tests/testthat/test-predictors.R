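# predictor construction: census aggregation, crowding, density, zonal
# statistics, NDVI, elevation differencing, matrix assembly

toy_households <- function(toilets, ea = "E1") {
  data.frame(ea_id = ea, toilet = toilets,
             household_size = 4, bedrooms = 2, stringsAsFactors = FALSE)
}

test_that("aggregate_census computes group proportions", {
  h <- toy_households(rep("flush", 10))
  a <- aggregate_census(h)
  expect_equal(a$flush_toilet, 1.0)
  expect_equal(a$pit_latrine, 0.0)
  h2 <- data.frame(ea_id = "E1",
                   water_source = c(rep("indoor_piped", 4),
                                    rep("public_tap", 6)),
                   stringsAsFactors = FALSE)
  a2 <- aggregate_census(h2)
  expect_equal(a2$indoor_piped, 0.4)   # brute-force count: 4 of 10
  expect_equal(a2$sachet_bottled, 0)
  expect_error(aggregate_census(toy_households("longdrop")), "longdrop")
})

test_that("group proportions partition unity on random tables", {
  cmap <- default_category_map()
  set.seed(42)
  for (rep_ in 1:5) {
    n <- 50
    h <- data.frame(ea_id = sample(c("A", "B", "C"), n, TRUE),
                    stringsAsFactors = FALSE)
    for (g in names(cmap))
      h[[g]] <- sample(names(cmap[[g]]$categories), n, TRUE)
    a <- aggregate_census(h, cmap)
    for (g in names(cmap)) {
      nonref <- setdiff(unique(unname(cmap[[g]]$categories)),
                        cmap[[g]]$reference)
      s <- rowSums(a[, nonref, drop = FALSE])
      expect_true(all(s <= 1 + 1e-12))
      # implied reference proportion stays in [0, 1]
      expect_true(all(1 - s >= -1e-12))
    }
  }
})

test_that("crowding is the mean persons-per-bedroom ratio", {
  one <- data.frame(ea_id = "E1", household_size = 6, bedrooms = 2)
  expect_equal(crowding(one)$crowding, 3.0)
  two <- data.frame(ea_id = "E1", household_size = c(4, 2),
                    bedrooms = c(2, 1))
  expect_equal(crowding(two)$crowding, 2.0)
  # ratio invariance under common scaling
  k <- 3
  two_k <- transform(two, household_size = household_size * k,
                     bedrooms = bedrooms * k)
  expect_equal(crowding(two_k)$crowding, crowding(two)$crowding)
  expect_error(crowding(data.frame(ea_id = "E1", household_size = 2,
                                   bedrooms = 0)), "bedrooms")
})

test_that("pop_density divides population by polygon area in km^2", {
  # 200 m x 250 m rectangle = 0.05 km^2 (the median urban EA footprint)
  fr <- frame_of_rects(list(rect_ring(0, 0, 200, 250)), population = 500)
  expect_equal(pop_density(fr), 10000)
  fr2 <- fr; fr2$population <- 1000
  expect_equal(pop_density(fr2), 2 * pop_density(fr))
  attr(fr, "crs") <- "EPSG:4326"
  expect_error(pop_density(fr), "planar")
})

test_that("zonal_mean matches brute-force cell enumeration", {
  # 2x2 raster {1,2,3,4} fully inside one polygon -> 2.5
  r <- raster_grid(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE), 0, 0, 10)
  fr <- frame_of_rects(list(rect_ring(-5, -5, 25, 25)))
  expect_equal(zonal_mean(r, fr), 2.5)
  # nodata masked out: {1, nodata, 3, nodata} -> 2
  r2 <- raster_grid(matrix(c(1, -9999, 3, -9999), 2, 2, byrow = TRUE),
                    0, 0, 10)
  expect_equal(zonal_mean(r2, fr), 2.0)
  # invariance to padding with nodata
  pad <- matrix(-9999, 6, 6)
  pad[3:4, 3:4] <- matrix(c(1, -9999, 3, -9999), 2, 2, byrow = TRUE)
  r3 <- raster_grid(pad, -20, -20, 10)
  expect_equal(zonal_mean(r3, fr), 2.0)
  # sub-cell polygon falls back to the centroid cell
  small <- frame_of_rects(list(rect_ring(11, 11, 13, 13)))
  expect_equal(zonal_mean(r, small), 2)
  # polygon fully outside the raster
  out <- frame_of_rects(list(rect_ring(100, 100, 120, 120)))
  expect_error(zonal_mean(r, out), "outside")
})

test_that("zonal_mean agrees with an independent oracle on random fields", {
  set.seed(1)
  r <- raster_grid(matrix(rnorm(400), 20, 20), 0, 0, 5)
  fr <- frame_of_rects(list(rect_ring(12, 7, 63, 48),
                            rect_ring(40, 40, 99, 99)))
  got <- zonal_mean(r, fr)
  for (i in 1:2) {
    g <- fr$geometry[[i]]
    acc <- c()
    for (row in 1:20) for (col in 1:20) {   # brute force, all cells
      x <- 0 + (col - 0.5) * 5; y <- 0 + (20 - row + 0.5) * 5
      if (x > min(g[, 1]) && x < max(g[, 1]) &&
          y > min(g[, 2]) && y < max(g[, 2]))
        acc <- c(acc, r$values[row, col])
    }
    expect_equal(got[i], mean(acc))
  }
})

test_that("ndvi follows its defining ratio", {
  mk <- function(v) raster_grid(matrix(v, 1, 1), 0, 0, 30)
  expect_equal(ndvi(mk(0.3), mk(0.3))$values[1, 1], 0)
  expect_equal(ndvi(mk(0.2), mk(0.6))$values[1, 1], 0.5)
  z <- ndvi(mk(0), mk(0))
  expect_equal(z$values[1, 1], z$nodata)
  expect_error(ndvi(mk(0.2), raster_grid(matrix(0.5, 1, 1), 5, 0, 30)),
               "align")
})

test_that("elevation_diff recovers a constructed step raster", {
  # 10 m plateau on a 0 m plain; EA sits on the plateau
  v <- matrix(0, 60, 60)
  v[26:35, 26:35] <- 10   # cell centres 2550-3450 m: exactly the EA below
  dem <- raster_grid(v, 0, 0, 100)       # 6 km x 6 km, 100 m cells
  fr0 <- frame_of_rects(list(rect_ring(2500, 2500, 3500, 3500)))
  # shift so the 0.5 km buffer fits with margin; use small buffer
  d <- elevation_diff(dem, fr0, buffer_km = 0.5)
  expect_equal(d, 10, tolerance = 0.05)
  # antisymmetry: swapping plateau and plain negates the value
  dem2 <- raster_grid(10 - v, 0, 0, 100)
  expect_equal(elevation_diff(dem2, fr0, buffer_km = 0.5), -d,
               tolerance = 1e-9)
  # insufficient coverage is a named error
  expect_error(elevation_diff(dem, fr0, buffer_km = 10), "E01")
})

test_that("build_matrix emits the 18 default predictors and a reusable transform", {
  w <- fixture_world()
  X <- w$X
  expect_equal(ncol(X), 18)
  expect_setequal(colnames(X), default_predictors())
  expect_false(any(is.na(X)))
  expect_true(all(abs(colMeans(X)) < 1e-10))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-10))
  # re-applying the stored transform reproduces the matrix bit-for-bit
  X2 <- build_matrix(w$frame, w$households, default_category_map(),
                     dem = w$rasters$dem, ndvi_raster = w$rasters$ndvi,
                     scaling = attr(X, "scaling"))
  expect_identical(unclass(X2)[, colnames(X)], unclass(X)[, colnames(X)])
  expect_error(build_matrix(w$frame, w$households,
                            predictors = c("crowding", "bogus_column")),
               "bogus_column")
})

test_that("predictor CSV round-trips with its sidecar", {
  w <- fixture_world()
  path <- file.path(withr::local_tempdir(), "pred.csv")
  write_predictors(w$X, path)
  X2 <- read_predictors(path)
  expect_equal(unclass(X2), unclass(w$X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(X2, "scaling")$scale, attr(w$X, "scaling")$scale,
               tolerance = 1e-12)
})

test_that("collinearity_report flags correlated pairs", {
  set.seed(7)
  X <- cbind(a = rnorm(10000), b = rnorm(10000))
  X <- cbind(X, dup = X[, "a"], neg = -X[, "b"])
  rep_ <- collinearity_report(X)
  pick <- function(v1, v2) rep_[rep_$var1 %in% c(v1, v2) &
                                  rep_$var2 %in% c(v1, v2), ]
  expect_equal(pick("a", "dup")$r, 1.0)
  expect_true(pick("a", "dup")$flagged)
  expect_equal(pick("b", "neg")$r, -1.0)
  expect_true(pick("b", "neg")$flagged)
  # independent columns stay uncorrelated at n = 10,000
  expect_lt(abs(pick("a", "b")$r), 0.05)
  expect_warning(collinearity_report(cbind(X[, 1:2], const = 1)),
                 "zero-variance")
})
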