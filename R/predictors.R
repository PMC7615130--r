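#' Aggregate household categories to EA-level proportions
#'
#' For every EA and every non-reference analysis category, the proportion
#' of the EA's sampled households falling in it (after recoding raw census
#' categories through the category map). Within each variable group the
#' proportions, reference included, partition unity.
#'
#' @param h household table: `ea_id` plus one raw-category column per
#'   variable group named in `cmap`
#' @param cmap a category map, see [default_category_map()]
#' @return data.frame: `ea_id`, `n_households`, one proportion column per
#'   non-reference analysis category
#' @export
aggregate_census <- function(h, cmap = default_category_map()) {
  stopifnot(nrow(h) > 0)
  validate_category_map(cmap)
  groups <- intersect(names(cmap), names(h))
  if (!length(groups)) stop("aggregate_census: no category-map group ",
                            "columns found in the household table")
  ea <- factor(h$ea_id, levels = unique(h$ea_id))
  n_hh <- as.integer(table(ea))
  out <- data.frame(ea_id = levels(ea), n_households = n_hh,
                    stringsAsFactors = FALSE)
  for (g in groups) {
    map <- cmap[[g]]$categories
    raw <- as.character(h[[g]])
    unknown <- setdiff(unique(raw), names(map))
    if (length(unknown))
      stop("aggregate_census: unknown raw categories in group '", g, "': ",
           paste(unknown, collapse = ", "))
    ana <- map[raw]
    cats <- analysis_categories(cmap[g])[[1]]
    counts <- table(ea, factor(ana, levels = cats))
    props <- counts / n_hh
    for (cc in cats[-1]) out[[cc]] <- as.numeric(props[, cc])
  }
  out
}

#' Mean persons-per-bedroom crowding per EA
#'
#' The household-level ratio `household_size / bedrooms`, averaged over
#' each EA's households.
#'
#' @param h household table with `ea_id`, `household_size`, `bedrooms`
#' @return data.frame `ea_id`, `crowding`
#' @export
crowding <- function(h) {
  if (any(h$bedrooms < 1))
    stop("crowding: bedrooms must be >= 1 for every household")
  ratio <- h$household_size / h$bedrooms
  agg <- tapply(ratio, factor(h$ea_id, levels = unique(h$ea_id)), mean)
  data.frame(ea_id = names(agg), crowding = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Population density per EA (persons per square kilometre)
#' @param frame an [ea_frame()] in a planar CRS
#' @return numeric vector aligned with the frame rows
#' @export
pop_density <- function(frame) {
  if (!crs_is_planar(frame))
    stop("pop_density: frame CRS is geographic; project to planar metres first")
  a <- ea_areas_km2(frame)
  if (any(a <= 0)) stop("pop_density: non-positive polygon area")
  frame$population / a
}

#' Assemble the EA-level predictor matrix
#'
#' Builds the design matrix used by the deprivation models: one proportion
#' column per non-reference analysis category, plus `crowding`,
#' `pop_density`, `ndvi_mean` (zonal NDVI mean) and `elev_diff` (EA mean
#' elevation minus the `buffer_km` surroundings). All columns are
#' standardized when `standardize = TRUE` (a common prior SD across
#' coefficients presumes a common column scale) and the reversible
#' transform is recorded in the `"scaling"` attribute; pass a stored
#' `scaling` to re-apply the training transform to a prediction region.
#'
#' EAs present in the frame but absent from the household table are kept
#' with `NA` proportions and listed in the `"flagged"` attribute rather
#' than silently imputed.
#'
#' @param frame an [ea_frame()]
#' @param h household table
#' @param cmap category map
#' @param dem DEM [raster_grid()] (or NULL to omit `elev_diff`)
#' @param ndvi_raster NDVI [raster_grid()] (or NULL to omit `ndvi_mean`)
#' @param standardize standardize continuous columns (default TRUE)
#' @param scaling optional stored scaling (data.frame column/center/scale)
#'   from a previous call; overrides `standardize`
#' @param buffer_km elevation-difference buffer radius
#' @param predictors optional character subset of columns to keep (a
#'   configuration error if not available)
#' @return numeric matrix (rows named by `ea_id`) of class
#'   `predictor_matrix`, with attributes `scaling` and `flagged`
#' @export
build_matrix <- function(frame, h, cmap = default_category_map(),
                         dem = NULL, ndvi_raster = NULL, standardize = TRUE,
                         scaling = NULL, buffer_km = 5, predictors = NULL) {
  props <- aggregate_census(h, cmap)
  cw <- crowding(h)
  tab <- merge(props, cw, by = "ea_id", all = TRUE, sort = FALSE)
  tab <- tab[match(frame$ea_id, tab$ea_id), , drop = FALSE]
  flagged <- frame$ea_id[is.na(tab$n_households) | tab$n_households == 0]
  tab$ea_id <- frame$ea_id
  tab$pop_density <- pop_density(frame)
  if (!is.null(ndvi_raster)) tab$ndvi_mean <- zonal_mean(ndvi_raster, frame)
  if (!is.null(dem)) tab$elev_diff <- elevation_diff(dem, frame, buffer_km)
  cols <- setdiff(names(tab), c("ea_id", "n_households"))
  if (!is.null(predictors)) {
    bad <- setdiff(predictors, cols)
    if (length(bad))
      stop("build_matrix: configured predictors not available: ",
           paste(bad, collapse = ", "))
    cols <- predictors
  }
  X <- as.matrix(tab[, cols, drop = FALSE])
  rownames(X) <- frame$ea_id
  # every column is centred/scaled, proportions included: a common prior SD
  # across coefficients is only meaningful when the columns share a scale,
  # and coefficient recovery is assessed on the model's own scale
  if (!is.null(scaling)) {
    for (i in seq_len(nrow(scaling))) {
      cc <- scaling$column[i]
      if (cc %in% cols)
        X[, cc] <- (X[, cc] - scaling$center[i]) / scaling$scale[i]
    }
  } else if (standardize) {
    ctr <- colMeans(X, na.rm = TRUE)
    scl <- apply(X, 2, sd, na.rm = TRUE)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    scaling <- data.frame(column = cols, center = as.numeric(ctr),
                          scale = as.numeric(scl), stringsAsFactors = FALSE)
  }
  structure(X, scaling = scaling, flagged = flagged,
            class = c("predictor_matrix", class(X)))
}

#' Pairwise Pearson correlations of predictor columns, with flags
#'
#' Zero-variance columns are excluded with a warning; pairs with
#' `|r| >= threshold` are flagged as collinearity candidates.
#'
#' @param X numeric predictor matrix (>= 2 columns, >= 3 rows)
#' @param threshold flagging threshold on `|r|` (default 0.7)
#' @return data.frame `var1`, `var2`, `r`, `flagged`, sorted by `|r|`
#' @export
collinearity_report <- function(X, threshold = 0.7) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2, nrow(X) >= 3)
  v <- apply(X, 2, var, na.rm = TRUE)
  if (any(v == 0)) {
    warning("collinearity_report: excluding zero-variance columns: ",
            paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  cm <- cor(X, use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(var1 = colnames(cm)[idx[, 1]],
                    var2 = colnames(cm)[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out$flagged <- abs(out$r) >= threshold
  out[order(-abs(out$r)), , drop = FALSE]
}

#' Write / read a predictor matrix as CSV plus a JSON sidecar
#'
#' The CSV is keyed by `ea_id`; the sidecar records the standardization
#' transform and flagged EAs so the training transform can be re-applied
#' at prediction time.
#'
#' @param X a `predictor_matrix`
#' @param path CSV path (sidecar written next to it as `<path>.json`)
#' @export
write_predictors <- function(X, path) {
  df <- data.frame(ea_id = rownames(X), as.data.frame(unclass(X)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  sc <- attr(X, "scaling")
  jsonlite::write_json(
    list(scaling = sc, flagged = attr(X, "flagged"),
         columns = colnames(X)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictors
#' @return `read_predictors`: the reconstructed `predictor_matrix`
#' @export
read_predictors <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(df[, setdiff(names(df), "ea_id"), drop = FALSE])
  rownames(X) <- df$ea_id
  structure(X, scaling = meta$scaling,
            flagged = as.character(meta$flagged %||% character(0)),
            class = c("predictor_matrix", class(X)))
}
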