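#' Per-colony mean isotope values with coordinates
#'
#' The kriging basemaps interpolate colony means, not individual feathers;
#' every colony contributes regardless of sample size (single-sample colonies
#' report their one value).
#'
#' @param feathers a `feather_table`.
#' @return data.frame with `colony_id`, `latitude`, `longitude`, `n`, and the
#'   mean of each isotope.
#' @export
colony_means <- function(feathers) {
  f <- factor(feathers$colony_id)
  out <- data.frame(
    colony_id = levels(f),
    latitude = as.numeric(tapply(feathers$latitude, f, `[`, 1)),
    longitude = as.numeric(tapply(feathers$longitude, f, `[`, 1)),
    n = as.integer(table(f)),
    stringsAsFactors = FALSE)
  for (col in ISO_COLS)
    out[[col]] <- as.numeric(tapply(feathers[[col]], f, mean))
  out
}

# Pairwise / cross distance in km between (lon, lat) matrices.
geo_dist_km <- function(p1, p2 = NULL, method = c("haversine", "planar")) {
  method <- match.arg(method)
  if (is.null(p2)) p2 <- p1
  if (method == "haversine") {
    geosphere::distm(p1, p2, fun = geosphere::distHaversine) / 1000
  } else {
    # equirectangular approximation at the mean latitude
    km_lat <- 111.32
    km_lon <- km_lat * cos(mean(c(p1[, 2], p2[, 2])) * pi / 180)
    outer(seq_len(nrow(p1)), seq_len(nrow(p2)), function(i, j)
      sqrt(((p1[i, 1] - p2[j, 1]) * km_lon)^2 +
             ((p1[i, 2] - p2[j, 2]) * km_lat)^2))
  }
}

#' Semivariance of a fitted variogram model at distance h
#'
#' The stable model is
#' \eqn{\gamma(h) = nugget + sill (1 - e^{-(h/range)^{shape}})} for h > 0 and
#' 0 at h = 0; shape = 1 is the exponential model and shape = 2 the Gaussian
#' model.
#'
#' @param model a `variogram_model`.
#' @param h distances (km), any shape.
#' @return Semivariances, same shape as `h`.
#' @export
variogram_gamma <- function(model, h) {
  g <- model$nugget + model$partial_sill *
    (1 - exp(-(h / model$range_km)^model$shape))
  g[h == 0] <- 0
  g
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Squared half-differences of the value between all point pairs, averaged in
#' `n_bins` equal-width distance bins up to half the maximum pairwise
#' distance (the standard geostatistical default).
#'
#' @param points data.frame with `latitude`, `longitude` and the value column.
#' @param value name of the value column.
#' @param n_bins number of distance bins.
#' @param max_dist upper distance cutoff in km (default half the maximum
#'   pairwise distance).
#' @param distance `"haversine"` (great-circle, default) or `"planar"`.
#' @return data.frame with `dist` (bin mean distance, km), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(points, value, n_bins = 12, max_dist = NULL,
                                distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  z <- points[[value]]
  stopifnot(!is.null(z), nrow(points) >= 5)
  d <- geo_dist_km(cbind(points$longitude, points$latitude), method = distance)
  iu <- upper.tri(d)
  dd <- d[iu]
  if (max(dd) == 0) stop("all points are collocated")
  gg <- 0.5 * outer(z, z, `-`)[iu]^2
  max_dist <- max_dist %||% (max(dd) / 2)
  keep <- dd > 0 & dd <= max_dist
  bins <- cut(dd[keep], breaks = seq(0, max_dist, length.out = n_bins + 1),
              include.lowest = TRUE)
  out <- data.frame(
    dist = as.numeric(tapply(dd[keep], bins, mean)),
    gamma = as.numeric(tapply(gg[keep], bins, mean)),
    n_pairs = as.integer(table(bins)))
  out[out$n_pairs > 0, , drop = FALSE]
}

#' Fit a variogram model to point data
#'
#' Bins the empirical semivariogram and fits the chosen family by weighted
#' least squares (weights = pair counts), minimizing the mean squared error
#' of the fit. The stable family's shape exponent is constrained to (0, 2];
#' five multi-starts over range and shape guard against local minima.
#' `"exponential"` and `"gaussian"` fix the shape at 1 and 2.
#'
#' @inheritParams empirical_variogram
#' @param family `"stable"`, `"exponential"` or `"gaussian"`.
#' @param n_starts multi-start count for the optimizer.
#' @return A `variogram_model`: list with `family`, `nugget`, `partial_sill`,
#'   `range_km`, `shape`, `mse` (weighted mean squared error of the fit), and
#'   `empirical` (the binned variogram).
#' @export
fit_variogram <- function(points, value,
                          family = c("stable", "exponential", "gaussian"),
                          n_bins = 12, max_dist = NULL,
                          distance = c("haversine", "planar"),
                          n_starts = 5) {
  family <- match.arg(family)
  distance <- match.arg(distance)
  emp <- empirical_variogram(points, value, n_bins = n_bins,
                             max_dist = max_dist, distance = distance)
  if (nrow(emp) < 4) stop("too few non-empty variogram bins to fit a model")
  h <- emp$dist; g <- emp$gamma; w <- emp$n_pairs / sum(emp$n_pairs)
  sill0 <- max(g)
  hmax <- max(h)
  shape_fixed <- switch(family, exponential = 1, gaussian = 2, NULL)

  obj <- function(par) {
    nug <- par[1]; psill <- par[2]; rng <- par[3]
    shp <- if (is.null(shape_fixed)) par[4] else shape_fixed
    gm <- nug + psill * (1 - exp(-(h / rng)^shp))
    sum(w * (g - gm)^2)
  }
  lower <- c(0, 0, hmax * 1e-3)
  upper <- c(sill0 * 2, sill0 * 3, hmax * 10)
  if (is.null(shape_fixed)) {
    lower <- c(lower, 0.05); upper <- c(upper, 2)
  }
  starts <- list()
  rng0 <- hmax * c(0.2, 0.5, 1, 0.35, 0.75)
  shp0 <- c(1, 1.5, 0.8, 2, 1.2)
  # first start reads the empirical curve: nugget from the shortest-distance
  # bin, partial sill from the rise above it (keeps a flat, pure-nugget curve
  # from being attributed to the sill)
  nug0 <- max(0, min(g[1], sill0))
  for (s in seq_len(n_starts)) {
    st <- if (s == 1) c(nug0, max(sill0 - nug0, 1e-3 * sill0), rng0[1])
          else c(0.05 * sill0, sill0, rng0[(s - 1) %% 5 + 1])
    if (is.null(shape_fixed)) st <- c(st, shp0[(s - 1) %% 5 + 1])
    starts[[s]] <- st
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed from all starts")
  par <- best$par
  structure(list(family = family, nugget = par[1], partial_sill = par[2],
                 range_km = par[3],
                 shape = if (is.null(shape_fixed)) par[4] else shape_fixed,
                 mse = best$value, empirical = emp, distance = distance),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "%s variogram: nugget %.3g, partial sill %.3g, range %.1f km, shape %.2f (fit MSE %.3g)\n",
    x$family, x$nugget, x$partial_sill, x$range_km, x$shape, x$mse))
  invisible(x)
}

#' Ordinary kriging of colony values onto a grid
#'
#' At each grid node the `n_max` nearest data points (great-circle distance
#' by default, unlimited search radius so the minimum-point rule only bites
#' when fewer than `n_min` points fall inside a configured `radius_km`) form
#' the ordinary-kriging system; weights sum to 1 through the Lagrange
#' multiplier, and both the prediction and the kriging variance are returned.
#' Nodes with fewer than `n_min` usable neighbours, or a singular system
#' (collocated neighbours), are masked `NA` with a warning.
#'
#' @param points data.frame with `latitude`, `longitude` and the value column.
#' @param value name of the value column.
#' @param model a `variogram_model`.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)`; default the
#'   bounding box of the points padded by 2 degrees.
#' @param resolution grid cell size in degrees (default 0.5).
#' @param n_max neighbours used per node (default 5).
#' @param n_min minimum neighbours required (default 2).
#' @param radius_km optional search-radius cap in km (default unlimited).
#' @param distance `"haversine"` or `"planar"`.
#' @return A `kriged_surface`: list with `lon`, `lat` (grid axes),
#'   `prediction` and `variance` (lat x lon matrices, row 1 = southernmost
#'   row), `weight_sum` (sum of kriging weights per node), `value`, `model`.
#' @export
krige <- function(points, value, model, bbox = NULL, resolution = 0.5,
                  n_max = 5, n_min = 2, radius_km = Inf,
                  distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  stopifnot(inherits(model, "variogram_model"), n_min >= 1, n_max >= n_min)
  z <- points[[value]]
  n <- length(z)
  if (n < n_min) stop("need at least n_min data points")
  xy <- cbind(points$longitude, points$latitude)
  bbox <- bbox %||% c(min(xy[, 1]) - 2, max(xy[, 1]) + 2,
                      min(xy[, 2]) - 2, max(xy[, 2]) + 2)
  lon <- seq(bbox[1], bbox[2], by = resolution)
  lat <- seq(bbox[3], bbox[4], by = resolution)
  grid <- cbind(rep(lon, each = length(lat)), rep(lat, length(lon)))
  ok <- ok_predict(xy, z, model, grid, n_max, n_min, radius_km, distance)
  shape_mat <- function(v) matrix(v, nrow = length(lat), ncol = length(lon))
  structure(list(lon = lon, lat = lat,
                 prediction = shape_mat(ok$pred), variance = shape_mat(ok$var),
                 weight_sum = shape_mat(ok$wsum),
                 value = value, model = model, resolution = resolution,
                 bbox = bbox),
            class = "kriged_surface")
}

# Ordinary-kriging solve at arbitrary target locations (lon, lat matrix).
ok_predict <- function(xy, z, model, loc, n_max, n_min, radius_km, distance) {
  D <- geo_dist_km(xy, method = distance)          # data-data distances
  G0 <- geo_dist_km(loc, xy, method = distance)    # target-data distances
  nq <- nrow(loc)
  pred <- var_k <- wsum <- rep(NA_real_, nq)
  n_sing <- 0L
  for (q in seq_len(nq)) {
    d0 <- G0[q, ]
    usable <- which(d0 <= radius_km)
    if (length(usable) < n_min) next
    nb <- usable[order(d0[usable])][seq_len(min(n_max, length(usable)))]
    m <- length(nb)
    # variogram_gamma() returns 0 at h = 0, so the data-data diagonal is 0
    A <- rbind(cbind(variogram_gamma(model, D[nb, nb, drop = FALSE]), 1),
               c(rep(1, m), 0))
    b <- c(variogram_gamma(model, d0[nb]), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) { n_sing <- n_sing + 1L; next }
    wts <- sol[seq_len(m)]
    pred[q] <- sum(wts * z[nb])
    v <- sum(wts * b[seq_len(m)]) + sol[m + 1]
    var_k[q] <- if (v > -1e-8 && v < 0) 0 else v
    wsum[q] <- sum(wts)
  }
  if (n_sing > 0)
    warning(n_sing, " node(s) masked: singular kriging system ",
            "(collocated neighbours)")
  list(pred = pred, var = var_k, wsum = wsum)
}

#' Ordinary kriging at arbitrary target locations
#'
#' Same neighbourhood-limited ordinary-kriging solve as [krige()], evaluated
#' at given points instead of a grid (e.g. at the data locations themselves,
#' where a nugget-free model must reproduce the data exactly).
#'
#' @inheritParams krige
#' @param locations data.frame with `latitude` and `longitude` columns.
#' @return data.frame with `longitude`, `latitude`, `prediction`, `variance`,
#'   `weight_sum`.
#' @export
krige_at <- function(points, value, model, locations, n_max = 5, n_min = 2,
                     radius_km = Inf, distance = c("haversine", "planar")) {
  distance <- match.arg(distance)
  stopifnot(inherits(model, "variogram_model"), n_min >= 1, n_max >= n_min)
  z <- points[[value]]
  if (length(z) < n_min) stop("need at least n_min data points")
  xy <- cbind(points$longitude, points$latitude)
  loc <- cbind(locations$longitude, locations$latitude)
  ok <- ok_predict(xy, z, model, loc, n_max, n_min, radius_km, distance)
  data.frame(longitude = loc[, 1], latitude = loc[, 2],
             prediction = ok$pred, variance = ok$var, weight_sum = ok$wsum)
}

#' Write a kriged surface as an ESRI ASCII raster
#'
#' @param surface a `kriged_surface`.
#' @param path output `.asc` path.
#' @param what `"prediction"` or `"variance"`.
#' @param nodata value written for masked nodes.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(surface, path, what = c("prediction", "variance"),
                             nodata = -9999) {
  what <- match.arg(what)
  m <- surface[[what]]
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.6f", surface$bbox[1] - surface$resolution / 2),
    sprintf("yllcorner %.6f", surface$bbox[3] - surface$resolution / 2),
    sprintf("cellsize %.6f", surface$resolution),
    sprintf("NODATA_value %g", nodata)), con)
  # ASCII grids run north to south; row 1 of the matrix is the south edge
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Write contour lines of a kriged surface as GeoJSON
#'
#' @param surface a `kriged_surface`.
#' @param path output `.geojson` path.
#' @param n_levels number of contour levels (spread over the prediction
#'   range).
#' @return `path`, invisibly.
#' @export
write_contours_geojson <- function(surface, path, n_levels = 8) {
  m <- surface$prediction
  if (all(is.na(m))) stop("surface has no unmasked nodes")
  lv <- pretty(range(m, na.rm = TRUE), n_levels)
  cl <- grDevices::contourLines(x = surface$lon, y = surface$lat,
                                z = t(m), levels = lv)
  features <- lapply(cl, function(line) {
    list(type = "Feature",
         properties = list(level = line$level, isotope = surface$value),
         geometry = list(type = "LineString",
                         coordinates = Map(c, line$x, line$y)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
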