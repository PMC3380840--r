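#' Population-median standardised risk scores
#'
#' @param scores a `score_set` from [compute_scores()].
#' @param populations population table with columns `population`,
#'   `latitude`, `longitude` and a `member_ids` list-column.
#' @return `data.frame` with one row per population: coordinates, median
#'   standardised score and number of scored members. Populations without
#'   scored members are dropped with a warning; unresolvable ids are
#'   skipped.
#' @export
population_medians <- function(scores, populations) {
  stopifnot(inherits(scores, "score_set"),
            !is.null(populations$member_ids))
  z <- stats::setNames(scores$z, scores$individual_id)
  rows <- lapply(seq_len(nrow(populations)), function(i) {
    ids <- populations$member_ids[[i]]
    zi <- z[intersect(ids, names(z))]
    if (!length(zi)) return(NULL)
    data.frame(population = populations$population[i],
               latitude = populations$latitude[i],
               longitude = populations$longitude[i],
               median_z = stats::median(zi), n_scored = length(zi),
               stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, logical(1))
  if (any(empty))
    warning("population(s) without scored members dropped: ",
            paste(populations$population[empty], collapse = ", "))
  out <- do.call(rbind, rows[!empty])
  if (is.null(out)) stop("no population has scored members")
  rownames(out) <- NULL
  out
}

# bivariate monomial basis up to total degree d: columns x^i * y^j, i+j <= d
poly_basis <- function(x, y, degree) {
  cols <- list()
  for (total in 0:degree) for (i in 0:total) {
    j <- total - i
    cols[[sprintf("x%dy%d", i, j)]] <- x^i * y^j
  }
  do.call(cbind, cols)
}

#' Least-squares polynomial trend surface
#'
#' Ordinary least squares of a population-level value on the bivariate
#' monomial basis in longitude and latitude up to total degree `degree`
#' (10 terms at degree 3). Coordinates are centred and scaled internally
#' for conditioning; predictions are returned in original units.
#'
#' @param points `data.frame` with `longitude`, `latitude` and a value
#'   column (default `median_z`).
#' @param degree polynomial total degree (default 3).
#' @param value name of the value column.
#' @return A `trend_surface` object with a [predict()] method.
#' @export
fit_trend_surface <- function(points, degree = 3, value = "median_z") {
  n_terms <- (degree + 1) * (degree + 2) / 2
  if (nrow(points) <= n_terms)
    stop(sprintf("need more than %d points for degree %d (got %d)",
                 n_terms, degree, nrow(points)))
  ctr <- c(lon = mean(points$longitude), lat = mean(points$latitude))
  scl <- c(lon = stats::sd(points$longitude), lat = stats::sd(points$latitude))
  if (any(scl == 0)) stop("degenerate coordinates: zero variance")
  x <- (points$longitude - ctr["lon"]) / scl["lon"]
  y <- (points$latitude - ctr["lat"]) / scl["lat"]
  X <- poly_basis(x, y, degree)
  fit <- stats::lm.fit(X, points[[value]])
  if (any(is.na(fit$coefficients)))
    stop("rank-deficient design: collinear coordinates")
  structure(
    list(coefficients = fit$coefficients, degree = degree,
         center = ctr, scale = scl, residuals = fit$residuals),
    class = "trend_surface"
  )
}

#' @param object a `trend_surface`.
#' @param newdata `data.frame` with `longitude` and `latitude`.
#' @param ... unused.
#' @rdname fit_trend_surface
#' @export
predict.trend_surface <- function(object, newdata, ...) {
  x <- (newdata$longitude - object$center["lon"]) / object$scale["lon"]
  y <- (newdata$latitude - object$center["lat"]) / object$scale["lat"]
  as.numeric(poly_basis(x, y, object$degree) %*% object$coefficients)
}

#' Evaluate a surface on a regular coordinate grid
#'
#' @param surface a `trend_surface` or `kriging_model`.
#' @param lat_range,lon_range numeric length-2 bounds.
#' @param step grid spacing in degrees.
#' @return `data.frame(latitude, longitude, value)` (plus `variance` for
#'   kriging).
#' @export
evaluate_grid <- function(surface, lat_range, lon_range, step = 1) {
  grid <- expand.grid(
    latitude = seq(lat_range[1], lat_range[2], by = step),
    longitude = seq(lon_range[1], lon_range[2], by = step)
  )
  if (inherits(surface, "kriging_model")) {
    pr <- predict(surface, grid)
    grid$value <- pr$prediction
    grid$variance <- pr$variance
  } else {
    grid$value <- predict(surface, grid)
  }
  grid
}

# great-circle distances in km between two coordinate sets
haversine_km <- function(a, b = a) {
  geosphere::distm(cbind(a$longitude, a$latitude),
                   cbind(b$longitude, b$latitude),
                   fun = geosphere::distHaversine) / 1000
}

#' Empirical semivariogram with exponential weighted-least-squares fit
#'
#' Bins pairwise squared half-differences by great-circle distance and
#' fits `gamma(h) = nugget + sill * (1 - exp(-h / range))` by least
#' squares weighted with the pair counts.
#'
#' @param points `data.frame` with `longitude`, `latitude` and a value
#'   column (default `median_z`).
#' @param n_bins number of distance bins (default 12).
#' @param value name of the value column.
#' @param nugget fixed nugget; `NULL` (default) estimates it.
#' @return `list(sill, range_km, nugget, empirical)`.
#' @export
fit_exponential_variogram <- function(points, n_bins = 12,
                                      value = "median_z", nugget = NULL) {
  h <- haversine_km(points)
  v <- points[[value]]
  dif2 <- 0.5 * outer(v, v, "-")^2
  up <- upper.tri(h)
  hh <- h[up]; gg <- dif2[up]
  br <- seq(0, max(hh), length.out = n_bins + 1)
  bin <- cut(hh, br, include.lowest = TRUE)
  emp <- data.frame(
    distance = tapply(hh, bin, mean),
    gamma = tapply(gg, bin, mean),
    n = as.integer(table(bin))
  )
  emp <- emp[emp$n > 0 & is.finite(emp$gamma), ]
  s0 <- stats::var(v); r0 <- max(hh) / 3
  obj <- function(par) {
    s <- exp(par[1]); r <- exp(par[2])
    ng <- if (is.null(nugget)) exp(par[3]) else nugget
    sum(emp$n * (emp$gamma - (ng + s * (1 - exp(-emp$distance / r))))^2)
  }
  # under a trend-dominated (non-plateauing) semivariogram, sill and range
  # diverge jointly with only their ratio identified; box constraints keep
  # both on the scale of the data and the kriging system well-posed
  up <- c(log(10 * max(emp$gamma)), log(max(hh)), log(10 * max(emp$gamma)))
  lo <- c(log(1e-8 + s0 / 100), log(max(hh) / 100), log(1e-12))
  p0 <- pmin(up, pmax(lo, log(c(s0, r0, s0 / 10 + 1e-8))))
  if (!is.null(nugget)) { up <- up[1:2]; lo <- lo[1:2]; p0 <- p0[1:2] }
  op <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = up,
                     control = list(maxit = 2000, factr = 1e4))
  list(sill = exp(op$par[1]), range_km = exp(op$par[2]),
       nugget = if (is.null(nugget)) exp(op$par[3]) else nugget,
       empirical = emp)
}

#' Ordinary kriging with exponential covariance
#'
#' Best linear unbiased spatial prediction with weights constrained to
#' sum to one (Lagrange multiplier). The covariance is
#' `C(h) = sill * exp(-h / range_km)` plus `nugget` at `h = 0`; distances
#' are great-circle kilometres. With zero nugget the predictor
#' interpolates the training points exactly.
#'
#' @param points training `data.frame` with `longitude`, `latitude` and a
#'   value column (default `median_z`).
#' @param sill,range_km,nugget exponential covariance parameters; if
#'   `sill` or `range_km` is `NULL` they are fitted with
#'   [fit_exponential_variogram()].
#' @param value name of the value column.
#' @return A `kriging_model` with a [predict()] method returning
#'   predictions and kriging variances.
#' @export
krige <- function(points, sill = NULL, range_km = NULL, nugget = 0,
                  value = "median_z") {
  if (nrow(points) < 3) stop("kriging needs at least 3 points")
  if (is.null(sill) || is.null(range_km)) {
    vg <- fit_exponential_variogram(points, value = value, nugget = nugget)
    sill <- vg$sill; range_km <- vg$range_km; nugget <- vg$nugget
  }
  stopifnot(sill > 0, range_km > 0, nugget >= 0)
  h <- haversine_km(points)
  if (nugget == 0 && any(h[upper.tri(h)] < 1e-9)) {
    dup <- which(h < 1e-9 & upper.tri(h), arr.ind = TRUE)[1, ]
    if (abs(points[[value]][dup[1]] - points[[value]][dup[2]]) > 1e-12)
      stop("duplicate coordinates with differing values and zero nugget: ",
           "singular kriging system")
  }
  # tiny diagonal jitter keeps the system well-posed when points are dense
  # relative to the range; its effect on predictions is O(1e-8)
  C <- sill * exp(-h / range_km) + diag(nugget + 1e-8 * sill, nrow(h))
  A <- rbind(cbind(C, 1), c(rep(1, nrow(C)), 0))
  structure(
    list(points = points[, c("longitude", "latitude")],
         values = points[[value]], A = A, sill = sill,
         range_km = range_km, nugget = nugget),
    class = "kriging_model"
  )
}

#' @param object a `kriging_model`.
#' @param newdata `data.frame` with `longitude` and `latitude`.
#' @param ... unused.
#' @rdname krige
#' @export
predict.kriging_model <- function(object, newdata, ...) {
  h0 <- haversine_km(object$points, newdata)
  c0 <- object$sill * exp(-h0 / object$range_km)
  c0[h0 < 1e-9] <- object$sill + object$nugget
  rhs <- rbind(c0, 1)
  sol <- solve(object$A, rhs)
  w <- sol[seq_len(nrow(c0)), , drop = FALSE]
  lambda <- sol[nrow(sol), ]
  pred <- as.numeric(crossprod(w, object$values))
  varg <- object$sill + object$nugget - colSums(w * c0) - lambda
  data.frame(prediction = pred, variance = pmax(0, varg))
}

#' Correlation of population risk with a geographic axis
#'
#' Pearson correlation (with the two-sided t-transform p-value) of the
#' per-population median standardised score against longitude (eastward
#' distance from the prime meridian, operationalised as signed longitude)
#' or latitude.
#'
#' @param points output of [population_medians()].
#' @param axis `"longitude"` or `"latitude"`.
#' @param filter optional logical/integer index restricting to a region.
#' @param value name of the value column (default `median_z`).
#' @return `list(r, p, n)`.
#' @export
geographic_correlation <- function(points, axis = c("longitude", "latitude"),
                                   filter = NULL, value = "median_z") {
  axis <- match.arg(axis)
  if (!is.null(filter)) points <- points[filter, , drop = FALSE]
  if (nrow(points) < 3) stop("need at least 3 points")
  x <- points[[axis]]; y <- points[[value]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in ", if (stats::sd(x) == 0) axis else value)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(points))
}
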