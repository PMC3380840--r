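make_points <- function(n, f, seed = 1, lat = c(35, 65), lon = c(-10, 40)) {
  set.seed(seed)
  data.frame(
    population = sprintf("p%02d", seq_len(n)),
    latitude = runif(n, lat[1], lat[2]),
    longitude = runif(n, lon[1], lon[2])
  ) |> transform(median_z = f(longitude, latitude))
}

test_that("population medians match a sort-based oracle", {
  d <- simulate_case_control(igan_sim_config(60, 60, seed = 81))
  sc <- compute_scores(igan_model(), d)
  pops <- data.frame(population = c("A", "B"), latitude = c(10, 20),
                     longitude = c(5, 15))
  ids <- sc$individual_id
  pops$member_ids <- list(ids[1:41], ids[42:100])
  pm <- population_medians(sc, pops)
  sorted_median <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  expect_equal(pm$median_z[1], sorted_median(sc$z[1:41]))
  expect_equal(pm$median_z[2], sorted_median(sc$z[42:100]))
  expect_equal(pm$n_scored, c(41L, 59L))

  # ordering of members is irrelevant; single member equals its own score
  pops2 <- pops
  pops2$member_ids <- list(rev(ids[1:41]), ids[42])
  pm2 <- population_medians(sc, pops2)
  expect_equal(pm2$median_z[1], pm$median_z[1])
  expect_equal(pm2$median_z[2], sc$z[42])

  # a population with no scored members is dropped with a warning
  pops3 <- rbind(pops, data.frame(population = "C", latitude = 1,
                                  longitude = 1,
                                  member_ids = I(list("nobody"))))
  expect_warning(pm3 <- population_medians(sc, pops3), "dropped")
  expect_equal(nrow(pm3), 2)
})

test_that("trend surfaces are exact on nested polynomials", {
  pts <- make_points(40, function(lon, lat) 2 + 0.1 * lon - 0.05 * lat,
                     seed = 82)
  ts <- fit_trend_surface(pts, degree = 3)
  expect_lt(max(abs(ts$residuals)), 1e-8)
  # degree-1 surface on planar data is exact too
  ts1 <- fit_trend_surface(pts, degree = 1)
  expect_lt(max(abs(ts1$residuals)), 1e-8)

  cubic <- function(lon, lat)
    1 - 0.02 * lon + 0.03 * lat + 4e-4 * lon * lat - 5e-4 * lon^2 +
    2e-5 * lon^3 - 3e-5 * lat^3 + 1e-5 * lon^2 * lat
  pts3 <- make_points(60, cubic, seed = 83)
  ts3 <- fit_trend_surface(pts3, degree = 3)
  query <- make_points(25, cubic, seed = 84)
  expect_lt(max(abs(predict(ts3, query) - query$median_z)), 1e-6)

  # insufficient points for the requested degree are refused
  expect_error(fit_trend_surface(make_points(9, function(a, b) a + b)),
               "points")
})

test_that("trend-surface predictions agree with the spatial package", {
  skip_if_not_installed("spatial")
  pts <- make_points(50, function(lon, lat)
    0.5 + 0.01 * lon - 0.02 * lat + 3e-4 * lon * lat + rep(0, length(lon)),
    seed = 85)
  pts$median_z <- pts$median_z + rnorm(50, 0, 0.2)
  ts <- fit_trend_surface(pts, degree = 3)
  sf <- spatial::surf.ls(3, pts$longitude, pts$latitude, pts$median_z)
  query <- make_points(20, function(a, b) 0, seed = 86)
  theirs <- spatial::predict.trls(sf, query$longitude, query$latitude)
  expect_equal(predict(ts, query), theirs, tolerance = 1e-6)
})

test_that("ordinary kriging interpolates, averages far afield, and guards", {
  pts <- make_points(25, function(lon, lat) sin(lon / 10) + cos(lat / 10),
                     seed = 87)
  kg <- krige(pts, sill = 1, range_km = 800, nugget = 0)
  pr <- predict(kg, pts)
  expect_lt(max(abs(pr$prediction - pts$median_z)), 1e-6)
  expect_lt(max(pr$variance), 1e-4)

  # two-point system solved by hand: both weights 1/2 at the midpoint
  two <- data.frame(longitude = c(0, 2), latitude = c(0, 0),
                    median_z = c(1, 3))
  kg2 <- krige(two[c(1, 2, 1), ], sill = 2, range_km = 500, nugget = 0)
  # (third duplicated point keeps n >= 3; predict midpoint of the pair)
  mid <- data.frame(longitude = 1, latitude = 0)
  pr2 <- predict(kg2, mid)
  expect_equal(pr2$prediction, 2, tolerance = 1e-6)

  # far beyond the range the prediction approaches the training mean
  far <- data.frame(longitude = 170, latitude = -60)
  kg3 <- krige(pts, sill = 1, range_km = 5, nugget = 0)
  expect_lt(abs(predict(kg3, far)$prediction - mean(pts$median_z)) /
              abs(mean(pts$median_z)), 0.01)

  # predictions inside the hull stay within the training range
  grid <- expand.grid(longitude = seq(0, 30, 5), latitude = seq(40, 60, 5))
  prg <- predict(kg, grid)
  expect_true(all(prg$prediction >= min(pts$median_z) - 1e-6))
  expect_true(all(prg$prediction <= max(pts$median_z) + 1e-6))

  dup <- rbind(pts[1:3, ], transform(pts[1, ], median_z = median_z + 1))
  expect_error(krige(dup, sill = 1, range_km = 100, nugget = 0),
               "singular|duplicate")
  expect_error(krige(pts[1:2, ], sill = 1, range_km = 100), "at least 3")
})

test_that("variogram fitting recovers sensible exponential parameters", {
  pts <- make_points(60, function(lon, lat) 0, seed = 88)
  set.seed(88)
  pts$median_z <- rnorm(60, 0, 0.5)
  vg <- fit_exponential_variogram(pts)
  expect_gt(vg$sill + vg$nugget, 0.05)  # total variance on the data scale
  expect_lt(vg$sill + vg$nugget, 2)
  kg <- krige(pts)  # auto-fit must produce a solvable system
  expect_equal(nrow(predict(kg, pts[1:4, ])), 4)
})

test_that("geographic correlations behave like Pearson correlations", {
  pts <- make_points(30, function(lon, lat) 0.02 * lon, seed = 89)
  pts$median_z <- pts$median_z + rnorm(30, 0, 0.1)
  gc <- geographic_correlation(pts, "longitude")
  ct <- cor.test(pts$longitude, pts$median_z)
  expect_equal(gc$r, unname(ct$estimate))
  expect_equal(gc$p, ct$p.value)
  # affine rescaling of scores leaves r unchanged
  pts2 <- pts; pts2$median_z <- -2 + 7 * pts$median_z
  expect_equal(geographic_correlation(pts2, "longitude")$r, gc$r,
               tolerance = 1e-12)
  pts3 <- pts; pts3$median_z <- 1
  expect_error(geographic_correlation(pts3, "longitude"), "zero variance")
})

test_that("registry metrics, fold ratios and latitude regressions compute", {
  rec <- data.frame(region_name = c("X", "Y"), average_latitude = c(40, 60),
                    incident_count = c(50, 100), prevalent_count = c(100, 400),
                    total_esrd_count = c(1000, 4000),
                    gn_esrd_count = c(100, 800), population_millions = c(10, 20))
  em <- epi_metrics(rec)
  expect_equal(em$pct_esrd[1], 10)
  expect_equal(em$prevalence_pmp[1], 10)
  expect_equal(em$incidence_pmp[1], 5)
  expect_equal(em$pct_gn_esrd[1], 100)  # all GN-ESRD attributable

  us <- epi_metrics(read_prevalence_table(
    system.file("extdata", "usrds_igan_esrd_by_ethnicity_synthetic.csv",
                package = "igarisk")))
  fr <- ethnic_fold_ratio(us, "African American")
  expect_equal(fr$pct_esrd[fr$region_name == "African American"], 1)
  expect_lt(abs(fr$pct_esrd[fr$region_name == "Asian American"] - 15), 1.5)
  expect_lt(abs(fr$pct_esrd[fr$region_name == "White"] - 5), 0.8)

  era <- epi_metrics(read_prevalence_table(
    system.file("extdata", "era_edta_igan_esrd_synthetic.csv",
                package = "igarisk")))
  lr <- latitude_regression(era)
  # a metric exactly linear in latitude correlates perfectly
  expect_equal(latitude_regression(transform(era,
    incidence_pmp = 2 * average_latitude))$r[1], 1, tolerance = 1e-12)
  # negating latitude flips every correlation sign
  lr_neg <- latitude_regression(transform(era,
    average_latitude = -average_latitude))
  expect_equal(lr_neg$r, -lr$r, tolerance = 1e-12)

  # median risk scores enter the same regression
  sc <- setNames(rnorm(13), era$region_name)
  lr2 <- latitude_regression(era, scores = sc)
  expect_true("median_risk_score" %in% lr2$metric)
})
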