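test_that("empirical semivariances match direct pair enumeration", {
  # two points, values 0 and 2: gamma = 0.5 * (2)^2 = 2, one pair
  v <- empirical_variogram(c(0, 1), c(40, 40), c(0, 2), n_bins = 1,
                           max_dist = 200)
  expect_equal(v$gamma, 2)
  expect_equal(v$n_pairs, 1L)

  # equal values everywhere: gamma identically zero
  v0 <- empirical_variogram(c(0, 1, 2, 3), rep(40, 4), rep(7, 4),
                            n_bins = 3, max_dist = 400)
  expect_true(all(v0$gamma == 0))

  # 4 collinear equally spaced points: brute force over all 6 pairs
  lon <- c(0, 1, 2, 3); lat <- rep(0, 4); val <- c(0, 1, 0, 1)
  d <- geosphere::distm(cbind(lon, lat)) / 1000
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]; g <- 0.5 * (val[iu[, 1]] - val[iu[, 2]])^2
  md <- max(h)
  breaks <- seq(0, md, length.out = 4)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  expected <- vapply(sort(unique(bin)), function(b) mean(g[bin == b]),
                     numeric(1))
  v4 <- empirical_variogram(lon, lat, val, n_bins = 3, max_dist = md)
  expect_equal(v4$gamma, expected)
  expect_equal(sum(v4$n_pairs), 6L)

  expect_error(empirical_variogram(c(0, 0), c(40, 40), c(1, 2)),
               "coincident")
})

test_that("variogram WLS fit recovers noiseless model parameters", {
  h <- seq(5, 300, length.out = 15)
  true <- variogram_model("exponential", nugget = 0, psill = 1, range = 50)
  emp <- data.frame(dist = h, gamma = semivariance(true, h),
                    n_pairs = rep(20L, 15))
  class(emp) <- c("iso_variogram", "data.frame")
  fit <- fit_variogram(emp, "exponential")
  expect_equal(fit$psill, 1, tolerance = 0.01)
  expect_equal(fit$range, 50, tolerance = 0.01)
  expect_lt(fit$nugget, 0.01)

  # flat empirical variogram: pure nugget
  flat <- emp; flat$gamma <- rep(0.8, 15)
  f2 <- fit_variogram(flat, "exponential")
  expect_equal(f2$nugget + semivariance(f2, max(h)) - f2$nugget, 0.8,
               tolerance = 0.05)
  expect_equal(f2$nugget, 0.8, tolerance = 0.05)

  # scale equivariance of WLS: doubling gamma doubles the variance params
  emp2 <- emp; emp2$gamma <- 2 * emp$gamma
  f3 <- fit_variogram(emp2, "exponential")
  expect_equal(f3$psill, 2 * fit$psill, tolerance = 0.02)
})

test_that("semivariance is nondecreasing with valid parameters", {
  h <- seq(0, 500, by = 5)
  for (fam in c("exponential", "spherical", "gaussian")) {
    m <- variogram_model(fam, nugget = 0.2, psill = 1.3, range = 80)
    expect_true(all(diff(semivariance(m, h)) >= -1e-12), label = fam)
    expect_equal(semivariance(m, 0), 0)
  }
  expect_error(variogram_model("exponential", -1, 1, 10), "nugget")
  expect_error(variogram_model("exponential", 0, 1, 0), "range")
})

test_that("ordinary kriging honors unbiasedness and exact interpolation", {
  grid <- iso_raster(matrix(0, 5, 8), xmin = 0, ymax = 5, dx = 1)
  co <- raster_coords(grid)
  obs <- co[c(3, 12, 25, 37), ]
  vgm <- variogram_model("exponential", nugget = 0, psill = 1, range = 150)

  # constant observations reproduce the constant everywhere
  kc <- krige_ordinary(obs$lon, obs$lat, rep(4.2, 4), vgm, grid)
  expect_equal(kc$mean$values, matrix(4.2, 5, 8), tolerance = 1e-8)
  expect_lt(kc$weights_sum_check, 1e-8)

  # zero nugget: exact at observation cells, variance 0 there, >= 0 anywhere
  vals <- c(1, 5, 2, 8)
  k <- krige_ordinary(obs$lon, obs$lat, vals, vgm, grid)
  expect_equal(k$mean$values[cbind(obs$row, obs$col)], vals,
               tolerance = 1e-8)
  expect_equal(k$variance$values[cbind(obs$row, obs$col)], rep(0, 4),
               tolerance = 1e-8)
  expect_true(all(k$variance$values >= 0))
})

test_that("two-point kriging prediction matches a hand-solved 3x3 system", {
  grid <- iso_raster(matrix(0, 1, 3), xmin = 0, ymax = 0.5, dx = 1)
  co <- raster_coords(grid)
  vgm <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 100)
  vals <- c(2, 7)
  k <- krige_ordinary(co$lon[c(1, 3)], co$lat[c(1, 3)], vals, vgm, grid)

  # oracle: assemble and solve the OK equations for the middle cell
  pts <- cbind(co$lon[c(1, 3, 2)], co$lat[c(1, 3, 2)])
  d <- geosphere::distm(pts) / 1000
  sill <- vgm$nugget + vgm$psill
  C <- sill - semivariance(vgm, d[1:2, 1:2])
  diag(C) <- sill
  A <- rbind(cbind(C, 1), c(1, 1, 0))
  b <- c(sill - semivariance(vgm, d[3, 1:2]), 1)
  sol <- solve(A, b)
  expect_equal(sum(sol[1:2]), 1, tolerance = 1e-10)
  expect_equal(k$mean$values[1, 2], sum(sol[1:2] * vals), tolerance = 1e-8)
  expect_equal(k$variance$values[1, 2],
               sill - sum(sol[1:2] * b[1:2]) - sol[3], tolerance = 1e-8)
})

test_that("duplicate observation cells are averaged before kriging", {
  grid <- iso_raster(matrix(0, 1, 4), xmin = 0, ymax = 0.5, dx = 1)
  co <- raster_coords(grid)
  vgm <- variogram_model("exponential", nugget = 0, psill = 1, range = 100)
  expect_message(
    k <- krige_ordinary(co$lon[c(1, 1, 4)], co$lat[c(1, 1, 4)],
                        c(2, 4, 6), vgm, grid),
    "averaged")
  expect_equal(k$mean$values[1, 1], 3, tolerance = 1e-8)
})

test_that("tap-water isoscape equals base plus kriged difference field", {
  sc <- synthetic_scenario(seed = 5, grid_shape = c(10L, 14L),
                           env_range = c(-15, -3))
  base <- synth_raster(sc)
  co <- raster_coords(base)
  set.seed(9)
  pts <- co[sample.int(nrow(co), 12), ]
  base_at <- base$values[cbind(pts$row, pts$col)]
  vgm <- variogram_model("exponential", nugget = 0, psill = 0.5,
                         range = 400)

  # taps identical to base: zero difference field, output is the base
  out0 <- build_tapwater_isoscape(base, pts$lon, pts$lat, base_at,
                                  variogram = vgm)
  expect_equal(out0$isoscape$values, base$values, tolerance = 1e-8)

  # base of zeros: additivity reduces to kriging the tap values directly
  zero <- base; zero$values[] <- 0
  taps <- base_at + 1.5
  outz <- build_tapwater_isoscape(zero, pts$lon, pts$lat, taps,
                                  variogram = vgm)
  direct <- krige_ordinary(pts$lon, pts$lat, taps, vgm, zero)
  expect_equal(outz$isoscape$values, direct$mean$values, tolerance = 1e-10)

  # exactness at tap cells, zero-nugget model
  out <- build_tapwater_isoscape(base, pts$lon, pts$lat, taps,
                                 variogram = vgm)
  expect_equal(out$isoscape$values[cbind(pts$row, pts$col)], taps,
               tolerance = 1e-8)

  # equivariance under adding a constant to base and taps
  shifted <- build_tapwater_isoscape(base + 2, pts$lon, pts$lat, taps + 2,
                                     variogram = vgm)
  expect_equal(shifted$isoscape$values, out$isoscape$values + 2,
               tolerance = 1e-8)

  expect_error(build_tapwater_isoscape(base, pts$lon[1:2], pts$lat[1:2],
                                       taps[1:2]), "at least 3")
})

test_that("difference kriging recovers a smooth offset sampled at sites", {
  sc <- synthetic_scenario(seed = 21, grid_shape = c(12L, 18L),
                           env_range = c(-15, -3))
  base <- synth_raster(sc)
  # smooth known offset surface over the same grid
  off_sc <- synthetic_scenario(seed = 22, grid_shape = c(12L, 18L),
                               env_range = c(0.5, 2.5), spatial_scale = 10)
  offset <- synth_raster(off_sc)
  co <- raster_coords(base)
  set.seed(4)
  pts <- co[sample.int(nrow(co), 50), ]
  taps <- (base$values + offset$values)[cbind(pts$row, pts$col)]
  out <- build_tapwater_isoscape(base, pts$lon, pts$lat, taps)
  recovered <- out$isoscape$values - base$values
  mae <- mean(abs(recovered - offset$values))
  expect_lt(mae, 0.25)  # offset spans 2 per mil; kriging error well below
  expect_true(all(out$uncertainty$values >= 0))
})
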