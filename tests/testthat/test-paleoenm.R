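make_stack <- function(vars, time = 0, grid = NULL) {
  grid <- grid %||% list(nrows = nrow(vars[[1]]), ncols = ncol(vars[[1]]),
                         xll = 0, yll = 0, cellsize = 0.5, nodata = -9999)
  climate_stack(vars, grid = grid, time = time)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("climate PCA matches a direct eigendecomposition", {
  set.seed(50)
  vars <- list(v1 = matrix(rnorm(50, 10, 3), 5, 10),
               v2 = matrix(rnorm(50, 0, 1), 5, 10),
               v3 = matrix(rnorm(50, 5, 2), 5, 10))
  vars$v4 <- vars$v1 * 0.7 + matrix(rnorm(50, 0, 0.5), 5, 10)
  st <- make_stack(vars)
  pca <- climate_pca(st, n_axes = 3)
  z <- scale(sapply(vars, as.vector))
  eg <- eigen(stats::cov(z), symmetric = TRUE)
  ref <- z %*% eg$vectors[, 1:3]
  for (j in 1:3) {
    expect_equal(abs(as.vector(pca$axes$variables[[j]])), abs(ref[, j]),
                 tolerance = 1e-8)
  }
  expect_true(all(diff(pca$explained) <= 1e-12))

  vars$v5 <- matrix(1, 5, 10)
  expect_warning(climate_pca(make_stack(vars), 3), "constant")
})

test_that("anchors project with the current climate's standardization", {
  set.seed(51)
  vars <- list(a = matrix(rnorm(36, 20, 2), 6, 6), b = matrix(rnorm(36), 6, 6))
  cur <- make_stack(vars)
  pca <- climate_pca(cur, 2)
  same <- project_anchor(make_stack(vars, time = 21), pca)
  expect_equal(same$variables, pca$axes$variables, tolerance = 1e-12)

  # constant shift on one variable moves axes by loading * shift / scale
  shifted <- vars; shifted$a <- shifted$a + 3
  proj <- project_anchor(make_stack(shifted, time = 21), pca)
  for (j in 1:2) {
    expect_equal(proj$variables[[j]],
                 pca$axes$variables[[j]] + pca$loadings["a", j] * 3 / pca$scale["a"],
                 tolerance = 1e-10)
  }

  # masked cells stay masked
  masked <- vars
  masked$a[1, 1] <- NA; masked$b[1, 1] <- NA
  curm <- make_stack(masked)
  pcam <- climate_pca(curm, 2)
  pm <- project_anchor(make_stack(masked, time = 21), pcam)
  expect_true(is.na(pm$variables[[1]][1, 1]))

  expect_error(project_anchor(make_stack(vars["a"], time = 21), pca), "lacks")
})

test_that("forcing interpolation is exact on affine anchors and OLS otherwise", {
  forcing <- synthetic_forcing()
  base <- matrix(rnorm(25), 5, 5); slope <- matrix(rnorm(25, 0, 0.3), 5, 5)
  times <- c(0, 21, 130, 500)
  fv <- approx(forcing$time_ky, forcing$d18o, xout = times)$y
  stacks <- lapply(seq_along(times), function(i) {
    make_stack(list(axis1 = base + slope * fv[i]), time = times[i])
  })
  fm <- fit_forcing_interpolation(stacks, forcing)
  hc <- hindcast_axes(fm, times)
  for (i in seq_along(times)) {
    expect_equal(hc[[i]]$variables$axis1, stacks[[i]]$variables$axis1,
                 tolerance = 1e-10)
  }

  # noisy anchors: per-cell coefficients equal lm()
  set.seed(52)
  noisy <- lapply(seq_along(times), function(i) {
    make_stack(list(axis1 = base + slope * fv[i] + matrix(rnorm(25, 0, 0.1), 5, 5)),
               time = times[i])
  })
  fm2 <- fit_forcing_interpolation(noisy, forcing)
  y <- vapply(noisy, function(s) s$variables$axis1[2, 3], numeric(1))
  ref <- stats::lm(y ~ fv)
  expect_equal(fm2$intercept$axis1[2, 3], unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fm2$slope$axis1[2, 3], unname(coef(ref)[2]), tolerance = 1e-10)

  # constant axis -> zero slope
  const <- lapply(seq_along(times), function(i) {
    make_stack(list(axis1 = base), time = times[i])
  })
  fm3 <- fit_forcing_interpolation(const, forcing)
  expect_equal(fm3$slope$axis1, matrix(0, 5, 5), tolerance = 1e-12)
  expect_equal(fm3$intercept$axis1, base, tolerance = 1e-12)

  # degenerate forcing values rejected; out-of-domain times rejected
  expect_error(fit_forcing_interpolation(stacks[1], forcing), "anchors")
  expect_error(hindcast_axes(fm, times = 1000), "forcing domain")
})

test_that("the default hindcast grid has 694 slices at the stated spacing", {
  tg <- default_time_grid()
  expect_equal(length(tg), 694L)
  expect_equal(tg[1:3], c(0, 1, 2))
  expect_equal(tail(tg, 2), c(784, 786))
  expect_true(all(diff(tg)[601:692] == 2))
})

test_that("occurrence splitting follows the 70/30 arithmetic", {
  occ <- data.frame(lon = runif(21), lat = runif(21))
  sp <- split_occurrences(occ, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 15L)
  expect_equal(nrow(sp$test), 6L)
  expect_identical(sp, split_occurrences(occ, 0.7, seed = 1))
  expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(occ))
})

test_that("niche model contracts hold at their fixed points", {
  set.seed(53)
  train <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))

  # bioclim: the training median scores 1 (even n -> interpolated median)
  bc <- fit_niche_model(train, algorithm = "bioclim")
  med <- matrix(apply(train, 2, stats::median), 1)
  expect_equal(predict(bc, med), 1)
  expect_equal(predict(bc, matrix(c(99, 99, 99), 1)), 0)

  # domain: a training point is its own perfect analogue
  dm <- fit_niche_model(train, algorithm = "domain")
  expect_equal(predict(dm, train[3, , drop = FALSE]), 1)

  # enfa: background equal to presences has ~zero marginality
  en <- fit_niche_model(train, background = train, algorithm = "enfa")
  expect_lt(sqrt(sum(en$marginality^2)), 1e-8)
  en2 <- fit_niche_model(train, background = bg, algorithm = "enfa")
  cent <- matrix(colMeans(train), 1)
  expect_equal(predict(en2, cent), 1)

  # all algorithms map into [0, 1]
  for (alg in c("bioclim", "domain", "enfa", "maxent", "ocsvm")) {
    m <- fit_niche_model(train, background = bg, algorithm = alg, seed = 1)
    s <- predict(m, bg)
    expect_true(all(s >= 0 & s <= 1), info = alg)
  }
  expect_error(fit_niche_model(train, algorithm = "maxent"), "background")
})

test_that("evaluation implements D = TPR x (1 - pi) exactly", {
  test_scores <- c(rep(0.9, 9), 0.1)          # TPR 0.9 at threshold 0.5
  cells <- c(rep(0.9, 400), rep(0.1, 600))    # pi = 0.4
  ev <- evaluate_prediction(test_scores, cells, 0.5)
  expect_equal(ev$tpr, 0.9)
  expect_equal(ev$predicted_area_fraction, 0.4)
  expect_equal(ev$d_stat, 0.54)

  expect_equal(evaluate_prediction(1, 0.2, 0.5)$d_stat, 1)   # TPR 1, pi 0
  ev0 <- evaluate_prediction(test_scores, cells, 2)
  expect_equal(ev0$tpr, 0)
  expect_equal(ev0$d_stat, 0)
})

test_that("max-SSS thresholds match an exhaustive scan", {
  # perfectly separated: the tie rule returns the lowest presence score
  expect_equal(as.numeric(max_sss_threshold(c(0.8, 0.9), c(0.1, 0.2))), 0.8)
  # degenerate: identical scores -> lowest candidate
  expect_equal(as.numeric(max_sss_threshold(c(0.5, 0.5), c(0.5, 0.5))), 0.5)

  set.seed(54)
  for (rep in 1:20) {
    p <- runif(8); a <- runif(30)
    got <- as.numeric(max_sss_threshold(p, a))
    cand <- sort(unique(c(p, a)))
    ss <- vapply(cand, function(t) mean(p >= t) + mean(a < t), numeric(1))
    best <- max(ss)
    expect_equal(mean(p >= got) + mean(a < got), best, tolerance = 1e-12)
    expect_equal(got, min(cand[abs(ss - best) < 1e-12]))
  }
})

test_that("committee consensus is a monotone majority vote", {
  maps <- lapply(1:5, function(i) matrix(c(1, 0, 1, 0), 2, 2) * (i %% 2))
  one <- matrix(1, 2, 2)
  expect_equal(ensemble_consensus(list(one, one, one)), one == 1)
  votes3 <- list(one, one, one, one * 0, one * 0)
  expect_true(all(ensemble_consensus(votes3)))
  expect_error(ensemble_consensus(list(one, matrix(1, 3, 3))), "grid")

  set.seed(55)
  for (rep in 1:50) {
    vs <- lapply(1:5, function(i) matrix(rbinom(9, 1, 0.5), 3, 3))
    cons <- ensemble_consensus(vs)
    flip <- sample(5, 1); cell <- sample(9, 1)
    vs2 <- vs
    vs2[[flip]][cell] <- 1
    cons2 <- ensemble_consensus(vs2)
    expect_true(all(cons2 >= cons))   # adding a vote never removes presence
  }
})

test_that("MIS aggregation and stage tables behave", {
  mis <- load_mis_table()
  expect_equal(nrow(mis), 19L)
  expect_equal(mis$start_ky[1], 0)
  expect_true(all(mis$type %in% c("glacial", "interglacial")))
  expect_error(mis_table(data.frame(name = "x", start_ky = 0, end_ky = 5,
                                    type = "warm")), "glacial")

  # hand-built series: presence everywhere except interglacial slices at one cell
  cons <- list(matrix(TRUE, 2, 2), matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  cons[[1]][1, 1] <- FALSE   # t = 5 (interglacial in the synthetic table)
  series <- structure(list(times = c(5, 40, 60), consensus = cons,
                           area_fraction = vapply(cons, mean, numeric(1))),
                      class = "ensemble_series")
  tbl <- mis_table(data.frame(name = c("i1", "g1"), start_ky = c(0, 20),
                              end_ky = c(20, 100),
                              type = c("interglacial", "glacial")))
  agg <- mis_aggregate(series, tbl)
  expect_equal(agg$glacial$frequency[1, 1], 1)
  expect_equal(agg$interglacial$frequency[1, 1], 0)
  expect_equal(agg$glacial$n_slices, 2L)
  tbl_short <- mis_table(data.frame(name = "g", start_ky = 0, end_ky = 50,
                                    type = "glacial"))
  expect_error(mis_aggregate(series, tbl_short), "not covered")
})

test_that("range metrics measure areas, overlap and corridors", {
  grid <- list(nrows = 6, ncols = 10, xll = -48, yll = -25, cellsize = 0.1)
  a <- matrix(FALSE, 6, 10); a[2:3, 1:2] <- TRUE
  b <- matrix(FALSE, 6, 10); b[2:3, 8:9] <- TRUE

  same <- range_metrics(a, a, grid)
  expect_equal(same$overlap_cells, sum(a))
  expect_true(same$corridor)
  expect_gt(same$area_km2[["a"]], 0)

  apart <- range_metrics(a, b, grid)
  expect_equal(apart$overlap_cells, 0L)
  expect_false(apart$corridor)

  # a one-cell-wide bridge connects the cores
  bridged <- a | b
  bridged[2, 3:7] <- TRUE
  expect_true(range_metrics(bridged, b, grid)$corridor)

  empty <- matrix(FALSE, 6, 10)
  z <- range_metrics(empty, b, grid)
  expect_equal(z$area_cells[["a"]], 0L)
  expect_false(z$corridor)
})

test_that("the full engine recovers the niche at the present day", {
  w <- simulate_climate_history(grid_rows = 30, grid_cols = 30,
                                n_presences = 78, seed = 1)
  es <- run_paleo_enm(w$anchors[["t0"]], w$anchors, w$forcing, w$occurrences,
                      time_grid = c(0, 21, 130), background_n = 1500, seed = 1)
  ev <- es$evaluation
  expect_true(all(ev$tpr >= 0.7))
  expect_gte(stats::median(ev$tpr), 0.8)
  expect_true(all(ev$d_stat > 0))
  # the committee is at least as sensitive as its median member at present
  idx <- skyisland:::cell_index(es$grid, es$split$test$lon, es$split$test$lat)
  cons_tpr <- mean(es$consensus[[1]][idx])
  expect_gte(cons_tpr, stats::median(ev$tpr) - 1e-9)
})
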