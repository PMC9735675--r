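# hand-built cube: draws[i, j, k] with point predictions = per-condition
# draw means unless given explicitly
make_cube <- function(draws, grid, point = NULL) {
  if (is.null(point)) point <- apply(draws, c(1, 2), mean)
  structure(list(draws = draws, point_pred = point,
                 compounds = dimnames(draws)[[1]], grid = grid,
                 n_draws = dim(draws)[3], seed = NULL),
            class = "sample_cube")
}

small_grid <- condition_grid(ph_values = seq(3, 7, by = 1),
                             tg_values = seq(20, 60, by = 10))

degenerate_cube <- function(values, grid = small_grid, n_draws = 5) {
  # every compound elutes at a fixed time at every condition
  nm <- names(values)
  nc <- nrow(grid$conditions)
  draws <- array(rep(values, times = nc * n_draws),
                 dim = c(length(values), nc, n_draws),
                 dimnames = list(nm, NULL, NULL))
  make_cube(draws, grid)
}

specs_for <- function(nm, hw = 0.5) {
  setNames(lapply(nm, compound_spec, pka = numeric(0),
                  half_width_left = hw, half_width_right = hw), nm)
}

test_that("separation of degenerate peaks is the gap minus half-widths", {
  # identical peaks: S = 0 - 0.5 - 0.5
  cube <- degenerate_cube(c(a = 10, b = 10))
  S <- separation_surface(cube, specs_for(c("a", "b")))
  expect_true(all(S == -1))
  # well-separated peaks: S = 4 - 1
  cube2 <- degenerate_cube(c(a = 14, b = 10))
  S2 <- separation_surface(cube2, specs_for(c("a", "b")))
  expect_true(all(S2 == 3))
  # critical pair governs: three peaks at 10, 14, 22
  cube3 <- degenerate_cube(c(a = 10, b = 14, c = 22))
  S3 <- separation_surface(cube3, specs_for(c("a", "b", "c")))
  expect_true(all(S3 == 3))
})

test_that("separation with stochastic draws matches the sort-based oracle", {
  nm <- c("a", "b", "c")
  nc <- nrow(small_grid$conditions)
  set.seed(314)
  draws <- array(exp(rnorm(3 * nc * 200, mean = rep(c(2.3, 2.6, 2.9), nc * 200),
                           sd = 0.1)),
                 dim = c(3, nc, 200), dimnames = list(nm, NULL, NULL))
  cube <- make_cube(draws, small_grid)
  specs <- specs_for(nm)
  S <- separation_surface(cube, specs)
  expected <- oracle_separation(draws, cube$point_pred,
                                rep(0.5, 3), rep(0.5, 3))
  expect_equal(as.vector(t(S)), expected, tolerance = 1e-12)
})

test_that("larger half-widths never increase separation", {
  nm <- c("a", "b", "c")
  nc <- nrow(small_grid$conditions)
  set.seed(99)
  draws <- array(exp(rnorm(3 * nc * 100, rep(c(2, 2.4, 2.8), nc * 100), 0.08)),
                 dim = c(3, nc, 100), dimnames = list(nm, NULL, NULL))
  cube <- make_cube(draws, small_grid)
  S_small <- separation_surface(cube, specs_for(nm, hw = 0.3))
  S_big <- separation_surface(cube, specs_for(nm, hw = 0.6))
  expect_true(all(S_big < S_small))
})

test_that("separation is invariant to compound input order", {
  nm <- c("a", "b", "c")
  nc <- nrow(small_grid$conditions)
  set.seed(5)
  draws <- array(exp(rnorm(3 * nc * 50, rep(c(2, 2.5, 3), nc * 50), 0.05)),
                 dim = c(3, nc, 50), dimnames = list(nm, NULL, NULL))
  cube1 <- make_cube(draws, small_grid)
  perm <- c(3, 1, 2)
  cube2 <- make_cube(draws[perm, , ], small_grid)
  specs <- specs_for(nm)
  expect_equal(separation_surface(cube1, specs),
               separation_surface(cube2, specs[perm]))
})

test_that("sensitivity of simple surfaces is exact", {
  g <- small_grid
  np <- length(g$ph_values); nt <- length(g$tg_values)
  # constant surface: zero everywhere
  expect_true(all(sensitivity_surface(matrix(5, np, nt), g) == 0))
  # linear surface in coded axes: R = (|2| + |4|)/2 everywhere (one-sided
  # borders are exact for linear surfaces too)
  ph_star <- seq(-1, 1, length.out = np)
  tg_star <- seq(-1, 1, length.out = nt)
  S <- outer(2 * ph_star, 4 * tg_star, `+`)
  expect_equal(sensitivity_surface(S, g), matrix(3, np, nt),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("sensitivity matches the stencil oracle on a random surface", {
  g <- small_grid
  set.seed(12)
  S <- matrix(rnorm(length(g$ph_values) * length(g$tg_values)),
              length(g$ph_values))
  expect_equal(sensitivity_surface(S, g), oracle_sensitivity(S),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analysis time is the worst-compound upper quantile", {
  cube <- degenerate_cube(c(a = 10, b = 14, c = 22))
  A <- analysis_time_surface(cube)
  expect_true(all(A == 22))
  # adding a uniformly faster compound changes nothing
  cube2 <- degenerate_cube(c(a = 10, b = 14, c = 22, d = 3))
  expect_equal(analysis_time_surface(cube2), A, ignore_attr = TRUE)
  # empirical quantile matches the sort-based oracle
  nc <- nrow(small_grid$conditions)
  set.seed(8)
  draws <- array(exp(rnorm(nc * 100, 2.5, 0.2)), dim = c(1, nc, 100),
                 dimnames = list("x", NULL, NULL))
  cube3 <- make_cube(draws, small_grid)
  expect_equal(as.vector(t(analysis_time_surface(cube3))),
               oracle_analysis_time(draws), tolerance = 1e-12)
})

test_that("analysis time is monotone in its quantile level", {
  nc <- nrow(small_grid$conditions)
  set.seed(21)
  draws <- array(exp(rnorm(2 * nc * 80, rep(c(2, 2.7), nc * 80), 0.15)),
                 dim = c(2, nc, 80), dimnames = list(c("a", "b"), NULL, NULL))
  cube <- make_cube(draws, small_grid)
  A50 <- analysis_time_surface(cube, 0.5)
  A90 <- analysis_time_surface(cube, 0.9)
  A99 <- analysis_time_surface(cube, 0.99)
  expect_true(all(A90 >= A50))
  expect_true(all(A99 >= A90))
})

test_that("separation approaches the deterministic gap as noise vanishes", {
  # models with tiny residual sd: S -> point-prediction gap minus widths
  d1 <- random_design("NO_PH", seed = 1)
  d1$retention_time_min <- exp(2 + 0.01 * d1$gradient_time_min)
  d2 <- d1
  d2$retention_time_min <- exp(2.6 + 0.01 * d2$gradient_time_min)
  models <- list(fast = rsm_fit(d1, case = "NO_PH"),
                 slow = rsm_fit(d2, case = "NO_PH"))
  cube <- sample_cube(models, small_grid, n_draws = 400, seed = 2)
  S <- separation_surface(cube, specs_for(c("fast", "slow")))
  gap <- cube$point_pred[2, ] - cube$point_pred[1, ] - 1
  expect_equal(as.vector(t(S)), gap, tolerance = 1e-6)
})

test_that("criteria surfaces are deterministic given a cube", {
  d <- random_design("NO_PH", seed = 4)
  models <- list(a = rsm_fit(d, case = "NO_PH"),
                 b = rsm_fit(transform(d, retention_time_min =
                                            retention_time_min * 2),
                             case = "NO_PH"))
  cube <- sample_cube(models, small_grid, n_draws = 100, seed = 9)
  cr1 <- criteria_surfaces(cube, specs_for(c("a", "b")))
  cr2 <- criteria_surfaces(cube, specs_for(c("a", "b")))
  expect_identical(cr1, cr2)
})

test_that("criteria inputs are validated", {
  cube <- degenerate_cube(c(a = 10))
  expect_error(separation_surface(cube, specs_for("a")), "2 compounds")
  cube2 <- degenerate_cube(c(a = 10, b = 12))
  expect_error(separation_surface(cube2, specs_for(c("a", "b")),
                                  quantile_level = 1.2), "0, 1")
  expect_error(separation_surface(cube2, specs_for("a")), "no compound spec")
  expect_error(sensitivity_surface(matrix(0, 2, 2), small_grid), "matrix")
  expect_error(condition_grid(ph_values = c(1, 2, 4)), "uniformly")
  expect_error(condition_grid(ph_values = c(1, 2)), "3 levels")
})
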