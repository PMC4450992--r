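test_that("angular coordinates follow the counter-clockwise convention", {
  # rank-2 toy: two orthogonal gene patterns, so the PC plane reproduces
  # the construction up to sign and cells fall in distinct angular sectors
  n <- 12
  a <- rep(c(3, -3), each = n / 2)
  b <- rep(c(2, -2, 2, -2), n / 4)
  m <- tibble::tibble(cell_id = sprintf("c%02d", 1:n),
                      stage = rep(c(8L, 16L), n / 2),
                      g1 = 10 + a, g2 = 10 + a, g3 = 10 + b, g4 = 10 - b)
  pr <- pca_project(m, origin = c(0, 0))
  # independent oracle: eigendecomposition of the 2x2 covariance of the
  # two construction coordinates recovers them as the principal axes
  expect_equal(abs(cor(pr$pc1, a)), 1, tolerance = 1e-8)
  expect_equal(abs(cor(pr$pc2, b)), 1, tolerance = 1e-8)
  expect_true(all(pr$theta > -pi & pr$theta <= pi))
  # theta is a pure function of the shifted coordinates
  expect_equal(pr$theta, atan2(pr$pc2, pr$pc1))
  grp <- interaction(a > 0, b > 0)
  rng <- vapply(split(pr$theta, grp), range, numeric(2))
  ov <- function(i, j) min(rng[2, i], rng[2, j]) - max(rng[1, i], rng[1, j])
  expect_true(all(combn(4, 2, function(ij) ov(ij[1], ij[2]) < 0)))
})

test_that("quadrant angles come out as 0 and pi/2", {
  th <- atan2(c(0, 1) - 0, c(1, 0) - 0)
  expect_equal(th, c(0, pi / 2))
  # same convention inside pca_project: a cell at shifted (r, 0) has theta 0
  m <- small_synth()
  pr <- pca_project(m, origin = "auto")
  on_axis <- atan2(pr$pc2 - attr(pr, "origin")[2],
                   pr$pc1 - attr(pr, "origin")[1])
  expect_equal(pr$theta, unname(on_axis))
  expect_true(all(pr$theta > 0 & pr$theta < pi))  # below-cloud origin
})

test_that("projection fails on degenerate dimensions", {
  m <- tibble::tibble(cell_id = c("a", "b"), stage = c(1L, 1L), g1 = c(1, 2),
                      g2 = c(2, 1))
  expect_error(pca_project(m), "at least 3 cells")
})

test_that("mixture fitting recovers planted parameters", {
  set.seed(42)
  x1 <- rnorm(200, mean = 1, sd = 0.5)
  f1 <- fit_stage_mixture(x1)
  expect_equal(f1$m, 1)
  expect_lt(abs(f1$mu - 1), 3 * 0.5 / sqrt(200))

  x2 <- c(rnorm(100, 0, 1), rnorm(100, 4, 1))  # means 4 sd apart
  f2 <- fit_stage_mixture(x2)
  expect_equal(f2$m, 2)
  expect_true(all(abs(f2$tau - 0.5) < 0.1))
  expect_equal(sum(f2$tau), 1, tolerance = 1e-9)
  expect_true(all(f2$sigma2 > 0))
  expect_false(is.unsorted(f2$mu))
})

test_that("degenerate and undersized stages are handled", {
  f <- fit_stage_mixture(rep(0.7, 10))
  expect_equal(f$m, 1)
  expect_equal(f$sigma2, 1e-6)
  expect_error(fit_stage_mixture(c(1, 2, 3)), "at least 5")
})

test_that("mixture density matches the closed form and integrates to one", {
  sm <- fit_stage_mixture(c(rnorm(100, 0, 1), rnorm(100, 4, 1)))
  # standard normal peak
  one <- structure(list(stage = NA, m = 1L, tau = 1, mu = 0,
                        sigma2 = 1, n = 10, loglik = NA,
                        bic = NA), class = "stage_mixture")
  expect_equal(mixture_density(one, 0), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # quadrature oracle
  int <- integrate(function(x) mixture_density(sm, x), -pi - 10, pi + 10,
                   subdivisions = 500L)$value
  expect_equal(int, 1, tolerance = 1e-3)
  # symmetry of two equal components about 0
  sym <- structure(list(stage = NA, m = 2L, tau = c(0.5, 0.5),
                        mu = c(-1, 1), sigma2 = c(0.3, 0.3), n = 10,
                        loglik = NA, bic = NA), class = "stage_mixture")
  xs <- seq(0.1, 3, by = 0.3)
  expect_equal(mixture_density(sym, xs), mixture_density(sym, -xs))
  expect_true(all(mixture_density(sm, seq(-10, 10, by = 0.5)) >= 0))
})

test_that("the pseudo-potential is a gauged monotone transform of density", {
  p <- potential_params()
  expect_equal(pseudo_potential(1, p), 0)
  expect_equal(pseudo_potential(exp(-1), p), 1)
  # gauge invariance: shifting omega shifts U by exactly that constant
  p2 <- potential_params(omega = 3.7)
  f <- c(0.01, 0.1, 1, 2)
  expect_equal(pseudo_potential(f, p2), pseudo_potential(f, p) + 3.7)
  # monotone: argmin U == argmax f on a shared grid
  sm <- fit_stage_mixture(c(rnorm(100, 0, 1), rnorm(100, 4, 1)))
  grid <- seq(-3, 7, length.out = 400)
  fx <- mixture_density(sm, grid)
  expect_equal(which.min(pseudo_potential(fx, p)), which.max(fx))
  # floor keeps U finite even where the density underflows
  expect_true(is.finite(pseudo_potential(0, p)))
})

test_that("landscape interpolation and tilt behave linearly", {
  mk <- function(stage, mu) {
    structure(list(stage = stage, m = 1L, tau = 1, mu = mu, sigma2 = 0.2,
                   n = 50, loglik = NA, bic = NA), class = "stage_mixture")
  }
  same <- list(mk(1L, 0.5), mk(2L, 0.5))
  surf0 <- build_landscape(same, x_resolution = 50, interp_rows = 4)
  z_by_t <- split(surf0$surface$z, surf0$surface$t)
  for (zz in z_by_t) expect_equal(zz, z_by_t[[1]])
  # pure tilt: z(t=1, x) - z(t=0, x) = tilt_rate everywhere
  surft <- build_landscape(same, x_resolution = 50, interp_rows = 4,
                           params = potential_params(tilt_rate = 1))
  zt <- split(surft$surface$z, surft$surface$t)
  expect_equal(zt[[length(zt)]] - zt[[1]], rep(1, 50))
  # midpoint row is the mean of the flanking stage rows when untilted
  diff_mix <- list(mk(1L, 0.2), mk(2L, 1.2))
  surfm <- build_landscape(diff_mix, x_resolution = 50, interp_rows = 1)
  zs <- split(surfm$surface$z, surfm$surface$t)
  expect_equal(zs[[2]], (zs[[1]] + zs[[3]]) / 2)
})

test_that("landscape validates stage ordering and attaches cells", {
  mk <- function(stage, mu) {
    structure(list(stage = stage, m = 1L, tau = 1, mu = mu, sigma2 = 0.2,
                   n = 50, loglik = NA, bic = NA), class = "stage_mixture")
  }
  expect_error(build_landscape(list(mk(2L, 0), mk(1L, 0))), "increasing")
  expect_error(build_landscape(list(mk(1L, 0), mk(1L, 0))), "distinct|increasing")
  m <- small_synth()
  pr <- pca_project(m, origin = "auto")
  mixes <- fit_all_stages(pr)
  surf <- build_landscape(mixes, x_resolution = 60, cells = pr,
                          color_expr = m, color_genes = c("Cdx2", "Eomes"))
  expect_true(all(is.finite(surf$surface$z)))
  expect_equal(nrow(surf$cells), nrow(pr))
  expect_true(all(c("x", "t", "z", "color") %in% names(surf$cells)))
  expect_s3_class(autoplot(surf), "ggplot")
})

test_that("normality diagnostics separate one cell type from a mixture", {
  set.seed(11)
  null_draw <- rnorm(100)
  res <- validate_normality(null_draw)
  expect_gt(res$p_value, 0.01)   # calibration under the null
  mixed <- c(rnorm(50, 0, 0.3), rnorm(50, 4, 0.3))
  expect_lt(validate_normality(mixed)$p_value, 0.01)  # power
  qq <- res$qq_points
  expect_false(is.unsorted(qq$theoretical))
  expect_false(is.unsorted(qq$sample))
  expect_error(validate_normality(c(1, 2)), "between 3 and 5000")
})

test_that("stage mixtures on synthetic data recover the planted counts", {
  for (s in 1:5) {
    m <- generate_synthetic(synthetic_config(seed = s))
    pr <- pca_project(m, origin = "auto")
    mixes <- fit_all_stages(pr)
    stages <- vapply(mixes, function(x) x$stage, numeric(1))
    ms <- vapply(mixes, function(x) x$m, integer(1))
    expect_equal(ms[stages <= 16], rep(1L, sum(stages <= 16)),
                 info = paste("seed", s))
    expect_equal(ms[stages == 32], 2L, info = paste("seed", s))
    expect_equal(ms[stages == 64], 3L, info = paste("seed", s))
  }
})
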