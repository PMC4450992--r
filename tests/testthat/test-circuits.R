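test_that("the two-TF rate law evaluates its closed form exactly", {
  p <- circuit_params()  # alpha 1.5, beta 1, n 4, s 0.5, gamma 1
  # at u = v = s both sigmoids sit at one half
  d <- two_tf_rhs(c(0.5, 0.5), p)
  expect_equal(d, c(0.75, 0.75))
  # at the origin only the inhibition-release term survives
  expect_equal(two_tf_rhs(c(0, 0), p), c(1, 1))
  # frozen from an independent arbitrary-precision evaluation
  expect_equal(two_tf_rhs(c(2.4, 0.05), p),
               c(0.09707962137201041, -0.04796975591384035),
               tolerance = 1e-12)
  # perturbed TF uses its own degradation rate
  pp <- circuit_params(gamma = c(1.5, 1))
  expect_equal(two_tf_rhs(c(1, 1), pp)[1] - two_tf_rhs(c(1, 1), p)[1], -0.5)
  expect_error(two_tf_rhs(c(-0.1, 1), p), "non-negative")
})

test_that("eta pools cluster activation and keeps only decay asymmetric", {
  p <- circuit_params()
  expect_equal(eta(0, 0, 0, 0, p, 1), p$beta)
  # a^n + b^n = s^n at a = b = s / 2^(1/n), activation is alpha / 2
  a <- p$s / 2^(1 / p$n)
  act <- eta(a, a, 10, 10, p, 0) -
    p$beta * p$s^p$n / (p$s^p$n + 2 * 10^p$n)
  expect_equal(act, p$alpha / 2, tolerance = 1e-12)
  # swapping the first two arguments changes only the decay term
  for (i in 1:25) {
    x <- runif(4, 0, 3)
    expect_equal(eta(x[1], x[2], x[3], x[4], p, 1) -
                   eta(x[2], x[1], x[3], x[4], p, 1),
                 -(x[1] - x[2]), tolerance = 1e-12)
  }
})

test_that("the two-cluster system keeps its exchange and decay structure", {
  p <- circuit_params()
  # symmetric manifold is invariant
  d <- two_cluster_rhs(c(0.8, 0.8, 0.3, 0.3), p)
  expect_equal(d[1], d[2])
  expect_equal(d[3], d[4])
  expect_equal(two_cluster_rhs(c(0, 0, 0, 0), p), rep(p$beta, 4))
  # within-cluster differences decay at rate gamma at any state
  set.seed(99)
  for (i in 1:100) {
    st <- runif(4, 0, 3)
    d <- two_cluster_rhs(st, p)
    expect_equal(d[1] - d[2], -p$gamma[1] * (st[1] - st[2]),
                 tolerance = 1e-10)
    expect_equal(d[3] - d[4], -p$gamma[1] * (st[3] - st[4]),
                 tolerance = 1e-10)
  }
})

test_that("force fields report speeds and respect model symmetries", {
  p <- circuit_params()
  ff <- force_field("two_tf", p, resolution = 21)
  expect_equal(ff$speed, sqrt(ff$du^2 + ff$dv^2))
  # reflection symmetry when the degradation rates are equal
  key <- paste(round(ff$u, 9), round(ff$v, 9))
  mirror <- match(paste(round(ff$v, 9), round(ff$u, 9)), key)
  expect_equal(ff$du, ff$dv[mirror])
  # two-cluster slice: on the diagonal the totals move identically
  fc <- force_field("two_cluster", p, resolution = 21)
  diag_rows <- fc[abs(fc$x - fc$y) < 1e-12, ]
  expect_equal(diag_rows$dx, diag_rows$dy)
  expect_error(force_field("two_tf", p, resolution = 1), "resolution")
  expect_s3_class(autoplot(ff), "ggplot")
})

test_that("the unperturbed two-TF circuit is tristable with mirror symmetry", {
  p <- circuit_params()
  fp <- find_fixed_points("two_tf", p)
  expect_equal(count_stable(fp), 3)
  st <- fp[fp$kind == "stable", ]
  # one attractor on the diagonal, the other two mirror images
  expect_true(any(abs(st$u - st$v) < 1e-6))
  off <- st[abs(st$u - st$v) > 1e-6, ]
  expect_equal(sort(off$u), sort(off$v), tolerance = 1e-6)
  expect_true(all(fp$residual <= 1e-10))
  # stable points are minima of motion: the field speed vanishes there
  ff_speed <- sqrt(rowSums(two_tf_rhs(cbind(st$u, st$v), p)^2))
  expect_true(all(ff_speed < 1e-8))
})

test_that("a pure decay system has a single stable fixed point at the origin", {
  p <- circuit_params(alpha = 1e-12, beta = 1e-12, gamma = 1)
  fp <- find_fixed_points("two_tf", p, n_starts = 8)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$kind, "stable")
  expect_equal(c(fp$u, fp$v), c(0, 0), tolerance = 1e-8)
})

test_that("fixed points agree with the damped-descent oracle", {
  p <- circuit_params()
  fp <- find_fixed_points("two_tf", p)
  stable <- fp[fp$kind == "stable", c("u", "v")]
  term <- descent_termini("two_tf", p, resolution = 20)
  expect_equal(nrow(term), nrow(stable))
  # every terminus is one of the stable roots, and vice versa
  d <- as.matrix(dist(rbind(as.matrix(stable), term)))
  cross <- d[seq_len(nrow(stable)), nrow(stable) + seq_len(nrow(term))]
  expect_true(all(apply(cross, 1, min) < 1e-2))
  expect_true(all(apply(cross, 2, min) < 1e-2))
})

test_that("fixed-point sets are equivariant under TF relabelling", {
  p <- circuit_params(gamma = c(1.5, 1))
  q <- circuit_params(gamma = c(1, 1.5))
  fp <- find_fixed_points("two_tf", p)
  fq <- find_fixed_points("two_tf", q)
  expect_equal(nrow(fp), nrow(fq))
  swapped <- fq[order(fq$v, fq$u), ]
  orig <- fp[order(fp$u, fp$v), ]
  expect_equal(orig$u, swapped$v, tolerance = 1e-7)
  expect_equal(orig$v, swapped$u, tolerance = 1e-7)
  expect_equal(sort(orig$kind), sort(swapped$kind))
})

test_that("the perturbed two-cluster circuit keeps three attractors", {
  p <- circuit_params(gamma = c(1, 1.5, 1, 1))
  fp <- find_fixed_points("two_cluster", p)
  expect_equal(count_stable(fp), 3)
  st <- fp[fp$kind == "stable", ]
  # the three attractors remain distinct in cluster totals
  expect_equal(nrow(unique(round(st[, c("x", "y")], 3))), 3)
})

test_that("nonnegativity is preserved along forward trajectories", {
  p <- circuit_params()
  set.seed(5)
  st <- matrix(runif(20 * 2, 0, 3), ncol = 2)
  for (i in 1:2000) st <- st + 0.02 * two_tf_rhs(st, p)
  expect_true(all(st > -1e-9))
})

test_that("count_stable counts only attractors", {
  fp <- find_fixed_points("two_tf", circuit_params(), n_starts = 12)
  expect_equal(count_stable(fp), 3)
  expect_equal(count_stable(fp[fp$kind != "stable", ]), 0L)
  empty <- tibble::tibble(residual = numeric(), max_re = numeric(),
                          kind = character(), marginal = logical())
  expect_equal(count_stable(empty), 0L)
})
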