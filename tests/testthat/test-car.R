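test_that("intrinsic CAR draws satisfy the sum-to-zero constraint", {
  g <- make_lattice(6, 6)
  for (s in 1:5) {
    v <- sample_car_field(g, tau = 1, seed = s)
    expect_lt(abs(sum(v)), 1e-10)
  }
  expect_equal(sample_car_field(g, tau = 0), rep(0, 36))
})

test_that("CAR draws are deterministic given a seed and leave the RNG alone", {
  g <- make_lattice(5, 5)
  set.seed(99)
  before <- .Random.seed
  v1 <- sample_car_field(g, tau = 0.7, seed = 42)
  expect_identical(.Random.seed, before)
  v2 <- sample_car_field(g, tau = 0.7, seed = 42)
  expect_identical(v1, v2)
})

test_that("CAR fields are positively spatially autocorrelated (Moran's I)", {
  skip_if_not_installed("ape")
  g <- make_lattice(10, 10)
  W <- adjacency_matrix(g)
  v <- sample_car_field(g, tau = 1, seed = 1)
  mi <- ape::Moran.I(v, W)
  expect_gt(mi$observed, 0)
  expect_lt(mi$p.value, 0.01)
})

test_that("spatial signal-to-noise of a CAR field grows with tau", {
  skip_if_not_installed("ape")
  # Moran's I of a pure ICAR field is scale-free, so the tau effect is
  # checked on field-plus-fixed-noise, where tau controls signal strength
  g <- make_lattice(10, 10)
  W <- adjacency_matrix(g)
  set.seed(11)
  noise <- rnorm(100, 0, 0.5)
  mor <- vapply(c(0.2, 0.6, 1.5), function(tau) {
    mean(vapply(1:8, function(s) {
      ape::Moran.I(sample_car_field(g, tau, seed = s) + noise, W)$observed
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mor) > 0))
})

test_that("disconnected graphs are rejected by the CAR sampler", {
  g <- nbhd_graph(data.frame(from = c(1, 3), to = c(2, 4)),
                  allow_islands = TRUE)
  expect_error(sample_car_field(g, 1, seed = 1),
               class = "recwalk_error_island")
  expect_error(sample_car_field(make_lattice(3, 3), -1),
               class = "recwalk_error_invalid_argument")
})

test_that("empirical spread of CAR draws matches the Laplacian pseudo-inverse", {
  # independent oracle: marginal variances from MASS::ginv of the Laplacian
  g <- make_lattice(10, 10)
  L <- recwalk:::graph_laplacian(g)
  oracle_rms <- sqrt(mean(diag(MASS::ginv(L))))
  emp <- mean(vapply(1:30, function(s) {
    sd(sample_car_field(g, tau = 1, seed = s))
  }, numeric(1)))
  expect_lt(abs(emp - oracle_rms) / oracle_rms, 0.10)
})
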