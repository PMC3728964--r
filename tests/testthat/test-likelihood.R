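test_that("structure log-likelihood has its closed form for a uniform
           prediction", {
  m <- quick_mesh()
  W <- m$upper - m$lower
  tt <- c(5L, 9L)
  structures <- matrix(2.5, m$n, 2) # uniform, density 2.5 * W
  tr <- fake_trajectory(structures, tt, m)
  sizes <- tibble::tibble(time = rep(tt, c(4, 3)),
                          individual_id = c(1:4, 1:3),
                          log_size = runif(7, 0, 10))
  dens <- tibble::tibble(time = tt, density = rep(2.5 * W, 2))
  obs <- observed_series(sizes, dens)
  expect_equal(structure_loglik(tr, obs), -7 * log(W), tolerance = 1e-12)
})

test_that("a single individual contributes the log of the normalized
           predicted density at its cell", {
  m <- quick_mesh()
  v <- dnorm(m$nodes, 4, 1) * 42
  tr <- fake_trajectory(matrix(v, m$n, 1), 10L, m)
  x0 <- m$nodes[which.max(v)]
  obs <- observed_series(
    tibble::tibble(time = 10, individual_id = 1, log_size = x0),
    tibble::tibble(time = 10, density = sum(v) * m$h))
  expect_equal(structure_loglik(tr, obs),
               log(max(v) / (sum(v) * m$h)), tolerance = 1e-12)
  # an observed size where the prediction is zero sinks the likelihood
  v2 <- v; v2[1] <- 0
  tr2 <- fake_trajectory(matrix(v2, m$n, 1), 10L, m)
  obs2 <- observed_series(
    tibble::tibble(time = 10, individual_id = 1,
                   log_size = m$nodes[1]),
    tibble::tibble(time = 10, density = sum(v2) * m$h))
  expect_identical(structure_loglik(tr2, obs2), -Inf)
})

test_that("no observed individuals gives an empty-sum likelihood of zero", {
  m <- quick_mesh()
  tr <- fake_trajectory(matrix(1, m$n, 1), 4L, m)
  obs <- observed_series(
    tibble::tibble(time = numeric(0), individual_id = integer(0),
                   log_size = numeric(0)),
    tibble::tibble(time = 4, density = 3))
  expect_identical(structure_loglik(tr, obs), 0)
})

test_that("density log-likelihood is the mean-parameterized lognormal", {
  m <- quick_mesh()
  dens <- c(120, 260, 80)
  tr <- fake_trajectory(matrix(rep(dens, each = m$n) / (m$n * m$h), m$n, 3),
                        c(2L, 7L, 9L), m)
  obs <- observed_series(
    tibble::tibble(time = numeric(0), individual_id = integer(0),
                   log_size = numeric(0)),
    tibble::tibble(time = c(2, 7, 9), density = dens))
  s <- 0.3
  manual <- sum(-log(dens) - log(s) - 0.5 * log(2 * pi) -
                  (log(dens) - (log(dens) - s^2 / 2))^2 / (2 * s^2))
  expect_equal(density_loglik(tr, obs, sigma_d = s), manual,
               tolerance = 1e-12)
  # widening the error always lowers the density at its own mean point
  one <- observed_series(
    tibble::tibble(time = numeric(0), individual_id = integer(0),
                   log_size = numeric(0)),
    tibble::tibble(time = 2, density = 120))
  tr1 <- fake_trajectory(matrix(120 / (m$n * m$h), m$n, 1), 2L, m)
  expect_lt(density_loglik(tr1, one, sigma_d = 0.6),
            density_loglik(tr1, one, sigma_d = 0.3))
  # zero observed density lies outside the lognormal support: skipped
  zero <- observed_series(
    tibble::tibble(time = numeric(0), individual_id = integer(0),
                   log_size = numeric(0)),
    tibble::tibble(time = 2, density = 0))
  expect_identical(density_loglik(tr1, zero), 0)
})

test_that("the composite equals l_n + w * l_d for the whole w sweep", {
  obs <- small_dataset()
  m <- quick_mesh()
  withr::with_seed(51, p <- kernel_params(random_species_theta()))
  for (w in c(0, 1, 10, 100, 1000)) {
    cl <- composite_loglik(p, obs, w = w, mesh = m)
    expect_equal(cl$l, cl$l_n + w * cl$l_d,
                 tolerance = 1e-12)
  }
  cl0 <- composite_loglik(p, obs, w = 0, mesh = m)
  expect_identical(cl0$l, cl0$l_n)
})

test_that("fast composite components agree with the reference R
           implementation", {
  obs <- small_dataset()
  m <- quick_mesh()
  withr::with_seed(52, p <- kernel_params(random_species_theta()))
  tt <- obs$densities$time
  scale0 <- obs$densities$density[1]
  cl <- composite_loglik(p, obs, w = 10, mesh = m, scale0 = scale0)
  tr <- simulate_series(p, m, t0 = min(tt), horizon = max(tt) - min(tt),
                        initial_density = scale0)
  expect_equal(cl$l_n, structure_loglik(tr, obs), tolerance = 1e-9)
  expect_equal(cl$l_d, density_loglik(tr, obs, sigma_d = 0.3),
               tolerance = 1e-9)
})

test_that("adding an individual at an interior cell strictly lowers l_n", {
  obs <- small_dataset()
  m <- quick_mesh()
  p <- demo_species()
  base <- composite_loglik(p, obs, w = 0, mesh = m)
  sizes2 <- dplyr::bind_rows(
    obs$sizes,
    tibble::tibble(time = obs$densities$time[1],
                   individual_id = max(obs$sizes$individual_id) + 1,
                   log_size = 5))
  obs2 <- observed_series(sizes2, obs$densities)
  more <- composite_loglik(p, obs2, w = 0, mesh = m,
                           scale0 = base$scale0)
  expect_lt(more$l_n, base$l_n)
})

test_that("l_n is stable under doubling the mesh resolution", {
  obs <- small_dataset()
  p <- demo_species()
  a <- composite_loglik(p, obs, w = 0, mesh = quick_mesh(50))
  b <- composite_loglik(p, obs, w = 0, mesh = quick_mesh(100))
  expect_equal(a$l_n, b$l_n, tolerance = 1e-3)
})

test_that("on clean data the composite peaks at the generating truth", {
  m <- quick_mesh()
  sp <- demo_species()
  withr::with_seed(53, {
    obs <- dataset_from_trajectory(sp, m, times = c(0, 15, 30, 45, 60),
                                   effort = 3)
    l_true <- composite_loglik(sp, obs, w = 1, mesh = m,
                               scale0 = obs$densities$density[1])$l
    worse <- replicate(20, {
      q <- perturb_initial(sp, 20, default_intervals())
      composite_loglik(q, obs, w = 1, mesh = m,
                       scale0 = obs$densities$density[1])$l
    })
  })
  expect_true(all(l_true > worse))
})
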