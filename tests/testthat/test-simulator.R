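# base species with wide viability margins, so freeing one parameter over
# its whole interval never triggers the viability screen (verified in the
# uniformity test below by construction of the intervals)
margin_species <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      withr::with_seed(3,
        cache <<- draw_species(default_intervals(), quick_mesh()))
    cache
  }
})

test_that("degenerate intervals return exactly those values", {
  sp <- margin_species()
  iv <- species_intervals(unname(sp$theta), unname(sp$theta))
  drawn <- draw_species(iv, quick_mesh())
  expect_equal(drawn$theta, sp$theta, tolerance = 0)
})

test_that("draws are uniform within the intervals and seed-reproducible", {
  sp <- margin_species()
  lo <- unname(sp$theta); hi <- lo
  i_free <- match("o_time", param_names("standard"))
  lo[i_free] <- -0.005; hi[i_free] <- 0.005
  iv <- species_intervals(lo, hi)
  withr::with_seed(41, {
    vals <- replicate(1000,
      unname(draw_species(iv, quick_mesh())$theta[i_free]))
  })
  expect_gte(min(vals), -0.005)
  expect_lte(max(vals), 0.005)
  se <- (0.01 / sqrt(12)) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0), 3 * se)
  withr::with_seed(42, a <- draw_species(default_intervals(), quick_mesh()))
  withr::with_seed(42, b <- draw_species(default_intervals(), quick_mesh()))
  expect_identical(a$theta, b$theta)
})

test_that("an unviable box errors with advice after bounded retries", {
  # survival and fecundity annihilated: certain collapse
  lo <- unname(margin_species()$theta); hi <- lo
  lo[c(1, 10)] <- -60; hi[c(1, 10)] <- -40
  iv <- species_intervals(lo, hi)
  expect_error(draw_species(iv, quick_mesh(), max_tries = 5), "viable")
})

test_that("observation times are distinct sorted integers in range", {
  cfg <- sampling_config(n_times = 10, horizon = 100)
  withr::with_seed(43, tt <- draw_observation_times(cfg))
  expect_length(tt, 10)
  expect_true(all(tt == sort(tt)) && !anyDuplicated(tt))
  expect_true(all(tt >= 1 & tt <= 100))
  full <- draw_observation_times(sampling_config(n_times = 20, horizon = 20))
  expect_identical(as.integer(full), 1:20)
  withr::with_seed(44, a <- draw_observation_times(cfg))
  withr::with_seed(44, b <- draw_observation_times(cfg))
  expect_identical(a, b)
  expect_error(sampling_config(n_times = 30, horizon = 20), "horizon")
})

test_that("sampled counts are mean-parameterized lognormal draws", {
  expect_identical(sample_count(137.4, sigma_c = 0), 137L)
  withr::with_seed(45, {
    draws <- replicate(1e5, sample_count(100, sigma_c = 0.3))
  })
  expect_lt(abs(mean(draws) - 100) / 100, 0.01)
  expect_true(all(draws >= 0))
  expect_warning(z <- sample_count(-1, 0.3), "density")
  expect_identical(z, 0L)
})

test_that("size draws follow the structure as a probability distribution", {
  m <- quick_mesh()
  point <- rep(0, m$n); point[17] <- 3
  st <- size_structure(point, m)
  withr::with_seed(46, draws <- sample_sizes(st, 500))
  cell_lo <- m$lower + 16 * m$h
  expect_true(all(draws >= cell_lo & draws <= cell_lo + m$h))
  expect_identical(sample_sizes(st, 0), numeric(0))
  expect_error(sample_sizes(size_structure(rep(0, m$n), m), 5), "zero-mass")

  # bimodal structure: chi-square goodness of fit on mesh cells
  v <- dnorm(m$nodes, 2, 0.5) + dnorm(m$nodes, 7, 0.8)
  stb <- size_structure(v, m)
  withr::with_seed(47, draws <- sample_sizes(stb, 1e5))
  counts <- tabulate(vitalrecon:::mesh_cell(m, draws), nbins = m$n)
  p <- v / sum(v)
  keep <- p > 1e-12
  gof <- suppressWarnings(
    chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
  expect_true(all(draws >= m$lower & draws <= m$upper))
})

test_that("make_dataset composes the full sampling protocol", {
  sp <- margin_species()
  cfg <- sampling_config(n_times = 10, horizon = 100)
  obs <- make_dataset(sp, cfg, quick_mesh(), seed = 48)
  expect_s3_class(obs, "observed_series")
  tt <- obs$densities$time
  expect_length(tt, 10)
  expect_true(all(tt >= 1 & tt <= 100))
  expect_true(all(obs$sizes$log_size >= 0 & obs$sizes$log_size <= 10))
  expect_true(all(obs$densities$sample_count ==
                    as.integer(obs$densities$sample_count)))
  expect_identical(obs$provenance$true_params$theta, sp$theta)
  # byte-identical CSV on a repeated seed
  obs2 <- make_dataset(sp, cfg, quick_mesh(), seed = 48)
  d1 <- withr::local_tempdir()
  write_observations(obs, file.path(d1, "o1.csv"), file.path(d1, "d1.csv"))
  write_observations(obs2, file.path(d1, "o2.csv"), file.path(d1, "d2.csv"))
  expect_identical(readLines(file.path(d1, "o1.csv")),
                   readLines(file.path(d1, "o2.csv")))
  expect_identical(readLines(file.path(d1, "d1.csv")),
                   readLines(file.path(d1, "d2.csv")))
})

test_that("with exhaustive noise-free sampling the empirical structure
           converges to the deterministic one", {
  sp <- margin_species()
  m <- quick_mesh()
  tr <- simulate_series(sp, m, 0, 40, 250)
  st <- vitalrecon:::structure_at(tr, 40)
  count <- 1e5
  withr::with_seed(49, draws <- sample_sizes(st, count))
  emp <- tabulate(vitalrecon:::mesh_cell(m, draws), nbins = m$n) / count
  truth <- st$values / sum(st$values)
  expect_lt(max(abs(emp - truth)), 0.05)
})
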