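# tiny-but-real fitting problem: coarse mesh, short series, few iterations
tiny_fit_setup <- function() {
  list(obs = small_dataset(), mesh = quick_mesh(), iv = default_intervals(),
       control = list(maxit = 40))
}

test_that("perturbation respects the relative error envelope", {
  sp <- demo_species()
  expect_identical(perturb_initial(sp, 0)$theta, sp$theta)
  iv <- default_intervals()
  withr::with_seed(61, {
    for (i in 1:200) {
      q <- perturb_initial(sp, 50, iv)
      rel <- abs(q$theta - sp$theta) / abs(sp$theta)
      expect_true(all(rel <= 0.5 + 1e-12))
      expect_true(all(q$theta >= iv$lower & q$theta <= iv$upper))
    }
  })
  withr::with_seed(62, a <- perturb_initial(sp, 25, iv))
  withr::with_seed(62, b <- perturb_initial(sp, 25, iv))
  expect_identical(a$theta, b$theta)
  expect_error(perturb_initial(sp, -5), ">= 0")
})

test_that("the default start plan is 1 exact + 10 x 4 perturbed starts", {
  plan <- start_plan(demo_species(), seed = 63)
  expect_identical(nrow(plan), 41L)
  expect_identical(sum(plan$error_pct == 0), 1L)
  expect_identical(as.vector(table(plan$error_pct)),
                   c(1L, 10L, 10L, 10L, 10L))
  expect_identical(plan$init[[1]]$theta, demo_species()$theta)
})

test_that("a fit never ends below its starting likelihood", {
  s <- tiny_fit_setup()
  init <- perturb_initial(demo_species(), 0)
  l_init <- composite_loglik(init, s$obs, w = 1, mesh = s$mesh,
                             scale0 = s$obs$densities$density[1])$l
  fit <- fit_single(s$obs, init, s$iv, w = 1, mesh = s$mesh,
                    control = s$control)
  expect_gte(fit$loglik$l, l_init)
  expect_true(all(fit$params$theta >= s$iv$lower - 1e-12 &
                    fit$params$theta <= s$iv$upper + 1e-12))
})

test_that("a degenerate box pins its parameter at the optimum", {
  s <- tiny_fit_setup()
  sp <- demo_species()
  iv <- s$iv
  i <- match("o_time", iv$term)
  iv$lower[i] <- iv$upper[i] <- unname(sp$theta["o_time"])
  fit <- fit_single(s$obs, sp, iv, w = 1, mesh = s$mesh, control = s$control)
  expect_identical(unname(fit$params$theta["o_time"]),
                   unname(sp$theta["o_time"]))
})

test_that("tidy() and glance() summarize a fit", {
  s <- tiny_fit_setup()
  fit <- fit_single(s$obs, demo_species(), s$iv, w = 1, mesh = s$mesh,
                    control = list(maxit = 10))
  td <- tidy(fit)
  expect_identical(td$term, param_names("standard"))
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_equal(g$l, fit$loglik$l)
  expect_equal(g$l, g$l_n + g$w * g$l_d, tolerance = 1e-12)
})

test_that("noise-free generous data recover the generating parameters", {
  m <- quick_mesh()
  sp <- demo_species()
  iv <- default_intervals()
  withr::with_seed(64, {
    obs <- dataset_from_trajectory(sp, m, times = seq(0, 60, by = 10),
                                   effort = 5)
  })
  fit <- fit_single(obs, sp, iv, w = 1, mesh = m)
  expect_true(fit$converged)
  width <- iv$upper - iv$lower
  err <- abs(unname(fit$params$theta - sp$theta))
  tol <- pmax(0.02 * abs(unname(sp$theta)), 0.02 * width)
  expect_true(all(err <= tol))
  # the optimum cannot be (much) better than the truth that generated the data
  l_true <- composite_loglik(sp, obs, w = 1, mesh = m,
                             scale0 = obs$densities$density[1])$l
  expect_gte(fit$loglik$l, l_true - 1e-6)
})

test_that("multi-start bookkeeping tags, sorts and counts runs", {
  s <- tiny_fit_setup()
  plan <- start_plan(demo_species(), error_levels = c(0, 25),
                     replicates = 1, bounds = s$iv, seed = 65)
  fits <- fit_multistart(s$obs, plan, s$iv, w_values = c(0, 1),
                         mesh = s$mesh, control = list(maxit = 15))
  expect_lte(nrow(fits), 4L)
  expect_setequal(unique(fits$w), c(0, 1))
  for (wv in unique(fits$w)) {
    l <- fits$l[fits$w == wv]
    expect_true(all(diff(l) <= 0))
  }
  expect_identical(attr(fits, "n_failed"), 0L)
  expect_equal(fits$l, fits$l_n + fits$w * fits$l_d, tolerance = 1e-12)
})

test_that("solution clustering groups equivalent optima and ignores input
           order", {
  iv <- default_intervals()
  mk <- function(theta, l, w = 1, start_id = 1) {
    tibble::tibble(start_id = start_id, error_pct = 0, w = w,
                   converged = TRUE, l = l, l_n = l, l_d = 0, scale0 = 100,
                   fit = list(structure(
                     list(params = kernel_params(theta), scale0 = 100,
                          mesh = quick_mesh(), w = w, bounds = iv),
                     class = "ipm_fit")))
  }
  th <- unname(demo_species()$theta)
  th2 <- th
  i <- match("s_int", iv$term)
  th2[i] <- th[i] + 0.5 * (iv$upper[i] - iv$lower[i]) # 10 x the 0.05 tol
  same <- dplyr::bind_rows(mk(th, -100, start_id = 1),
                           mk(th, -100, start_id = 2))
  class(same) <- c("ipm_fits", class(same))
  cl <- cluster_solutions(same, iv)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_runs, 2L)

  two <- dplyr::bind_rows(mk(th, -100, start_id = 1),
                          mk(th2, -100.1, start_id = 2))
  class(two) <- c("ipm_fits", class(two))
  expect_identical(nrow(cluster_solutions(two, iv)), 2L)

  withr::with_seed(66, {
    many <- dplyr::bind_rows(lapply(1:6, function(k) {
      mk(if (k %% 2) th else th2, -100 - k * 0.01, start_id = k)
    }))
    class(many) <- c("ipm_fits", class(many))
    ref <- cluster_solutions(many, iv)
    for (r in 1:5) {
      shuf <- many[sample(nrow(many)), ]
      class(shuf) <- c("ipm_fits", class(shuf))
      got <- cluster_solutions(shuf, iv)
      expect_identical(got$l, ref$l)
      expect_identical(got$n_runs, ref$n_runs)
      expect_identical(got$start_id, ref$start_id)
    }
  })
})
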