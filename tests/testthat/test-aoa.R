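test_that("transfer operator follows its closed form and bounds", {
  expect_equal(transfer_operator(100, 100), 1.0)
  expect_equal(transfer_operator(0, 100), exp(-1), tolerance = 1e-12)
  expect_equal(transfer_operator(50, 100), exp(-0.5), tolerance = 1e-12)
  ts <- 0:50
  tf <- transfer_operator(ts, 50)
  expect_true(all(diff(tf) > 0))          # strictly increasing
  expect_true(all(tf > 0 & tf <= 1))
  expect_error(transfer_operator(101, 100), class = "histodbn_parameter_error")
})

test_that("density-decrease factor decays to zero at the final iteration", {
  expect_equal(density_decrease(100, 100), 0.0)
  expect_equal(density_decrease(0, 100), exp(1), tolerance = 1e-12)
  expect_equal(density_decrease(50, 100), exp(0.5) - 0.5, tolerance = 1e-12)
  d <- density_decrease(0:50, 50)
  expect_true(all(diff(d) < 0))           # strictly decreasing
})

test_that("transfer operator and density factor cross exactly once", {
  tmax <- 100
  ts <- 0:tmax
  gap <- transfer_operator(ts, tmax) - density_decrease(ts, tmax)
  expect_equal(sum(diff(sign(gap)) != 0), 1)
})

test_that("population initialization is bounded, seeded and uniform", {
  cfg <- aoa_config(n_pop = 5, max_iter = 10, lower = c(-1, -1),
                    upper = c(1, 1), seed = 7)
  p1 <- withr::with_seed(7, initialize_population(cfg))
  p2 <- withr::with_seed(7, initialize_population(cfg))
  expect_identical(p1, p2)
  expect_true(all(p1$X >= -1 & p1$X <= 1))
  expect_true(all(p1$V > 0 & p1$V < 1))
  expect_true(all(p1$Dn > 0 & p1$Dn < 1))

  degen <- aoa_config(n_pop = 4, max_iter = 5, lower = c(0, 0), upper = c(0, 0))
  pd <- withr::with_seed(1, initialize_population(degen))
  expect_true(all(pd$X == 0))

  big <- aoa_config(n_pop = 1000, max_iter = 1, lower = 0, upper = 1, seed = 2)
  pb <- withr::with_seed(2, initialize_population(big))
  expect_lt(abs(mean(pb$X) - 0.5), 0.05)

  expect_error(aoa_config(n_pop = 1), class = "histodbn_parameter_error")
})

test_that("density and volume move toward the best by the drawn fraction", {
  obj <- list(V = c(0.2, 0.2), Dn = c(0.4, 0.4))
  best <- list(V = c(0.8, 0.8), Dn = c(0.4, 0.4))
  expect_equal(update_density_volume(obj, best, rand = 1)$V, c(0.8, 0.8))
  expect_equal(update_density_volume(obj, best, rand = 0.5)$V, c(0.5, 0.5))
  expect_equal(update_density_volume(best, best, rand = 0.3)$V, best$V)
  # outputs always between old value and best value, and inside (0,1)
  withr::with_seed(31, {
    for (rep in 1:20) {
      o <- list(V = runif(3), Dn = runif(3))
      b <- list(V = runif(3), Dn = runif(3))
      out <- update_density_volume(o, b)
      expect_true(all(out$V >= pmin(o$V, b$V) & out$V <= pmax(o$V, b$V)))
      expect_true(all(out$V > 0 & out$V < 1))
    }
  })
})

test_that("acceleration update follows the density-volume ratio with a guard", {
  expect_equal(update_acceleration(list(Dn = 1, V = 1),
                                   list(Dn = 1, V = 1, A = 1)), 2.0)
  expect_equal(update_acceleration(list(Dn = 0.5, V = 0.5),
                                   list(Dn = 0.5, V = 0.5, A = 1)),
               (0.5 + 0.5 * 1) / (0.5 * 0.5))  # = 4
  guarded <- update_acceleration(list(Dn = 0, V = 0),
                                 list(Dn = 1, V = 1, A = 1))
  expect_true(is.finite(guarded))
})

test_that("acceleration normalization maps min to l and handles degeneracy", {
  expect_equal(normalize_acceleration(c(2, 4, 6)), c(0.1, 0.55, 1.0))
  expect_equal(normalize_acceleration(c(5, 5, 5)), rep(0.55, 3))
  withr::with_seed(32, {
    a <- matrix(rnorm(12), 4, 3)
    an <- normalize_acceleration(a)
    expect_equal(an[which.min(a)], 0.1)
    expect_equal(an[which.max(a)], 1.0)
  })
})

test_that("position updates obey both branches and clamping", {
  cfg <- aoa_config(n_pop = 2, max_iter = 10, lower = rep(-10, 3),
                    upper = rep(10, 3))
  x <- c(1, 2, 3)
  # exploration with x == x_rand leaves x unchanged
  expect_equal(update_position(x, x, rep(0.5, 3), 0.3, 1, cfg), x)
  # exploitation with x == x_best collapses to x_best
  expect_equal(update_position(x, x, rep(0.5, 3), 0.9, 1, cfg), x)
  # worked exploration example
  got <- update_position(0, 1, 0.5, 0.3, 1,
                         aoa_config(n_pop = 2, max_iter = 10,
                                    lower = -10, upper = 10),
                         rand = 0.5)
  expect_equal(got, 0.5)  # 0 + 2 * 0.5 * 0.5 * 1 * (1 - 0)
  # clamping
  clamped <- update_position(9, 10, 1, 0.3, 3,
                             aoa_config(n_pop = 2, max_iter = 10,
                                        lower = -10, upper = 10), rand = 1)
  expect_lte(clamped, 10)
})

test_that("error-rate fitness is the misclassification percentage", {
  expect_equal(fitness_error_rate(c(rep("a", 95), rep("b", 5)), rep("a", 100)), 5)
  expect_equal(fitness_error_rate(c("a", "b"), c("a", "b")), 0)
  expect_equal(fitness_error_rate(c("b", "a"), c("a", "b")), 100)
  expect_error(fitness_error_rate(character(0), character(0)),
               class = "histodbn_parameter_error")
  expect_error(fitness_error_rate("a", c("a", "b")),
               class = "histodbn_parameter_error")
})

test_that("the optimizer is reproducible with a non-increasing best trace", {
  cfg <- aoa_config(n_pop = 10, max_iter = 30, lower = c(-5, -5),
                    upper = c(5, 5), seed = 5)
  r1 <- aoa_optimize(function(x) sum(x^2), cfg)
  r2 <- aoa_optimize(function(x) sum(x^2), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_fitness) <= 0))
  expect_true(all(r1$population$X >= -5 & r1$population$X <= 5))

  const <- aoa_optimize(function(x) 3.5, cfg)
  expect_equal(const$best$fitness, 3.5)
  expect_equal(const$best$iteration, 1)
  expect_true(all(const$trace$best_fitness == 3.5))

  expect_error(aoa_optimize(function(x) NaN, cfg),
               class = "histodbn_objective_error")
})

test_that("tidiers expose the optimizer trace and summary", {
  r <- aoa_optimize(function(x) sum(x^2),
                    aoa_config(n_pop = 5, max_iter = 10,
                               lower = -1, upper = 1, seed = 1))
  expect_s3_class(tidy(r), "tbl_df")
  expect_named(tidy(r), c("iteration", "best_fitness", "mean_fitness"))
  expect_equal(nrow(tidy(r)), 10)
  expect_equal(glance(r)$best_fitness, r$best$fitness)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("search-space decoding covers real, log, int and cat dimensions", {
  sp <- search_space(
    space_dim("lr", "log", -3, -1),
    space_dim("epochs", "int", 1, 5),
    space_dim("act", "cat", values = list("relu", "tanh"))
  )
  dec <- decode_position(c(-2, 2.7, 1.2), sp)
  expect_equal(dec$lr, 1e-2)
  expect_equal(dec$epochs, 3L)   # round-half-up decoding
  expect_equal(dec$act, "relu")
  expect_equal(decode_position(c(-2, 2.5, 1.9), sp)$epochs, 3L)
  expect_error(search_space(), class = "histodbn_parameter_error")
})

test_that("hyperparameter tuning recovers a stub optimum and logs every evaluation", {
  sp <- search_space(space_dim("lr", "real", 0, 0.05))
  cfg <- aoa_config(n_pop = 20, max_iter = 100, seed = 3)
  tn <- tune_hyperparameters(sp, function(hp) abs(hp$lr - 0.01), cfg)
  expect_lt(abs(tn$best$lr - 0.01), 1e-3)
  expect_equal(nrow(tn$log), 20 * 100)
  tn2 <- tune_hyperparameters(sp, function(hp) abs(hp$lr - 0.01), cfg)
  expect_identical(tn$log, tn2$log)  # seeded determinism of the full log
})
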