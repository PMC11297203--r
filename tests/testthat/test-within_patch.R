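test_that("dynamic program reproduces the closed-form boundary cases", {
  # pure dispersal: one propagule after one mean-1 waiting time, any R
  for (R in c(1, 5, 50)) {
    lh <- collective_life_history("intrinsic", 0, R)
    expect_equal(lh$rho, 1)
    expect_equal(lh$tau, 1)
  }
  # pure duplication: no propagule ever; lifespan = sum over n of 1/n
  lh <- collective_life_history("intrinsic", 1, 30)
  expect_equal(lh$rho, 0)
  expect_equal(lh$tau, sum(1 / (1:30)))

  # perfect coordination: alternate duplicate/disperse, one propagule per two
  # resource items, each cycle lasting 1 + 1/2 on average
  lh <- collective_life_history("density_dependent", 1, 20)
  expect_equal(lh$rho, 10)
  expect_equal(lh$tau, 15)
  lh <- collective_life_history("density_dependent", 1, 100)
  expect_equal(lh$rho, 50)
  expect_equal(lh$tau, 75)
})

test_that("dynamic program agrees with exhaustive path enumeration", {
  set.seed(42)
  cases <- data.frame(model = sample(c("intrinsic", "density_dependent"), 12,
                                     replace = TRUE),
                      theta = round(runif(12), 3),
                      R = sample(2:9, 12, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    m <- trait_model(cases$model[i])
    lh <- collective_life_history(m, cases$theta[i], cases$R[i])
    or <- enum_life_history(m, cases$theta[i], cases$R[i])
    expect_equal(lh$rho, or$rho, tolerance = 1e-12)
    expect_equal(lh$tau, or$tau, tolerance = 1e-12)
  }
})

test_that("density-dependent model at theta = 0.5 collapses to the intrinsic model", {
  a <- collective_life_history("density_dependent", 0.5, 37)
  b <- collective_life_history("intrinsic", 0.5, 37)
  expect_equal(a$rho, b$rho)
  expect_equal(a$tau, b$tau)
})

test_that("propagule output never exceeds the perfect-coordination bound R/2", {
  thetas <- seq(0.01, 1, by = 0.01)
  for (R in c(2, 3, 7, 20, 41, 100)) {
    for (kind in c("intrinsic", "density_dependent")) {
      rho <- ecoscaffold:::life_history_grid(trait_model(kind), thetas, R)$rho
      expect_true(all(rho <= R / 2 + 1e-12))
      at_bound <- abs(rho - R / 2) < 1e-9
      if (kind == "density_dependent" && R %% 2 == 0) {
        expect_true(all(thetas[at_bound] == 1))
      } else {
        expect_false(any(at_bound))
      }
    }
  }
})

test_that("intrinsic viability is an interval (0, theta_max) with rho = 1 at its edge", {
  for (R in c(10, 50, 100)) {
    theta_max <- solve_theta_max("intrinsic", R)
    expect_lt(theta_max, 1)
    expect_gt(theta_max, 0)
    expect_equal(collective_life_history("intrinsic", theta_max, R)$rho, 1,
                 tolerance = 1e-5)
    inside <- seq(0.05, theta_max - 0.02, length.out = 9)
    rho <- ecoscaffold:::life_history_grid(trait_model("intrinsic"), inside, R)$rho
    expect_true(all(rho > 1))
    expect_false(viability("intrinsic", min(theta_max + 0.01, 1), R))
  }
})

test_that("single-patch simulation is reproducible and exact for deterministic policies", {
  # perfect coordination fixes the outcome sequence; only times are random
  for (seed in c(1, 99)) {
    s <- simulate_single_patch("density_dependent", 1, 20, seed = seed)
    expect_identical(s$propagules, 10L)
  }
  s <- simulate_single_patch("intrinsic", 0, 5, seed = 3)
  expect_identical(s$propagules, 1L)
  expect_equal(nrow(s$trajectory), 1)

  a <- simulate_single_patch("intrinsic", 0.6, 20, seed = 7)
  b <- simulate_single_patch("intrinsic", 0.6, 20, seed = 7)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("Monte-Carlo life histories agree with the dynamic program", {
  set.seed(2024)
  nrep <- 10000
  cases <- data.frame(model = sample(c("intrinsic", "density_dependent"), 6,
                                     replace = TRUE),
                      theta = runif(6, 0.2, 0.9),
                      R = sample(5:30, 6))
  for (i in seq_len(nrow(cases))) {
    m <- trait_model(cases$model[i])
    lh <- collective_life_history(m, cases$theta[i], cases$R[i])
    mc <- mc_life_history(m, cases$theta[i], cases$R[i], nrep)
    expect_lt(abs(mc$rho_hat - lh$rho), 4 * mc$rho_se + 1e-9)
    expect_lt(abs(mc$tau_hat - lh$tau), 4 * mc$tau_se + 1e-9)
  }
})

test_that("rho_curve finds the bistable landscape in large patches only", {
  rc <- rho_curve("density_dependent", 100)
  ex <- rc$extrema
  expect_equal(sum(ex$type == "max"), 1)
  expect_equal(sum(ex$type == "min"), 1)
  expect_lt(abs(ex$theta[ex$type == "max"] - 0.41), 0.02)
  expect_lt(abs(ex$theta[ex$type == "min"] - 0.66), 0.02)

  # small patches: no interior extremum between 0.5 and 1, rho rising to 1
  rc20 <- rho_curve("density_dependent", 20)
  upper <- rc20$extrema[rc20$extrema$theta > 0.5, ]
  expect_equal(nrow(upper), 0)
  tail_curve <- rc20$curve[rc20$curve$theta >= 0.5, ]
  expect_true(all(diff(tail_curve$rho) > 0))

  expect_error(rho_curve("intrinsic", 10, theta_grid = c(0.2, 0.8)),
               "at least 3")
  expect_error(rho_curve("intrinsic", 10, theta_grid = c(0.2, 0.2, 0.8)),
               "strictly increasing")
})

test_that("life-history curves round-trip through CSV", {
  curves <- life_history_curve("density_dependent", 20,
                               thetas = seq(0.1, 0.9, by = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_history_csv(curves, path)
  back <- utils::read.csv(path)
  expect_equal(back$rho, curves$rho)
  expect_equal(back$theta, curves$theta)
})
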