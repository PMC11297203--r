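test_that("invasion fitness vanishes on the diagonal and tracks the rho landscape", {
  for (th in c(0.3, 0.5, 0.7)) {
    expect_equal(invasion_fitness(th, th, "intrinsic", 50), 0)
  }
  # sign(s) = sign(rho_mut - rho_res) across a grid of viable pairs
  grid <- seq(0.15, 0.9, by = 0.05)
  lh <- ecoscaffold:::life_history_grid(trait_model("density_dependent"),
                                        grid, 60)
  viable <- which(lh$rho > 1)
  for (i in viable) {
    for (j in viable) {
      s <- invasion_fitness(grid[i], grid[j], "density_dependent", 60)
      expect_equal(sign(s), sign(lh$rho[i] - lh$rho[j]))
    }
  }
  # the anti-coordinated peak invades the ancestral value in large patches
  expect_gt(invasion_fitness(0.41, 0.50, "density_dependent", 100), 0)
  expect_error(invasion_fitness(0.5, 0.995, "intrinsic", 100), "not viable")
})

test_that("pairwise invasibility plot is antisymmetric with a zero diagonal", {
  pip <- pairwise_invasibility("density_dependent", 60,
                               grid = seq(0.2, 0.9, by = 0.05))
  sgn <- pip$sign
  viable_cols <- which(!is.na(sgn[1, ]))
  expect_true(all(diag(sgn)[viable_cols] == 0))
  both <- viable_cols
  expect_true(all(sgn[both, both] == -t(sgn[both, both])))
  # long format covers the full grid
  df <- as.data.frame(pip)
  expect_equal(nrow(df), length(pip$grid)^2)
})

test_that("ESS structure: bistable at R = 100, monostable at R = 20", {
  rep100 <- find_ess("density_dependent", 100)
  expect_equal(nrow(rep100$ess), 2)
  interior <- rep100$ess[!rep100$ess$boundary, ]
  expect_lt(abs(interior$theta - 0.41), 0.02)
  expect_true(any(rep100$ess$boundary & rep100$ess$theta == 1))
  expect_lt(abs(rep100$valleys$theta - 0.66), 0.02)

  rep20 <- find_ess("density_dependent", 20)
  expect_equal(nrow(rep20$ess), 1)
  expect_equal(rep20$ess$theta, 1)
  expect_equal(nrow(rep20$valleys), 0)

  # every interior ESS is a strict local max of rho, every valley a strict min
  for (ex in list(list(r = rep100, R = 100))) {
    for (k in seq_len(nrow(ex$r$ess))) {
      if (ex$r$ess$boundary[k]) next
      th <- ex$r$ess$theta[k]
      rho <- sapply(c(th - 1e-3, th, th + 1e-3),
                    function(t) collective_life_history("density_dependent", t, ex$R)$rho)
      expect_gt(rho[2], rho[1]); expect_gt(rho[2], rho[3])
    }
    for (k in seq_len(nrow(ex$r$valleys))) {
      th <- ex$r$valleys$theta[k]
      rho <- sapply(c(th - 1e-3, th, th + 1e-3),
                    function(t) collective_life_history("density_dependent", t, ex$R)$rho)
      expect_lt(rho[2], rho[1]); expect_lt(rho[2], rho[3])
    }
  }
})

test_that("intrinsic model has a single ESS that increases with patch size", {
  ess <- sapply(c(10, 50, 100), function(R) {
    rep <- find_ess("intrinsic", R)
    expect_equal(nrow(rep$ess), 1)
    expect_equal(nrow(rep$valleys), 0)
    rep$ess$theta
  })
  expect_true(all(diff(ess) > 0))
})

test_that("fold bifurcation of the density-dependent landscape sits at R* = 39", {
  scan <- fold_bifurcation_scan("density_dependent", 30, 50)
  expect_identical(scan$R_star, 39L)
  counts <- scan$scan
  expect_true(all(counts$n_interior_extrema[counts$R <= 39] == 0))
  expect_true(all(counts$n_interior_extrema[counts$R >= 40] == 2))

  # intrinsic model: no fold anywhere
  scan_i <- fold_bifurcation_scan("intrinsic", 30, 50)
  expect_true(is.na(scan_i$R_star))
  expect_true(all(scan_i$scan$n_interior_extrema == 1))

  # degenerate single-R scan reports no fold
  one <- fold_bifurcation_scan("density_dependent", 25, 25)
  expect_true(is.na(one$R_star))
})

test_that("trait substitution follows the gradient and shows hysteresis", {
  dd <- "density_dependent"
  # constant large patches: ancestral value slides to the anti-coordinated peak
  traj <- trait_substitution_trajectory(dd, data.frame(duration = Inf, R = 100), 0.5)
  expect_lt(abs(trajectory_endpoint(traj) - 0.41), 0.02)

  # scaffold-and-revert: endpoint jumps to perfect coordination and stays
  sched <- data.frame(duration = c(Inf, Inf, Inf), R = c(100, 20, 100))
  traj2 <- trait_substitution_trajectory(dd, sched, 0.5)
  expect_equal(trajectory_endpoint(traj2), 1, tolerance = 1e-6)

  # a zero-duration scaffold changes nothing
  sched0 <- data.frame(duration = c(Inf, 0, Inf), R = c(100, 20, 100))
  traj0 <- trait_substitution_trajectory(dd, sched0, 0.5)
  # both sit at the anti-coordinated peak, up to the substitution step size
  expect_lt(abs(trajectory_endpoint(traj0) - trajectory_endpoint(traj)), 2e-3)

  # intrinsic control: the trait tracks the single optimum, no hysteresis
  tr_i <- trait_substitution_trajectory("intrinsic",
                                        data.frame(duration = Inf, R = 100), 0.5)
  tr_i2 <- trait_substitution_trajectory("intrinsic",
    data.frame(duration = c(Inf, Inf, Inf), R = c(100, 20, 100)), 0.5)
  expect_equal(trajectory_endpoint(tr_i2), trajectory_endpoint(tr_i),
               tolerance = 2e-3)

  expect_error(trait_substitution_trajectory(dd,
    data.frame(duration = Inf, R = 100), 0), "not viable")
})

test_that("endogenisation conditions hold for coordination but not the intrinsic trait", {
  rep <- check_endogenisation_conditions("density_dependent", 20, 100, 0.5)
  expect_true(rep$condition1)
  expect_true(rep$condition2)
  expect_true(rep$condition3)
  expect_true(rep$endogenisable)
  expect_lt(abs(rep$basin_boundary_nonscaffold - 0.66), 0.02)
  expect_equal(rep$endpoint_scaffold, 1, tolerance = 1e-6)

  rep_i <- check_endogenisation_conditions("intrinsic", 20, 100, 0.5)
  expect_false(rep_i$condition1)
  expect_false(rep_i$endogenisable)

  # identical environments cannot lose the ancestral ESS
  rep_same <- check_endogenisation_conditions("density_dependent", 100, 100, 0.5)
  expect_false(rep_same$condition2)
  expect_false(rep_same$endogenisable)
})
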