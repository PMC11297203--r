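test_that("endpoint classification uses the computed valley, not a constant", {
  ess100 <- find_ess("density_dependent", 100)
  expect_equal(classify_endpoint(0.95, "density_dependent", 100, ess100),
               "coordinated_branch")
  expect_equal(classify_endpoint(0.40, "density_dependent", 100, ess100),
               "ancestral_branch")
  # threshold sits exactly at the valley
  v <- ess100$valleys$theta[1]
  expect_equal(classify_endpoint(v + 1e-4, "density_dependent", 100, ess100),
               "coordinated_branch")
  expect_equal(classify_endpoint(v - 1e-4, "density_dependent", 100, ess100),
               "ancestral_branch")
  # monostable landscape: everything belongs to the single (coordinated) ESS
  expect_equal(classify_endpoint(0.3, "density_dependent", 20),
               "coordinated_branch")
})

test_that("scaffolding long enough to cross the valley endogenises coordination", {
  long_T <- run_temporary_scaffolding(T0 = 200, T_scaffold = 2000,
                                      replicates = 4, base_seed = 11,
                                      D = 100, t_post = 1200)
  expect_equal(long_T$fraction_endogenised, 1)
  expect_true(all(long_T$results$theta_end > 0.9))

  no_T <- run_temporary_scaffolding(T0 = 200, T_scaffold = 0,
                                    replicates = 4, base_seed = 11,
                                    D = 100, t_post = 1200)
  expect_equal(no_T$fraction_endogenised, 0)
  expect_true(all(abs(no_T$results$theta_end - 0.41) < 0.1))
})

test_that("gradient run shows the Goldilocks sequence", {
  fold <- fold_bifurcation_scan("density_dependent", 35, 45)$R_star
  res <- run_goldilocks_gradient(R_values = seq(100L, 3L),
                                 patches_per_class = 10, t_end = 5000,
                                 seed = 5, snapshot_interval = 25,
                                 fold_R = fold)
  ph <- res$phases
  # phase 1: the ancestral type cannot hold the poorest layers
  expect_false(is.na(ph$R0))
  expect_gt(ph$R0, min(res$R_values))
  # phase 2: coordination appears in the Goldilocks band (below the fold)
  # while the richest layer is still ancestral
  expect_false(is.na(ph$first_coordination_goldilocks_time))
  expect_gte(ph$first_coordination_goldilocks_R, ph$R0)
  pl <- res$per_layer
  rich_then <- pl$mean_theta[pl$layer_R == 100 &
                               pl$time == ph$first_coordination_goldilocks_time]
  expect_lt(rich_then, 0.6)
  # phase 3: the richest layer is eventually back-invaded
  expect_lt(ph$first_coordination_goldilocks_time, ph$back_invasion_time)
  # occupancy never exceeds the patches available per layer
  expect_true(all(res$per_layer$occupied <= 10))

  # negative control: severing inter-layer dispersal traps the rich layers
  # on the ancestral branch
  g <- build_gradient_graph(c(60L, 20L), patches_per_class = 15)
  keep_within <- function(i) g$adj[[i]][g$layer[g$adj[[i]]] == g$layer[i]]
  g$adj <- lapply(seq_len(g$D), keep_within)
  rich <- which(g$layer == 60L)
  sim <- run_gillespie(sim_config("density_dependent", 3000, seed = 6,
                                  snapshot_interval = 100),
                       g, init_metapop(g, rich[1:5], 0.5))
  thetas <- unlist(sim$final_state$thetas[rich])
  expect_gt(length(thetas), 0)
  expect_lt(mean(thetas), 0.6)  # still on the ancestral side of the valley
})

test_that("CLI subcommands run and fail loudly on bad input", {
  out_csv <- withr::local_tempfile(fileext = ".csv")
  expect_output(st <- scaffolding_cli(c("life-history", "--model", "intrinsic",
                                        "--theta", "0", "--R", "50",
                                        "--out", out_csv)),
                "rho 1")
  expect_identical(st, 0L)
  lh <- utils::read.csv(out_csv)
  expect_equal(lh$rho, 1)
  expect_equal(lh$tau, 1)

  out_json <- withr::local_tempfile(fileext = ".json")
  expect_output(st <- scaffolding_cli(c("ess", "--model", "dd",
                                        "--R", "100", "--out", out_json)))
  expect_identical(st, 0L)
  rep <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  expect_equal(nrow(rep$ess), 2)

  expect_message(st_bad <- scaffolding_cli(c("unknown-cmd")), "unknown")
  expect_identical(st_bad, 1L)
  expect_message(st_cfg <- scaffolding_cli(c("simulate", "--config",
                                             "/nonexistent.json",
                                             "--seed", "1",
                                             "--out", tempfile())),
                 "not found")
  expect_identical(st_cfg, 1L)
})
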