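test_that("geometry and receptor placement obey the stated bounds", {
  g <- synapse_geometry()
  expect_equal(g$cleft, 0.02)
  expect_equal(g$cluster, 0.2)
  expect_error(synapse_geometry(cleft_width = 0), "cleft")
  expect_error(synapse_geometry(escape_radius = 0.5), "escape_radius")

  rec <- place_receptors(g, 300)
  expect_equal(nrow(rec), 300L)
  expect_true(all(abs(rec) <= 0.1 + 1e-12))
  # areal density 300 / (0.2 um)^2 = 7500 per um^2
  expect_equal(300 / g$cluster^2, 7500)
  # grid placement never overlaps capture disks
  dmin <- min(dist(rec))
  expect_gt(dmin, 2 * 5 / 1000)
  expect_equal(nrow(place_receptors(g, 0)), 0L)
  expect_error(place_receptors(g, 300, capture_radius = 10), "packing")
  ru <- place_receptors(g, 50, "uniform_random", seed = 3)
  expect_true(all(abs(ru) <= 0.1))
  # same count, 64-fold lower density on a 1600 nm cluster
  g2 <- synapse_geometry(cluster_side = 1600)
  expect_equal((300 / g2$cluster^2) * 64, 7500)
})

test_that("binding probability calibration bridges to mass action", {
  expect_equal(calibrate_binding_probability(0, 0.3, 1e-4), 0)
  p1 <- calibrate_binding_probability(10, 0.3, 1e-4)
  expect_gt(p1, 0); expect_lt(p1, 1)
  # p scales with sqrt(dt) so the flux per unit time is dt-invariant
  p2 <- calibrate_binding_probability(10, 0.3, 4e-4)
  expect_equal(p2 / p1, 2, tolerance = 1e-12)
  expect_error(calibrate_binding_probability(1e6, 0.3, 1), "decrease dt")

  # well-mixed box reproduces k_on * C * N within 5% (~16k bindings)
  v <- validate_binding_calibration(k_on = 200, D = 0.3, dt = 1e-4,
                                    n_molecules = 5000, box_side = 0.25,
                                    t_total = 3, seed = 2)
  expect_gt(v$n_bindings, 10000)
  expect_lt(abs(v$ratio - 1), 0.05)
  # halving dt leaves the flux invariant within 2%
  v2 <- validate_binding_calibration(k_on = 200, D = 0.3, dt = 5e-5,
                                     n_molecules = 5000, box_side = 0.25,
                                     t_total = 3, seed = 3)
  expect_lt(abs(v2$ratio / v$ratio - 1), 0.02)
})

test_that("step resolution guard is enforced and auto-derived", {
  expect_error(sim_config(dt = 1e-3), "resolution guard")
  for (D in c(0.1, 0.3, 0.8)) {
    cfg <- sim_config(D = D)
    expect_lt(sqrt(4 * D * cfg$dt), 0.02 / 2)
  }
  cfg10 <- sim_config(geometry = synapse_geometry(cleft_width = 10))
  expect_lt(sqrt(4 * 0.3 * cfg10$dt), 0.01 / 2)
})

test_that("a trial conserves molecules and is seed-deterministic", {
  cfg <- small_sim_config()
  tr <- run_trial(cfg)
  released_at <- function(t) cfg$n_molecules *
    vapply(t, function(s) sum(cfg$release_times < s), numeric(1))
  expect_true(all(tr$free + tr$bound + tr$escaped ==
                    released_at(tr$time)))
  expect_true(all(tr$open <= cfg$n_receptors))
  expect_true(all(tr$open >= 0))
  tr2 <- run_trial(cfg)
  expect_identical(tr$open, tr2$open)
  expect_identical(tr$free, tr2$free)
  cfg3 <- small_sim_config(); cfg3$seed <- 12L
  tr3 <- run_trial(cfg3)
  expect_false(identical(tr$open, tr3$open))
})

test_that("open count rises then decays back toward zero", {
  ens <- run_ensemble(sim_config(n_molecules = 1500, duration = 40,
                                 seed = 5), n_seeds = 4)
  ipk <- which.max(ens$mean)
  expect_gt(ens$mean[ipk], 4)
  expect_lt(ens$time[ipk], 6)         # peak within the first few ms
  # the default scheme holds agonist through desensitization cycles, so
  # the tail decays but retains a slow component at 40 ms
  expect_lt(tail(ens$mean, 1), 0.55 * ens$mean[ipk])
})

test_that("degenerate trials behave: no receptors, frozen diffusion", {
  tr0 <- run_trial(small_sim_config(n_receptors = 0))
  expect_true(all(tr0$open == 0))
  expect_true(all(tr0$bound == 0))
  expect_gt(tail(tr0$escaped, 1), 0)
  # D = 0: molecules released off-cluster never reach the receptors
  cfg <- small_sim_config(D = 0, dt = 6e-5,
                          release_pos = c(0.4, 0.4, 0.019))
  trf <- run_trial(cfg)
  expect_true(all(trf$open == 0))
  expect_true(all(tail(trf$free, 1) == cfg$n_molecules))
})

test_that("per-receptor event log tracks bindings and state changes", {
  cfg <- small_sim_config(record_events = TRUE, n_molecules = 800)
  tr <- run_trial(cfg)
  ev <- tr$events
  expect_true(nrow(ev) > 0)
  expect_true(all(ev$receptor >= 1 & ev$receptor <= cfg$n_receptors))
  labs <- cfg$scheme$states$label
  expect_true(all(ev$from %in% labs) && all(ev$to %in% labs))
  # replaying the log gives the final receptor states
  st <- setNames(rep(labs[1], cfg$n_receptors), NULL)
  for (i in seq_len(nrow(ev))) st[ev$receptor[i]] <- ev$to[i]
  expect_identical(st, tr$receptor_state)
})

test_that("free-diffusion displacement variance follows 2 D k dt", {
  dx <- synkin:::cpp_free_displacement(100000L, 0.3, 1e-4, 20L, 77)
  expect_lt(abs(var(dx) / (2 * 0.3 * 20 * 1e-4) - 1), 0.01)
})

test_that("ensemble averaging shrinks the SEM as 1/sqrt(n)", {
  cfg <- small_sim_config(n_molecules = 600)
  e1 <- run_ensemble(cfg, n_seeds = 4)
  e2 <- run_ensemble(cfg, n_seeds = 16)
  expect_equal(length(e1$mean), length(e2$mean))
  expect_equal(ncol(e1$trials), 4L)
  # pooled SEM ratio ~ sqrt(16/4) = 2
  i <- which(e2$sem > 0)
  expect_equal(median(e1$sem[i] / e2$sem[i]), 2, tolerance = 0.5)
  expect_error(run_ensemble(cfg, n_seeds = 1), "n_seeds")
})

test_that("well-mixed gating matches the master equation within 3 SEM", {
  sch <- scheme_biliganded()
  n <- 10000
  ch <- simulate_channels_uniform(sch, conc_constant(0.05),
                                  n_channels = n, duration = 50,
                                  dt = 0.005, sample_dt = 0.25, seed = 31)
  m <- solve_master_equation(sch, conc_constant(0.05), duration = 50,
                             dt = 0.25)
  dev <- ch$open / n - m$open
  sem <- pmax(sqrt(pmax(m$open * (1 - m$open), 1e-9) / n), 2 / n)
  z <- dev / sem
  # unbiased: mean standardized deviation small (samples are correlated
  # within the ensemble, so the mean z fluctuates more than 1/sqrt(T));
  # pointwise within the binomial band (4 sigma cap, 3 sigma for 95%)
  expect_lt(abs(mean(z)), 1)
  expect_true(all(abs(z) <= 4))
  expect_gte(mean(abs(z) <= 3), 0.95)
})

test_that("sweep rejects empty values and labels rows with provenance", {
  base <- small_sim_config()
  expect_error(parameter_sweep(base, "diffusion", numeric(0)),
               "non-empty")
  sw <- parameter_sweep(base, "diffusion", c(0.3, 0.8), n_seeds = 2)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("peak_open", "decay_tau", "config_hash",
                    "first_seed") %in% names(sw)))
  expect_false(sw$config_hash[1] == sw$config_hash[2])
})
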