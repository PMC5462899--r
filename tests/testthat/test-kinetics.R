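test_that("generator matrix is built correctly and conserves probability", {
  sch <- two_state_scheme(beta = 2, alpha = 8)
  Q <- build_generator(sch, 0)
  expect_equal(unname(Q), matrix(c(-2, 8, 2, -8), 2, 2))

  # rows sum to zero for every template scheme and concentration
  for (sch in list(scheme_biliganded(), scheme_petrini(),
                   two_state_scheme())) {
    for (conc in c(0, 0.1, 1, 10)) {
      Q <- build_generator(sch, conc)
      expect_equal(rowSums(Q), rep(0, nrow(Q)), ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_true(all(Q[row(Q) != col(Q)] >= 0))
    }
  }
})

test_that("order-1 entries vanish at zero agonist and scale linearly", {
  for (sch in list(scheme_biliganded(), scheme_petrini())) {
    tr <- sch$transitions
    Q0 <- build_generator(sch, 0)
    i1 <- cbind(match(tr$from[tr$order == 1], sch$states$label),
                match(tr$to[tr$order == 1], sch$states$label))
    expect_true(all(Q0[i1] == 0))
    Q1 <- build_generator(sch, 0.5)
    Q2 <- build_generator(sch, 1.0)
    expect_equal(Q2[i1], 2 * Q1[i1])
    i0 <- cbind(match(tr$from[tr$order == 0], sch$states$label),
                match(tr$to[tr$order == 0], sch$states$label))
    expect_equal(Q1[i0], Q2[i0])
  }
})

test_that("malformed schemes and inputs are rejected", {
  st <- data.frame(label = c("C", "O"), open = c(FALSE, TRUE),
                   n_bound = c(0L, 1L))
  expect_error(build_generator(two_state_scheme(), -1), "concentration")
  expect_error(kinetic_scheme(st, data.frame(from = "C", to = "X",
                                             rate = 1, order = 0L)),
               "unknown state")
  expect_error(kinetic_scheme(st[c(1, 1), ],
                              data.frame(from = "C", to = "C", rate = 1,
                                         order = 0L)),
               "unique")
  expect_error(kinetic_scheme(
    data.frame(label = c("C", "O"), open = c(FALSE, FALSE),
               n_bound = c(0L, 0L)),
    data.frame(from = "C", to = "O", rate = 1, order = 0L)),
    "open state")
  # binding transition must add exactly one agonist molecule
  expect_error(kinetic_scheme(st,
    data.frame(from = "O", to = "C", rate = 1, order = 1L)),
    "n_bound")
  expect_error(kinetic_scheme(st,
    data.frame(from = "C", to = "O", rate = -2, order = 0L)),
    "rate")
})

test_that("master equation matches the two-state closed form", {
  sch <- two_state_scheme(beta = 2, alpha = 8)
  tr <- solve_master_equation(sch, 0, duration = 0.3, dt = 0.01)
  # relaxation toward beta/(alpha+beta) with rate alpha+beta
  expect_equal(tail(tr$open, 1), 0.2 * (1 - exp(-10 * 0.3)),
               tolerance = 1e-9)
  long <- solve_master_equation(sch, 0, duration = 5, dt = 0.01)
  expect_equal(tail(long$open, 1), 0.2, tolerance = 1e-6)
  expect_equal(unname(steady_state(sch, 0)), c(0.8, 0.2),
               tolerance = 1e-12)
})

test_that("master equation conserves probability and handles pulses", {
  sch <- scheme_biliganded()
  tr <- solve_master_equation(sch, conc_pulse(1, 0.5), duration = 20,
                              dt = 0.02)
  expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
  expect_gt(max(tr$open), 0)
  # converges to the agonist-free steady state (all unbound) eventually
  far <- solve_master_equation(sch, conc_constant(0.3), duration = 200,
                               dt = 0.1)
  expect_equal(unname(far$occupancy[nrow(far$occupancy), ]),
               unname(steady_state(sch, 0.3)), tolerance = 1e-5)
})

test_that("zero-duration master equation returns the initial occupancy", {
  sch <- scheme_biliganded()
  p0 <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  tr <- solve_master_equation(sch, 1, p0 = p0, duration = 0)
  expect_equal(nrow(tr$occupancy), 1L)
  expect_equal(unname(tr$occupancy[1, ]), p0)
  expect_error(solve_master_equation(sch, 1, p0 = c(1, 1, 0, 0, 0),
                                     duration = 1),
               "sum to 1")
})

test_that("Gillespie ensemble agrees with the master equation", {
  sch <- two_state_scheme(beta = 2, alpha = 8)
  n <- 10000
  g <- simulate_gillespie_ensemble(sch, 0, n_channels = n, duration = 50,
                                   dt = 0.05, seed = 42)
  m <- solve_master_equation(sch, 0, duration = 50, dt = 0.05)
  # counts conserved at every sample
  expect_true(all(rowSums(g$occupancy) == n))
  # open fraction at 1 ms within 3 standard errors of the oracle
  i1 <- which.min(abs(g$time - 1))
  p <- m$open[i1]
  expect_lt(abs(g$open[i1] / n - p), 3 * sqrt(p * (1 - p) / n))
  # pointwise over the full 50 ms window (binomial 3-sigma band)
  dev <- abs(g$open / n - m$open)
  bound <- 3 * sqrt(pmax(m$open * (1 - m$open), 1e-6) / n)
  expect_gt(mean(dev <= bound), 0.99)
})

test_that("Gillespie is seed-deterministic and freezes with zero rates", {
  sch <- two_state_scheme()
  g1 <- simulate_gillespie_ensemble(sch, 0, n_channels = 100,
                                    duration = 10, seed = 7)
  g2 <- simulate_gillespie_ensemble(sch, 0, n_channels = 100,
                                    duration = 10, seed = 7)
  expect_identical(g1$occupancy, g2$occupancy)
  frozen <- two_state_scheme(beta = 0, alpha = 0)
  g0 <- simulate_gillespie_ensemble(frozen, 0, n_channels = 50,
                                    duration = 5, seed = 1)
  expect_true(all(g0$occupancy[, "C"] == 50))
  expect_error(simulate_gillespie_ensemble(sch, 0, n_channels = 100,
                                           duration = 1),
               "seed")
})

test_that("discrete-time channel engine reproduces the oracle", {
  sch <- scheme_biliganded()
  n <- 10000
  ch <- simulate_channels_uniform(sch, conc_pulse(1, 0.3), n_channels = n,
                                  duration = 40, dt = 0.002,
                                  sample_dt = 0.1, seed = 5)
  m <- solve_master_equation(sch, conc_pulse(1, 0.3), duration = 40,
                             dt = 0.1)
  dev <- abs(ch$open / n - m$open)
  sem <- sqrt(pmax(m$open * (1 - m$open), 1e-9) / n)
  expect_true(all(dev <= pmax(3 * sem, 2 / n)))
})

test_that("detailed balance check flags irreversible cycles only", {
  # a tree has no cycles, nothing to flag
  expect_equal(nrow(detailed_balance_check(scheme_biliganded())), 0L)
  # balanced 3-cycle: product of rates equal both ways
  # Kolmogorov: 2*3*1 (A-B-O-A) == 3*2*1 (A-O-B-A)
  cyc <- kinetic_scheme(
    data.frame(label = c("A", "B", "O"), open = c(FALSE, FALSE, TRUE),
               n_bound = 0L),
    data.frame(from = c("A", "B", "B", "O", "O", "A"),
               to   = c("B", "A", "O", "B", "A", "O"),
               rate = c(2, 1, 3, 2, 1, 3), order = 0L))
  chk <- detailed_balance_check(cyc)
  expect_equal(nrow(chk), 1L)
  expect_true(chk$reversible)
  cyc2 <- kinetic_scheme(
    data.frame(label = c("A", "B", "O"), open = c(FALSE, FALSE, TRUE),
               n_bound = 0L),
    data.frame(from = c("A", "B", "B", "O", "O", "A"),
               to   = c("B", "A", "O", "B", "A", "O"),
               rate = c(1, 2, 3, 4, 5, 1), order = 0L))
  expect_false(detailed_balance_check(cyc2)$reversible)
})

test_that("scheme files round-trip losslessly", {
  f <- withr::local_tempfile(fileext = ".scheme")
  for (sch in list(scheme_biliganded(), scheme_petrini(),
                   two_state_scheme(beta = 0.123456789, alpha = 8))) {
    write_scheme(sch, f)
    back <- read_scheme(f)
    expect_equal(back$states, sch$states)
    expect_equal(back$transitions, sch$transitions)
    expect_equal(back$name, sch$name)
  }
})

test_that("template schemes deactivate with a 10-20 ms time constant", {
  for (sch in list(scheme_biliganded(), scheme_petrini())) {
    tr <- solve_master_equation(sch, conc_pulse(1, 0.3), duration = 80,
                                dt = 0.05)
    ipk <- which.max(tr$open)
    fit <- fit_decay(tr$open[ipk:length(tr$open)], dt = 0.05)
    expect_gt(fit$tau, 10)
    expect_lt(fit$tau, 20)
  }
})
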