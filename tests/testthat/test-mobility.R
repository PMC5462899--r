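test_that("mask classification follows the residency thresholds", {
  m <- gen_mask(centers = rbind(c(5, 5)), radius = 0.5,
                image_size = c(10, 10), pixel_size = 0.05, seed = 1)$mask
  inside <- data.frame(track_id = 1, frame = 1:25, t = (0:24) / 40,
                       x = 5 + runif(25, -0.2, 0.2),
                       y = 5 + runif(25, -0.2, 0.2))
  outside <- data.frame(track_id = 2, frame = 1:25, t = (0:24) / 40,
                        x = 8 + runif(25, -0.2, 0.2),
                        y = 8 + runif(25, -0.2, 0.2))
  half <- data.frame(track_id = 3, frame = 1:24, t = (0:23) / 40,
                     x = c(rep(5, 12), rep(8, 12)),
                     y = c(rep(5, 12), rep(8, 12)))
  ts <- trajectory_set(rbind(inside, outside, half), fps = 40)
  cl <- classify_by_mask(ts, m, dilate_um = 0)
  expect_equal(as.character(cl$label), c("synaptic", "extrasynaptic",
                                         "exchanging"))
  expect_equal(cl$exchange_fraction, 1 / 3)

  empty <- synaptic_mask(matrix(FALSE, 10, 10), 0.1)
  expect_warning(cle <- classify_by_mask(ts, empty), "empty mask")
  expect_true(all(cle$label == "extrasynaptic"))
})

test_that("mask-seeded slow tracks classify as synaptic", {
  mk <- gen_mask(lambda = 0.03, radius = 0.4, image_size = c(20, 20),
                 pixel_size = 0.1, seed = 41)$mask
  two <- gen_two_population_tracks(frac_slow = 0.5, mask = mk,
                                   n_tracks = 200, n_points = 40,
                                   sigma_loc = 0.02, seed = 42,
                                   length_dist = "fixed")
  cl <- classify_by_mask(two$tracks, mk)
  pop <- two$truth$params$population
  syn_rate <- mean(cl$label[pop == "slow"] == "synaptic")
  expect_gte(syn_rate, 0.95)
})

test_that("two-population mixtures give a bimodal log-D histogram", {
  two <- gen_two_population_tracks(frac_slow = 0.5, D_slow = 0.004,
                                   D_fast = 0.1, n_tracks = 400,
                                   n_points = 50, sigma_loc = 0.02,
                                   seed = 43, length_dist = "fixed")
  inst <- instantaneous_D(two$tracks)
  expect_true(inst$bimodal)
  expect_lt(abs(inst$frac_slow - 0.5), 0.10)
  # negative control: one population is unimodal
  one <- gen_free_tracks(D = 0.1, n_tracks = 300, n_points = 50,
                         sigma_loc = 0.02, seed = 44,
                         length_dist = "fixed")
  expect_false(instantaneous_D(one$tracks)$bimodal)
})

test_that("sampling rate does not change the recovered mean D", {
  d20 <- gen_free_tracks(D = 0.06, n_tracks = 300, n_points = 50,
                         fps = 20, sigma_loc = 0.05, seed = 45,
                         length_dist = "fixed")
  d40 <- gen_free_tracks(D = 0.06, n_tracks = 300, n_points = 50,
                         fps = 40, sigma_loc = 0.05, seed = 46,
                         length_dist = "fixed")
  D20 <- fit_msd_linear(mean_msd(d20$tracks, max_lag = 8))$D
  D40 <- fit_msd_linear(mean_msd(d40$tracks, max_lag = 8))$D
  expect_lt(abs(D20 - D40) / D40, 0.15)
})

test_that("mobility metrics separate confined from mobile populations", {
  conf <- gen_confined_tracks(D_micro = 0.03, L = 0.25, D_mac = 0,
                              n_tracks = 120, n_points = 50, fps = 40,
                              sigma_loc = 0.02, seed = 47,
                              length_dist = "fixed")$tracks
  rep_conf <- mobility_metrics(conf)
  expect_equal(rep_conf$mobile_fraction, 0, tolerance = 0.05)
  expect_lt(abs(rep_conf$confinement_L - 0.25) / 0.25, 0.3)

  mix <- gen_two_population_tracks(frac_slow = 0.7, D_slow = 0.01,
                                   D_fast = 0.1, L = 0.25,
                                   n_tracks = 300, n_points = 50,
                                   sigma_loc = 0.02, seed = 48,
                                   length_dist = "fixed")
  rep_mix <- mobility_metrics(mix$tracks)
  expect_lt(abs(rep_mix$mobile_fraction - 0.3), 0.05)
})

test_that("excluding exchangers lowers the synaptic diffusion estimate", {
  mk <- gen_mask(lambda = 0.03, radius = 0.4, image_size = c(20, 20),
                 pixel_size = 0.1, seed = 49)$mask
  two <- gen_two_population_tracks(frac_slow = 0.6, D_slow = 0.005,
                                   D_fast = 0.12, mask = mk,
                                   n_tracks = 300, n_points = 40,
                                   sigma_loc = 0.02, seed = 50,
                                   length_dist = "fixed")
  cl <- classify_by_mask(two$tracks, mk)
  rep <- mobility_metrics(two$tracks, classification = cl)
  expect_lte(rep$D_synaptic_resident, rep$D_synaptic + 1e-9)
})

test_that("cluster detection finds puncta and their spacing", {
  set.seed(51)
  pts <- rbind(cbind(rnorm(60, 3, 0.05), rnorm(60, 3, 0.05)),
               cbind(rnorm(60, 7, 0.05), rnorm(60, 3, 0.05)))
  cl <- detect_clusters_and_distances(pts, eps = 0.2, min_pts = 10)
  expect_equal(nrow(cl$centroids), 2L)
  expect_equal(cl$mean_nn, 4, tolerance = 0.05)
  # sparse uniform points below the density threshold: no clusters
  sparse <- cbind(runif(60, 0, 20), runif(60, 0, 20))
  cl0 <- detect_clusters_and_distances(sparse, eps = 0.1, min_pts = 10)
  expect_equal(nrow(cl0$centroids), 0L)
})

test_that("Poisson punctum fields match the 2D nearest-neighbour law", {
  lam <- 0.05   # puncta per um^2
  mk <- gen_mask(lambda = lam, radius = 0.25, image_size = c(60, 60),
                 pixel_size = 0.1, seed = 52)
  centers <- mk$truth$params$centers
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    cbind(rnorm(20, centers[i, 1], 0.05), rnorm(20, centers[i, 2],
                                                0.05))))
  cl <- detect_clusters_and_distances(pts, eps = 0.3, min_pts = 8)
  # mean NN distance of a 2D Poisson process is 1 / (2 sqrt(lambda));
  # interior centroids only, to avoid window-edge truncation bias
  interior <- cl$centroids[, 1] > 5 & cl$centroids[, 1] < 55 &
    cl$centroids[, 2] > 5 & cl$centroids[, 2] < 55
  expect_gt(sum(interior), 50)
  nn_int <- cl$nn_dist[interior]
  # normalize by the realized punctum density (merging and the Poisson
  # draw shift the nominal intensity)
  lam_hat <- nrow(cl$centroids) / 3600
  theory <- 1 / (2 * sqrt(lam_hat))
  expect_lt(abs(mean(nn_int) - theory) / theory, 0.10)
})
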