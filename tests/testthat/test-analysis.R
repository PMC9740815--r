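# a tiny host + two diatomics trajectory assembled by hand
.mini_traj <- function(frames, box = c(40, 40, 40),
                       periodic = c(FALSE, FALSE, FALSE)) {
  n <- nrow(frames[[1]])
  species <- c(rep("A", n - 4), "Od", "Hd", "Od", "Hd")
  group <- rep("HAP", n)
  ion <- c(rep(NA_integer_, n - 4), 1L, 1L, 2L, 2L)
  md_trajectory(frames, seq_along(frames) - 1, species,
                rep(1, n), box, periodic, group, ion)
}

test_that("ion-host minimum distance takes the closer of O and H", {
  # host atom at origin; ion O at 3 A, ion H at 3.97 A
  pos <- rbind(c(0, 0, 0), c(5, 5, 5),
               c(3, 0, 0), c(3.97, 0, 0), c(0, 8, 0), c(0, 8.97, 0))
  tr <- .mini_traj(list(pos))
  expect_equal(min_distance_to_host(tr, 1, 1), 3)
  expect_error(min_ion_host_distance(pos, diag(c(40, 40, 40)),
                                     c(FALSE, FALSE, FALSE), c(3, 4),
                                     integer()), "empty host")
  expect_error(min_ion_host_distance(pos, diag(c(40, 40, 40)),
                                     c(FALSE, FALSE, FALSE), c(3, 4),
                                     c(1, 3)), "disjoint")
})

test_that("minimum image is honoured: an ion near the box edge sees the periodic image", {
  # host at x = 1; ion at x = 9 in a 10 A periodic box -> distance 2
  pos <- rbind(c(1, 5, 5), c(5, 1, 1),
               c(9, 5, 5), c(8.2, 5, 5), c(5, 8, 5), c(5, 8.8, 5))
  tr <- .mini_traj(list(pos), box = c(10, 10, 10),
                   periodic = c(TRUE, TRUE, TRUE))
  d <- min_distance_to_host(tr, 1, 1)
  want <- oracle_min_dist(pos, c(3, 4), c(1, 2, 5, 6), diag(c(10, 10, 10)),
                          c(TRUE, TRUE, TRUE))
  expect_equal(d, 2)
  expect_equal(d, want)
})

test_that("per-frame distances equal the exhaustive pair scan on a toy crystal", {
  toy <- make_toy_crystal(8, 2, seed = 5)
  ev <- list(scripted_event(1, frame = 3, target_dist = 7))
  tr <- make_scripted_trajectory(toy, ev, n_frames = 5, seed = 2)
  for (f in c(1, 3, 5)) for (ion in 1:2) {
    ion_atoms <- which(!is.na(tr$ion_id) & tr$ion_id == ion)
    host <- setdiff(which(tr$group == "HAP"), ion_atoms)
    expect_equal(min_distance_to_host(tr, f, ion),
                 oracle_min_dist(tr$frames[[f]], ion_atoms, host, tr$box,
                                 tr$periodic))
  }
})

test_that("the ledger flips permanently and counts ions that have EVER detached", {
  led <- new_ledger(3, threshold = 5)
  led <- update_ledger(led, c(1, 2, 1))     # all bound
  led <- update_ledger(led, c(1, 6, 1))     # ion 2 out
  led <- update_ledger(led, c(1, 2, 1))     # ion 2 returns: stays counted
  led <- update_ledger(led, c(7, 2, 1))     # ion 1 out
  expect_equal(led$counts, c(0, 1, 1, 2))
  expect_equal(led$V, c(1L, 1L, 0L))
  expect_error(update_ledger(led, c(1, 2)), "dimension")
})

test_that("scripted crossings appear in the detachment series at the scripted frames", {
  toy <- make_toy_crystal(8, 2, seed = 5)
  # ion 1 leaves at frame 40 and returns at 60; ion 2 leaves at 20 for good
  ev <- list(scripted_event(1, frame = 40, return_frame = 60),
             scripted_event(2, frame = 20))
  tr <- make_scripted_trajectory(toy, ev, n_frames = 80, seed = 3)
  led <- detachment_series(tr, threshold = 5)
  expect_equal(led$counts[19], 0)
  expect_equal(led$counts[20], 1)
  expect_equal(led$counts[39], 1)
  expect_equal(led$counts[40], 2)
  # "ever detached": the return at frame 60 does not decrease the count
  expect_true(all(led$counts[60:80] == 2))
  expect_true(all(diff(led$counts) >= 0))
})

test_that("the series equals a brute-force historical-OR recomputation", {
  toy <- make_toy_crystal(8, 2, seed = 5)
  ev <- list(scripted_event(1, frame = 10, return_frame = 18),
             scripted_event(2, frame = 24))
  tr <- make_scripted_trajectory(toy, ev, n_frames = 30, seed = 4)
  led <- detachment_series(tr, threshold = 5)
  # oracle: recompute distances per frame, apply OR over history
  ions <- 1:2
  seen <- c(FALSE, FALSE)
  want <- integer(0)
  for (f in seq_len(n_frames(tr))) {
    for (k in ions) {
      ion_atoms <- which(!is.na(tr$ion_id) & tr$ion_id == k)
      host <- setdiff(which(tr$group == "HAP"), ion_atoms)
      d <- oracle_min_dist(tr$frames[[f]], ion_atoms, host, tr$box,
                           tr$periodic)
      if (d > 5) seen[k] <- TRUE
    }
    want <- c(want, sum(seen))
  }
  expect_equal(led$counts, want)
})

test_that("ledger counts are monotone for arbitrary random trajectories", {
  toy <- make_toy_crystal(8, 2, seed = 5)
  n <- n_atoms(toy)
  for (seed in 1:10) {
    set.seed(seed)
    frames <- lapply(1:15, function(f)
      toy$positions + matrix(rnorm(n * 3, 0, runif(1, 0.1, 4)), n, 3))
    tr <- md_trajectory(frames, 0:14, toy$species, toy$masses, toy$box,
                        toy$periodic, toy$group, toy$ion_id)
    led <- detachment_series(tr, threshold = 5)
    expect_true(all(diff(led$counts) >= 0))
  }
})

test_that("detachment is invariant to rigid translation and degenerate thresholds", {
  toy <- make_toy_crystal(8, 2, seed = 5)
  ev <- list(scripted_event(1, frame = 5, target_dist = 8))
  tr <- make_scripted_trajectory(toy, ev, n_frames = 10, seed = 6)
  led <- detachment_series(tr, threshold = 5)
  shifted <- tr
  shifted$frames <- lapply(tr$frames, function(p) sweep(p, 2, c(3, -2, 5), "+"))
  expect_equal(detachment_series(shifted, threshold = 5)$counts, led$counts)
  expect_true(all(detachment_series(tr, threshold = Inf)$counts == 0))
  # static trajectory: constant series
  static <- md_trajectory(rep(list(toy$positions), 6), 0:5, toy$species,
                          toy$masses, toy$box, toy$periodic, toy$group,
                          toy$ion_id)
  expect_equal(length(unique(detachment_series(static)$counts)), 1)
})

test_that("radius of gyration matches closed forms and the direct formula", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1, 3), 12), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, c(7, 7)), 1)
  set.seed(8)
  cloud <- matrix(rnorm(300), 100, 3)
  m <- runif(100, 1, 40)
  com <- colSums(cloud * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(cloud, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(cloud, m), direct)
  expect_error(radius_of_gyration(cloud[0, , drop = FALSE], numeric()),
               "empty")
  expect_error(radius_of_gyration(two, c(1, -1)), "positive")
})

test_that("Rg is invariant under rigid motion and scales linearly", {
  set.seed(9)
  cloud <- matrix(rnorm(90), 30, 3)
  m <- runif(30, 1, 20)
  r0 <- radius_of_gyration(cloud, m)
  expect_equal(radius_of_gyration(sweep(cloud, 2, c(5, -3, 2), "+"), m), r0)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(radius_of_gyration(cloud %*% t(R), m), r0)
  expect_equal(radius_of_gyration(3.5 * cloud, m), 3.5 * r0)
})

test_that("replicate averaging gives the pointwise mean and SEM", {
  s <- list(c(0, 1, 2), c(0, 1, 2))
  same <- average_over_runs(rep(list(c(3, 1, 4)), 16))
  expect_equal(same$mean, c(3, 1, 4))
  expect_equal(same$sem, c(0, 0, 0))
  two <- average_over_runs(list(0, 2))
  expect_equal(two$mean, 1)
  expect_equal(two$sem, 1)
  set.seed(2)
  runs <- lapply(1:7, function(i) rnorm(11))
  got <- average_over_runs(runs)
  m <- do.call(rbind, runs)
  expect_equal(got$mean, colMeans(m))
  expect_equal(got$sem, apply(m, 2, sd) / sqrt(7))
  expect_error(average_over_runs(list(1:3, 1:4)), "lengths differ")
})

test_that("onset detection finds steps and knees, and reports no onset on flat series", {
  T <- seq(800, 1200, by = 10)
  flat <- onset_temperature(T, rep(0, length(T)))
  expect_true(is.na(flat$onset))
  step <- ifelse(T >= 1000, 10, 0)
  got <- onset_temperature(T, step, window = 50, slope_threshold = 0.02)
  expect_equal(got$onset, 1000, tolerance = 0.06)
  # piecewise-linear knee at 1050 with slope 0.05 ions/K after the knee
  knee <- pmax(0, (T - 1050) * 0.05)
  got2 <- onset_temperature(T, knee, window = 50, slope_threshold = 0.02)
  expect_lte(abs(got2$onset - 1050), 50)
})

test_that("melting is flagged on sustained collapse and not on noise", {
  s <- make_melting_rg_series(200, collapse_frame = 100, drop_fraction = 0.3,
                              noise = 0.005, seed = 3)
  got <- melting_flag(s$time, s$Rg, drop_fraction = 0.15)
  expect_true(got$melted)
  expect_lt(abs(got$collapse_time - 100), 25)
  flat <- make_melting_rg_series(200, collapse_frame = Inf, drop_fraction = 0,
                                 noise = 0.01, seed = 4)
  expect_false(melting_flag(flat$time, flat$Rg, drop_fraction = 0.1)$melted)
  expect_error(melting_flag(1:5, rep(1, 5), plateau_frames = 10), "shorter")
})

test_that("rg_series tracks a trajectory and excludes water by default", {
  toy <- make_toy_crystal(8, 1, seed = 2)
  tr <- md_trajectory(list(toy$positions, toy$positions * 2), 0:1,
                      toy$species, toy$masses, toy$box, toy$periodic,
                      toy$group, toy$ion_id)
  rs <- rg_series(tr)
  expect_equal(nrow(rs), 2)
  expect_equal(rs$Rg[2], 2 * rs$Rg[1])
})
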