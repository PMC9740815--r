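test_that("Lennard-Jones closed forms hold at their characteristic points", {
  expect_equal(lj_energy(3.0, 0.5, 3.0, "lj12-6"), 0)
  expect_equal(lj_energy(2^(1 / 6) * 3.0, 0.5, 3.0, "lj12-6"), -0.5)
  expect_equal(lj_energy(3.2, 0.7, 3.2, "lj9-6"), -0.7)
  # 9-6 minimum is at r0: derivative changes sign there
  eps <- 1e-6
  expect_lt(lj_energy(3.2, 0.7, 3.2, "lj9-6"),
            lj_energy(3.2 - 1e-3, 0.7, 3.2, "lj9-6"))
  expect_lt(lj_energy(3.2, 0.7, 3.2, "lj9-6"),
            lj_energy(3.2 + 1e-3, 0.7, 3.2, "lj9-6"))
  expect_error(lj_energy(0, 0.5, 3.0), "positive")
  expect_error(lj_energy(-1, 0.5, 3.0), "positive")
})

test_that("Coulomb term has the right constant, sign, and monotonicity", {
  expect_equal(coulomb_energy(1, -1, 1), -332.0637)
  expect_equal(coulomb_energy(0, 5, 2.3), 0)
  r <- seq(1, 10, by = 0.5)
  e <- coulomb_energy(1, 1, r)
  expect_true(all(e > 0))
  expect_true(all(diff(e) < 0))
  expect_error(coulomb_energy(1, 1, 0), "positive")
})

test_that("total_energy on trivial systems matches closed forms", {
  one <- atom_system(matrix(c(5, 5, 5), 1, 3), "A", c(20, 20, 20),
                     masses = 23, charges = 0.4,
                     periodic = c(FALSE, FALSE, FALSE))
  e <- total_energy(one, cluster_ff())
  expect_equal(e$total, 0)
  expect_equal(e$coulomb + e$lj + e$bond + e$angle, 0)

  ta <- two_atom_lj(2^(1 / 6) * 3.0, eps = 0.3, sigma = 3.0)
  expect_equal(total_energy(ta$sys, ta$ff)$total, -0.3, tolerance = 1e-12)
})

test_that("total_energy equals the brute-force double-loop oracle", {
  for (seed in 1:4) {
    sys <- random_cluster(12, seed)
    ff <- cluster_ff()
    got <- total_energy(sys, ff)
    want <- oracle_energy(sys, ff)
    expect_equal(got$total, want$total, tolerance = 1e-10)
    expect_equal(got$coulomb, want$coulomb, tolerance = 1e-10)
    expect_equal(got$lj, want$lj, tolerance = 1e-10)
  }
})

test_that("cutoff, energy shift and periodic minimum image match the oracle", {
  set.seed(11)
  pos <- matrix(runif(30, 0, 12), 10, 3)
  # keep atoms apart to avoid pathological overlaps
  pos <- pos[order(pos[, 1]), ] + outer(seq_len(10), c(0.9, 0, 0))
  sys <- atom_system(pos, rep(c("A", "B"), 5), c(18, 18, 18),
                     masses = rep(c(23, 19), 5),
                     charges = rep(c(0.4, -0.4), 5),
                     periodic = c(TRUE, TRUE, TRUE))
  ff <- cluster_ff(cutoff = 6, shift = TRUE)
  got <- total_energy(sys, ff)
  want <- oracle_energy(sys, ff)
  expect_equal(got$total, want$total, tolerance = 1e-10)
})

test_that("bonded systems (bonds + angles + exclusions) match the oracle", {
  # a bent triatomic plus two counter-ions
  pos <- rbind(c(10, 10, 10), c(10.96, 10, 10), c(9.76, 10.93, 10),
               c(13, 12, 10), c(7, 8, 10))
  sys <- atom_system(pos, c("Ox", "Hx", "Hx", "A", "B"), c(30, 30, 30),
                     masses = c(16, 1, 1, 23, 19),
                     charges = c(-0.8, 0.4, 0.4, 0.4, -0.4),
                     bonds = rbind(c(1, 2), c(1, 3)),
                     periodic = c(FALSE, FALSE, FALSE))
  ff <- force_field(species = list(
    Ox = list(charge = -0.8, mass = 16, epsilon = 0.15, sigma = 3.15),
    Hx = list(charge = 0.4, mass = 1, epsilon = 0, sigma = 0.8),
    A = list(charge = 0.4, mass = 23, epsilon = 0.12, sigma = 2.6),
    B = list(charge = -0.4, mass = 19, epsilon = 0.10, sigma = 2.9)),
    bonds = list(`Hx-Ox` = list(k = 500, r0 = 0.96)),
    angles = list(`Hx-Ox-Hx` = list(k = 90, theta0 = 104.5)),
    cutoff = Inf, shift = FALSE)
  got <- total_energy(sys, ff)
  want <- oracle_energy(sys, ff)
  expect_equal(got$total, want$total, tolerance = 1e-10)
  expect_equal(got$bond, want$bond, tolerance = 1e-10)
  expect_equal(got$angle, want$angle, tolerance = 1e-10)
  expect_equal(got$total, got$coulomb + got$lj + got$bond + got$angle)
})

test_that("missing parameters raise errors naming the species", {
  one <- atom_system(matrix(1:6 + 10, 2, 3), c("A", "Zz"), c(40, 40, 40),
                     masses = c(23, 5), periodic = c(FALSE, FALSE, FALSE))
  expect_error(total_energy(one, cluster_ff()), "Zz")
})

test_that("forces are the analytic gradient of the energy (finite differences)", {
  # covers Coulomb, both LJ forms, bonds, angles, periodic minimum image
  pos <- rbind(c(10, 10, 10), c(10.96, 10, 10), c(9.76, 10.93, 10),
               c(12.5, 11.5, 10.5), c(7.5, 8.5, 9.5))
  sys <- atom_system(pos, c("Ox", "Hx", "Hx", "A", "B"), c(16, 16, 16),
                     masses = c(16, 1, 1, 23, 19),
                     charges = c(-0.8, 0.4, 0.4, 0.4, -0.4),
                     bonds = rbind(c(1, 2), c(1, 3)),
                     periodic = c(TRUE, TRUE, TRUE))
  ff <- force_field(species = list(
    Ox = list(charge = -0.8, mass = 16, epsilon = 0.15, sigma = 3.15),
    Hx = list(charge = 0.4, mass = 1, epsilon = 0, sigma = 0.8),
    A = list(charge = 0.4, mass = 23, epsilon = 0.12, sigma = 2.6,
             form = "lj9-6"),
    B = list(charge = -0.4, mass = 19, epsilon = 0.10, sigma = 2.9,
             form = "lj9-6")),
    bonds = list(`Hx-Ox` = list(k = 500, r0 = 0.96)),
    angles = list(`Hx-Ox-Hx` = list(k = 90, theta0 = 104.5)),
    cutoff = 7, shift = TRUE)
  f <- forces(sys, ff)
  h <- 1e-6
  for (i in seq_len(nrow(pos))) for (k in 1:3) {
    sp <- sys; sp$positions[i, k] <- sp$positions[i, k] + h
    sm <- sys; sm$positions[i, k] <- sm$positions[i, k] - h
    fd <- -(total_energy(sp, ff)$total - total_energy(sm, ff)$total) / (2 * h)
    expect_equal(f[i, k], fd, tolerance = 1e-6)
  }
})

test_that("Newton's third law and zero net force hold", {
  ta <- two_atom_lj(3.4)
  f <- forces(ta$sys, ta$ff)
  expect_equal(f[1, ], -f[2, ])
  sys <- random_cluster(14, 5)
  fs <- forces(sys, cluster_ff())
  expect_equal(colSums(fs), c(0, 0, 0), tolerance = 1e-9)
})

test_that("energy is invariant under rigid translation and (cubic box) rotation", {
  sys <- random_cluster(10, 9)
  ff <- cluster_ff()
  e0 <- total_energy(sys, ff)$total
  tr <- sys; tr$positions <- sweep(sys$positions, 2, c(1.3, -2.1, 0.7), "+")
  expect_equal(total_energy(tr, ff)$total, e0, tolerance = 1e-10)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sys
  ctr <- colMeans(sys$positions)
  rot$positions <- sweep(sweep(sys$positions, 2, ctr) %*% t(R), 2, ctr, "+")
  expect_equal(total_energy(rot, ff)$total, e0, tolerance = 1e-10)
})

test_that("pair terms are symmetric in the two atoms", {
  ta <- two_atom_lj(3.1)
  e0 <- total_energy(ta$sys, ta$ff)$total
  sw <- ta$sys
  sw$positions <- sw$positions[2:1, ]
  sw$species <- sw$species[2:1]
  expect_equal(total_energy(sw, ta$ff)$total, e0)
})

test_that("the shipped HAP force field loads and evaluates on the dry crystal", {
  ff <- default_force_field()
  expect_s3_class(ff, "force_field")
  expect_equal(ff$cutoff, 10)
  cell <- build_unit_cell(ff = ff)
  ff_small <- ff; ff_small$cutoff <- 3.4
  e <- total_energy(cell, ff_small)
  expect_true(is.finite(e$total))
  expect_lt(e$total, 0)   # bound crystal
})
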