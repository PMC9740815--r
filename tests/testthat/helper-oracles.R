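# Independent brute-force oracles, implemented without touching the
# package's evaluation path: explicit double loops, explicit 27-image
# minimum distances, explicit pair-parameter resolution.

K_COUL <- 332.0637
KB_EV <- 8.6173e-5
KB_KCAL <- KB_EV / 0.0433641
KB_MDU <- KB_KCAL * 418.4

# all periodic image shifts (-1, 0, 1 per periodic dimension)
.image_shifts <- function(box, periodic) {
  r <- lapply(1:3, function(k) if (periodic[k]) -1:1 else 0)
  g <- expand.grid(r[[1]], r[[2]], r[[3]])
  t(apply(g, 1, function(s) s[1] * box[1, ] + s[2] * box[2, ] + s[3] * box[3, ]))
}

# minimum distance between atoms i and j over explicit images
oracle_pair_dist <- function(pos, i, j, box, periodic) {
  shifts <- .image_shifts(box, periodic)
  d <- pos[i, ] - pos[j, ]
  min(sqrt(rowSums(sweep(shifts, 2, d, "+")^2)))
}

# brute-force minimum ion-host distance over 27 images
oracle_min_dist <- function(pos, ion_atoms, host, box, periodic) {
  best <- Inf
  for (i in ion_atoms) for (j in host)
    best <- min(best, oracle_pair_dist(pos, i, j, box, periodic))
  best
}

# resolve pair (eps, sigma, form) the way the model defines it:
# Lorentz-Berthelot from self entries, explicit pairs override
oracle_pair_params <- function(ff, sa, sb) {
  ea <- ff$species[[sa]]; eb <- ff$species[[sb]]
  g <- function(e, f, d) if (is.null(e[[f]])) d else e[[f]]
  out <- list(eps = sqrt(g(ea, "epsilon", 0) * g(eb, "epsilon", 0)),
              sig = (g(ea, "sigma", 1) + g(eb, "sigma", 1)) / 2,
              form = if (g(ea, "form", "lj12-6") == "lj9-6" &&
                         g(eb, "form", "lj12-6") == "lj9-6") "lj9-6" else "lj12-6")
  for (p in ff$pairs) {
    if ((p$a == sa && p$b == sb) || (p$a == sb && p$b == sa)) {
      out$eps <- p$epsilon; out$sig <- p$sigma
      out$form <- if (is.null(p$form)) "lj12-6" else p$form
    }
  }
  out
}

.oracle_lj <- function(r, eps, sig, form) {
  if (eps <= 0) return(0)
  if (form == "lj12-6") 4 * eps * ((sig / r)^12 - (sig / r)^6)
  else eps * (2 * (sig / r)^9 - 3 * (sig / r)^6)
}

# total energy by brute-force double loop (no neighbour lists, explicit
# images, explicit exclusions from the bond graph)
oracle_energy <- function(system, ff) {
  pos <- system$positions; n <- nrow(pos)
  sp <- system$species; q <- system$charges
  bonds <- system$bonds
  adj <- lapply(seq_len(n), function(i) integer())
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excluded <- function(i, j) {
    if (j %in% adj[[i]]) return(TRUE)                 # 1-2
    any(vapply(adj[[i]], function(k) j %in% adj[[k]], logical(1)))  # 1-3
  }
  cutoff <- ff$cutoff
  shift <- isTRUE(ff$shift) && is.finite(cutoff)
  e_c <- 0; e_l <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (excluded(i, j)) next
    r <- oracle_pair_dist(pos, i, j, system$box, system$periodic)
    if (is.finite(cutoff) && r > cutoff) next
    pp <- oracle_pair_params(ff, sp[i], sp[j])
    ec <- K_COUL * q[i] * q[j] / r
    el <- .oracle_lj(r, pp$eps, pp$sig, pp$form)
    if (shift) {
      ec <- ec - K_COUL * q[i] * q[j] / cutoff
      el <- el - .oracle_lj(cutoff, pp$eps, pp$sig, pp$form)
    }
    e_c <- e_c + ec; e_l <- e_l + el
  }
  e_b <- 0
  for (r in seq_len(nrow(bonds))) {
    key <- paste(sort(c(sp[bonds[r, 1]], sp[bonds[r, 2]])), collapse = "-")
    bp <- ff$bonds[[key]]
    d <- oracle_pair_dist(pos, bonds[r, 1], bonds[r, 2], system$box,
                          system$periodic)
    e_b <- e_b + bp$k * (d - bp$r0)^2
  }
  e_a <- 0
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    for (ci in utils::combn(nb, 2, simplify = FALSE)) {
      a <- ci[1]; b <- ci[2]
      sc <- sort(c(sp[a], sp[b]))
      key <- paste(c(sc[1], sp[j], sc[2]), collapse = "-")
      ap <- ff$angles[[key]]
      if (is.null(ap)) next
      v1 <- pos[a, ] - pos[j, ]; v2 <- pos[b, ] - pos[j, ]
      th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
      e_a <- e_a + ap$k * (th - ap$theta0 * pi / 180)^2
    }
  }
  list(coulomb = e_c, lj = e_l, bond = e_b, angle = e_a,
       total = e_c + e_l + e_b + e_a)
}

# a small random charged cluster in an open box, neutral overall
random_cluster <- function(n, seed, box_len = 40) {
  set.seed(seed)
  repeat {
    pos <- matrix(runif(n * 3, 12, box_len - 12), n, 3)
    dmin <- min(stats::dist(pos))
    if (dmin > 1.6) break
  }
  q <- rep(c(0.4, -0.4), length.out = n)
  q <- q - mean(q)
  atom_system(pos, rep(c("A", "B"), length.out = n), rep(box_len, 3),
              masses = rep(c(23, 19), length.out = n), charges = q,
              periodic = c(FALSE, FALSE, FALSE))
}

cluster_ff <- function(cutoff = Inf, shift = FALSE) {
  force_field(species = list(
    A = list(charge = 0.4, mass = 23, epsilon = 0.12, sigma = 2.6),
    B = list(charge = -0.4, mass = 19, epsilon = 0.10, sigma = 2.9)),
    cutoff = cutoff, shift = shift)
}

# two neutral atoms at separation r with pure LJ interaction
two_atom_lj <- function(r, eps = 0.3, sigma = 3.0, form = "lj12-6") {
  sys <- atom_system(rbind(c(10, 10, 10), c(10 + r, 10, 10)),
                     c("X1", "X2"), c(40, 40, 40),
                     masses = c(20, 20), periodic = c(FALSE, FALSE, FALSE))
  ff <- force_field(species = list(
    X1 = list(charge = 0, mass = 20, epsilon = eps, sigma = sigma,
              form = form),
    X2 = list(charge = 0, mass = 20, epsilon = eps, sigma = sigma,
              form = form)),
    cutoff = Inf, shift = FALSE)
  list(sys = sys, ff = ff)
}
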