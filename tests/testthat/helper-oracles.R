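# Independent brute-force oracles, written from the definitions and kept
# free of the package's vectorised code paths.

KE <- 138.935458

# Single-pair nonbonded force from first principles.  The LJ switch
# coefficients are obtained by numerically solving the two boundary
# conditions (force and its derivative vanish at r_cut) rather than from a
# closed form, so this path is independent of the implementation.
oracle_pair_force <- function(pa, pb, qa, qb, sig, eps, box,
                              r1 = 1.0, rc = 1.2) {
  d <- pa - pb
  d <- d - box * round(d / box)
  r <- sqrt(sum(d * d))
  if (r > rc) return(c(0, 0, 0))
  term <- function(alpha, p) {
    if (r <= r1) return(alpha / r^(p + 1))
    m <- rbind(c((rc - r1)^2, (rc - r1)^3),
               c(2 * (rc - r1), 3 * (rc - r1)^2))
    ab <- solve(m, c(-alpha / rc^(p + 1), (p + 1) * alpha / rc^(p + 2)))
    alpha / r^(p + 1) + ab[1] * (r - r1)^2 + ab[2] * (r - r1)^3
  }
  c6 <- 4 * eps * sig^6
  c12 <- 4 * eps * sig^12
  fmag <- KE * qa * qb / r^2 + term(12 * c12, 12) - term(6 * c6, 6)
  fmag / r * d
}

# Quadruple loop: residues x lipids x residue atoms x lipid atoms.
oracle_punctual_stress <- function(sys, coords = NULL) {
  if (is.null(coords)) coords <- sys$positions
  res <- sort(unique(sys$residue[sys$group == "protein"]))
  lips <- sort(unique(sys$molecule[sys$group == "lipid"]))
  ps <- numeric(length(res))
  for (i in seq_along(res)) {
    ia <- which(sys$group == "protein" & sys$residue == res[i])
    for (j in lips) {
      ib <- which(sys$group == "lipid" & sys$molecule == j)
      f <- c(0, 0, 0)
      for (a in ia) for (b in ib) {
        f <- f + oracle_pair_force(coords[a, ], coords[b, ],
                                   sys$charge[a], sys$charge[b],
                                   (sys$sigma[a] + sys$sigma[b]) / 2,
                                   sqrt(sys$epsilon[a] * sys$epsilon[b]),
                                   sys$box)
      }
      ps[i] <- ps[i] + sqrt(sum(f * f))
    }
  }
  ps
}

# Fraction of (positive, negative) pairs won, ties half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  wins <- 0
  for (a in sp) for (b in sn) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(sp) * length(sn))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Scaled-down ensemble spec for fast unit tests.
small_spec <- function(seed = 1, ...) {
  args <- list(n_replicas_transition = 3, n_replicas_control = 2,
               n_frames = 60, n_features = 30, n_hotspots = 5,
               noise_sigma = 1.0, transition_window = c(20, 40), seed = seed)
  args <- utils::modifyList(args, list(...))
  if (args$transition_window[2] > args$n_frames) {
    args$transition_window <- c(ceiling(args$n_frames / 3),
                                ceiling(2 * args$n_frames / 3))
  }
  do.call(synthetic_ensemble_spec, args)
}

# Independent random rotation for invariance tests.
random_rotation_test <- function() {
  a <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  rx %*% ry %*% rz
}
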