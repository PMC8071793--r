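box <- c(6, 6, 6)

test_that("pair force reproduces closed-form Coulomb and LJ landmarks", {
  # equal unit charges, no LJ, 1 nm apart: bare Coulomb, repulsive
  f <- pair_atom_force(c(0, 0, 0), c(1, 0, 0), 1, 1, 0.3, 0, box)
  expect_equal(sqrt(sum(f^2)), 138.935458, tolerance = 1e-12)
  expect_lt(f[1], 0)  # pushes atom a away from b (towards -x)

  # beyond the 1.2 nm cutoff everything vanishes identically
  expect_identical(pair_atom_force(c(0, 0, 0), c(1.3, 0, 0), 1, -1,
                                   0.35, 5, box), c(0, 0, 0))

  # LJ force vanishes at the potential minimum (inside the switch region)
  rmin <- 2^(1 / 6) * 0.3
  f <- pair_atom_force(c(0, 0, 0), c(rmin, 0, 0), 0, 0, 0.3, 0.5, box)
  expect_equal(f, c(0, 0, 0), tolerance = 1e-12)

  expect_error(pair_atom_force(c(1, 1, 1), c(1, 1, 1), 1, 1, 0.3, 0.5, box),
               "singular")
})

test_that("pair force is antisymmetric and obeys the minimum image", {
  set.seed(42)
  for (i in 1:25) {
    pa <- runif(3, 0, 6); pb <- pa + runif(3, -1.3, 1.3)
    qa <- runif(1, -0.5, 0.5); qb <- runif(1, -0.5, 0.5)
    sg <- runif(1, 0.25, 0.35); ep <- runif(1, 0.2, 0.8)
    fab <- pair_atom_force(pa, pb, qa, qb, sg, ep, box)
    fba <- pair_atom_force(pb, pa, qb, qa, sg, ep, box)
    expect_equal(fab, -fba, tolerance = 1e-12)
  }
  # atoms touching across the periodic boundary interact
  f <- pair_atom_force(c(0.1, 3, 3), c(5.9, 3, 3), 1, 1, 0.3, 0, box)
  expect_equal(sqrt(sum(f^2)), 138.935458 / 0.2^2, tolerance = 1e-10)
  expect_gt(f[1], 0)  # image of b sits at -0.1, so a is pushed towards +x
})

test_that("LJ force switch turns the force off smoothly at the cutoff", {
  lj <- function(r) pair_atom_force(c(0, 0, 0), c(r, 0, 0), 0, 0,
                                    0.34, 0.6, box)[1]
  # continuous at the start of the switch region
  expect_equal(lj(1.0 - 1e-9), lj(1.0 + 1e-9), tolerance = 1e-6)
  # |F| -> 0 approaching r_cut from below, zero beyond
  scan <- abs(vapply(1.2 - 10^-(2:6), lj, numeric(1)))
  expect_true(all(diff(scan) < 0))
  expect_lt(scan[5], 1e-9)
  expect_identical(lj(1.2 + 1e-9), 0)
})

test_that("residue-lipid force matches single pairs and the brute force", {
  s <- generate_toy_system(3, 4, 1, seed = 5)
  pr <- residue_lipid_force(s, residue_index = 1, lipid_index = 1)
  ia <- which(s$group == "protein" & s$residue == 1)
  ib <- which(s$group == "lipid" & s$molecule == 1)
  direct <- pair_atom_force(s$positions[ia, ], s$positions[ib, ],
                            s$charge[ia], s$charge[ib],
                            (s$sigma[ia] + s$sigma[ib]) / 2,
                            sqrt(s$epsilon[ia] * s$epsilon[ib]), s$box)
  expect_equal(pr$force, direct, tolerance = 1e-12)

  expect_error(residue_lipid_force(s, residue_index = 99, lipid_index = 1),
               "residue")
  expect_error(residue_lipid_force(s, residue_index = 1, lipid_index = 99),
               "lipid")

  s2 <- generate_toy_system(4, 6, 3, seed = 17)
  plan <- attr(s2, "placement")
  far <- which(plan == "far")[1]
  expect_identical(residue_lipid_force(s2, residue_index = 2,
                                       lipid_index = far)$force, c(0, 0, 0))

  for (res in 1:4) for (lip in 1:6) {
    got <- residue_lipid_force(s2, residue_index = res,
                               lipid_index = lip)$force
    ia <- which(s2$group == "protein" & s2$residue == res)
    ib <- which(s2$group == "lipid" & s2$molecule == lip)
    want <- c(0, 0, 0)
    for (a in ia) for (b in ib) {
      want <- want + oracle_pair_force(s2$positions[a, ], s2$positions[b, ],
                                       s2$charge[a], s2$charge[b],
                                       (s2$sigma[a] + s2$sigma[b]) / 2,
                                       sqrt(s2$epsilon[a] * s2$epsilon[b]),
                                       s2$box)
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("punctual stress sums force magnitudes across lipids", {
  # one single-atom residue pulled by two identical lipids on opposite
  # sides: net vector forces cancel but punctual stress adds
  pos <- rbind(c(3, 3, 3), c(3.8, 3, 3), c(2.2, 3, 3))
  sys <- toy_system(pos, charge = c(0.4, -0.2, -0.2),
                    sigma = rep(0.3, 3), epsilon = rep(0.5, 3),
                    residue = 1:3, molecule = 1:3,
                    group = c("protein", "lipid", "lipid"), box = box)
  f1 <- residue_lipid_force(sys, residue_index = 1, lipid_index = 2)$force
  ps <- punctual_stress(sys)
  expect_equal(unname(ps), 2 * sqrt(sum(f1^2)), tolerance = 1e-12)

  # no lipids: all-zero vector, not an error
  solo <- toy_system(pos, charge = rep(0.1, 3), sigma = rep(0.3, 3),
                     epsilon = rep(0.5, 3), residue = 1:3,
                     molecule = rep(1L, 3), group = rep("protein", 3),
                     box = box)
  expect_equal(unname(punctual_stress(solo)), c(0, 0, 0))
})

test_that("punctual stress equals the brute-force evaluation", {
  for (seed in 1:5) {
    s <- generate_toy_system(3 + seed %% 3, 4 + seed, 2, seed = seed)
    expect_equal(unname(punctual_stress(s)), oracle_punctual_stress(s),
                 tolerance = 1e-10)
  }
})

test_that("perturbing a beyond-cutoff lipid leaves the stress unchanged", {
  s <- generate_toy_system(4, 6, 2, seed = 23)
  plan <- attr(s, "placement")
  far <- which(plan == "far")
  ps0 <- punctual_stress(s)
  coords <- s$positions
  ib <- which(s$group == "lipid" & s$molecule %in% far)
  coords[ib, 3] <- coords[ib, 3] + 0.07   # stays beyond 1.2 nm of protein
  expect_identical(punctual_stress(s, coords), ps0)
})

test_that("stress trajectories apply the per-frame kernel", {
  s <- generate_toy_system(3, 4, 2, seed = 2)
  tr <- generate_transition_trajectory(s, 0.1, 4, seed = 9, jitter_sd = 0.01,
                                       rigid_motion = FALSE)
  ser <- stress_trajectory(s, tr$frames)
  expect_equal(dim(ser$values), c(4, 3))
  expect_equal(ser$frame_times, c(0, 40, 80, 120))
  for (t in 1:4) {
    expect_equal(unname(ser$values[t, ]),
                 oracle_punctual_stress(s, tr$frames[[t]]),
                 tolerance = 1e-10)
  }

  same <- stress_trajectory(s, rep(list(s$positions), 3), stride_ps = 20)
  expect_equal(same$values[1, ], same$values[2, ])
  expect_equal(same$values[2, ], same$values[3, ])
  expect_equal(same$frame_times, c(0, 20, 40))

  bad <- list(s$positions[-1, ])
  expect_error(stress_trajectory(s, bad), "dimensions")
})
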