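#' Toy membrane-protein system
#'
#' A minimal all-atom representation used for exercising the nonbonded force
#' kernel: atom positions, partial charges, Lennard-Jones parameters,
#' residue/molecule bookkeeping and protein/lipid group tags in an
#' orthorhombic box.  Constructed by [generate_toy_system()] or assembled
#' from a coordinate file plus a parameter table with [system_from_files()].
#'
#' @param positions N x 3 matrix (nm).
#' @param charge,sigma,epsilon per-atom nonbonded parameters (e, nm, kJ/mol).
#' @param residue per-atom residue index (protein residues and lipid
#'   molecules each carry a residue index).
#' @param molecule per-atom molecule index.
#' @param group per-atom label, `"protein"` or `"lipid"`.
#' @param chain per-residue chain label (`"A"`, `"B"` or `"none"`), indexed
#'   by residue number.
#' @param box orthorhombic box edge lengths (nm), each larger than twice the
#'   1.2 nm cutoff so the minimum image is unambiguous.
#' @return object of class `toy_system`.
#' @export
toy_system <- function(positions, charge, sigma, epsilon, residue, molecule,
                       group, chain = NULL, box) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, length(charge) == n, length(sigma) == n,
            length(epsilon) == n, length(residue) == n,
            length(molecule) == n, length(group) == n)
  if (!all(group %in% c("protein", "lipid"))) {
    stop("group tags must be 'protein' or 'lipid'", call. = FALSE)
  }
  check_box(box)
  if (any(box <= 2 * 1.2)) {
    stop("box edges must exceed twice the 1.2 nm cutoff", call. = FALSE)
  }
  structure(list(positions = positions, charge = as.numeric(charge),
                 sigma = as.numeric(sigma), epsilon = as.numeric(epsilon),
                 residue = as.integer(residue),
                 molecule = as.integer(molecule), group = group,
                 chain = chain, box = as.numeric(box)),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat("Toy system:", nrow(x$positions), "atoms,",
      length(unique(x$residue[x$group == "protein"])), "protein residues,",
      length(unique(x$molecule[x$group == "lipid"])), "lipid molecules\n")
  cat("  box:", paste(signif(x$box, 4), collapse = " x "), "nm\n")
  invisible(x)
}

#' Generate a toy membrane-protein system
#'
#' Places protein residues on a line along the membrane normal (z axis) and
#' lipid molecules at controlled distances from the protein: roughly half of
#' the lipids ("near") are guaranteed to have at least one atom within
#' 1.0 nm of a protein atom, the rest ("far") are guaranteed to keep all
#' their atoms beyond 1.2 nm of every protein atom.  Nonbonded parameters
#' are drawn uniformly: charges in [-0.5, 0.5] e, sigma in [0.25, 0.35] nm,
#' epsilon in [0.2, 0.8] kJ/mol.  The generator is a pure function of its
#' arguments including the seed.
#'
#' @param n_protein_residues,n_lipids,atoms_per_residue positive counts.
#' @param seed integer RNG seed.
#' @return a [toy_system] with attribute `placement`, the per-lipid
#'   `"near"`/`"far"` placement plan.
#' @export
generate_toy_system <- function(n_protein_residues, n_lipids,
                                atoms_per_residue, seed) {
  if (n_protein_residues < 1 || n_lipids < 1 || atoms_per_residue < 1) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (missing(seed)) stop("seed must be given", call. = FALSE)
  set.seed(seed)

  res_spacing <- 0.4
  jitter <- 0.05                       # max per-coordinate atom jitter (nm)
  zlen <- max(6, (n_protein_residues - 1) * res_spacing + 4)
  box <- c(6, 6, zlen)
  cx <- box[1] / 2
  cy <- box[2] / 2
  z0 <- zlen / 2 - (n_protein_residues - 1) * res_spacing / 2

  n_prot <- n_protein_residues * atoms_per_residue
  n_lip <- n_lipids * atoms_per_residue
  n <- n_prot + n_lip
  pos <- matrix(0, n, 3)

  # protein: residue centers on the z axis, atoms jittered about the center
  k <- 0L
  for (i in seq_len(n_protein_residues)) {
    center <- c(cx, cy, z0 + (i - 1) * res_spacing)
    for (a in seq_len(atoms_per_residue)) {
      k <- k + 1L
      pos[k, ] <- center + stats::runif(3, -jitter, jitter)
    }
  }

  # lipids: near lipids at lateral distance 0.4-0.7 nm from a residue
  # center (any atom then within 0.7 + 2*jitter*sqrt(3) < 1.0 nm of a
  # protein atom); far lipids at lateral distance 1.5-2.0 nm from the
  # protein axis (all atoms then beyond 1.5 - 2*jitter*sqrt(3) > 1.2 nm)
  n_near <- ceiling(n_lipids / 2)
  placement <- rep(c("near", "far"), c(n_near, n_lipids - n_near))
  for (j in seq_len(n_lipids)) {
    phi <- stats::runif(1, 0, 2 * pi)
    if (placement[j] == "near") {
      d <- stats::runif(1, 0.4, 0.7)
      anchor <- sample.int(n_protein_residues, 1)
      center <- c(cx + d * cos(phi), cy + d * sin(phi),
                  z0 + (anchor - 1) * res_spacing)
    } else {
      d <- stats::runif(1, 1.5, 2.0)
      zl <- stats::runif(1, z0, z0 + (n_protein_residues - 1) * res_spacing)
      center <- c(cx + d * cos(phi), cy + d * sin(phi), zl)
    }
    for (a in seq_len(atoms_per_residue)) {
      k <- k + 1L
      pos[k, ] <- center + stats::runif(3, -jitter, jitter)
    }
  }

  residue <- rep(seq_len(n_protein_residues + n_lipids),
                 each = atoms_per_residue)
  molecule <- c(rep(1L, n_prot),          # whole protein is one molecule
                rep(seq_len(n_lipids), each = atoms_per_residue))
  group <- rep(c("protein", "lipid"), c(n_prot, n_lip))
  # split protein residues evenly into chains A and B (dimer-like layout)
  chain <- rep("none", n_protein_residues + n_lipids)
  half <- ceiling(n_protein_residues / 2)
  chain[seq_len(n_protein_residues)] <-
    rep(c("A", "B"), c(half, n_protein_residues - half))

  sys <- toy_system(
    positions = pos,
    charge = stats::runif(n, -0.5, 0.5),
    sigma = stats::runif(n, 0.25, 0.35),
    epsilon = stats::runif(n, 0.2, 0.8),
    residue = residue, molecule = molecule, group = group,
    chain = chain, box = box
  )
  attr(sys, "placement") <- placement
  sys
}

#' Generate a down-to-up transition trajectory for a toy system
#'
#' Builds an "up" reference as the "down" reference plus a fixed random
#' displacement field of given root-mean-square magnitude on the protein
#' atoms, then interpolates linearly from down to up over `n_frames` with
#' optional Gaussian positional jitter.  Each frame can additionally be
#' passed through a random rigid rotation + translation to exercise the
#' least-squares superposition step of downstream analysis.
#'
#' @param down a [toy_system] providing the down reference coordinates.
#' @param displacement_magnitude RMS displacement (nm) of protein atoms
#'   between down and up; must be positive.
#' @param n_frames number of frames (>= 2).
#' @param seed integer RNG seed.
#' @param jitter_sd standard deviation of per-coordinate Gaussian jitter
#'   (nm); 0 gives exact interpolation.
#' @param rigid_motion apply a random rigid transform to every frame?
#' @return list with `frames` (list of N x 3 matrices), `r_down`, `r_up`
#'   (N x 3 reference coordinate sets) and `protein_atoms` (index vector of
#'   displaced atoms).
#' @export
generate_transition_trajectory <- function(down, displacement_magnitude,
                                           n_frames, seed, jitter_sd = 0.02,
                                           rigid_motion = TRUE) {
  if (displacement_magnitude <= 0) {
    stop("displacement_magnitude must be positive", call. = FALSE)
  }
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  set.seed(seed)
  r_down <- down$positions
  ip <- which(down$group == "protein")
  disp <- matrix(stats::rnorm(length(ip) * 3), ncol = 3)
  # remove the net rigid-body component of the random field (superpose the
  # displaced structure back onto the reference), so down and up differ by
  # a pure deformation; interpolated frames are then optimally aligned to
  # the down state and the difference-vector identities hold exactly
  raw_up <- r_down[ip, , drop = FALSE] + disp
  disp <- superpose(raw_up, r_down[ip, , drop = FALSE])$coords -
    r_down[ip, , drop = FALSE]
  disp <- disp * displacement_magnitude / sqrt(mean(rowSums(disp^2)))
  r_up <- r_down
  r_up[ip, ] <- r_up[ip, ] + disp

  frames <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    alpha <- (t - 1) / (n_frames - 1)
    f <- (1 - alpha) * r_down + alpha * r_up
    if (jitter_sd > 0) {
      f <- f + matrix(stats::rnorm(length(f), sd = jitter_sd), ncol = 3)
    }
    if (rigid_motion) {
      rot <- random_rotation()
      shift <- stats::runif(3, -1, 1)
      f <- sweep(f %*% rot, 2, shift, "+")
    }
    frames[[t]] <- f
  }
  list(frames = frames, r_down = r_down, r_up = r_up, protein_atoms = ip)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
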