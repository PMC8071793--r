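# Electric conversion factor f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2
KE_COULOMB <- 138.935458

#' Default short-range cutoff scheme
#'
#' The short-range nonbonded scheme used throughout: plain truncation of the
#' Coulomb interaction at `r_cut` and a force-switched Lennard-Jones
#' interaction that is smoothly turned off between `r_switch` and `r_cut`.
#'
#' @param r_cut cutoff radius (nm). Default 1.2 nm.
#' @param r_switch radius (nm) at which the Lennard-Jones force switch
#'   begins. Must be strictly smaller than `r_cut`. Default 1.0 nm.
#' @return a list with elements `r_cut` and `r_switch`.
#' @export
cutoff_scheme <- function(r_cut = 1.2, r_switch = 1.0) {
  if (!is.numeric(r_cut) || !is.numeric(r_switch) ||
      length(r_cut) != 1L || length(r_switch) != 1L ||
      !is.finite(r_cut) || !is.finite(r_switch)) {
    stop("r_cut and r_switch must be finite scalars", call. = FALSE)
  }
  if (r_switch >= r_cut) stop("r_switch must be < r_cut", call. = FALSE)
  if (r_switch <= 0) stop("r_switch must be positive", call. = FALSE)
  list(r_cut = r_cut, r_switch = r_switch)
}

# Minimum-image displacement for an orthorhombic box.
# d may be a vector or matrix with one column (or slice) per dimension handled
# by the caller; here d is the raw difference along one axis and len the box
# edge along that axis.
min_image1 <- function(d, len) d - len * round(d / len)

check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) ||
      any(box <= 0)) {
    stop("box must be three positive orthorhombic edge lengths (nm); ",
         "triclinic boxes are not supported", call. = FALSE)
  }
  invisible(box)
}

# Switched inverse-power force term.
#
# For an unmodified radial force alpha / r^(p+1), returns the force-switched
# value: unchanged below r_switch, taken smoothly to zero (value and first
# derivative) at r_cut by adding A (r - r_switch)^2 + B (r - r_switch)^3 on
# the switching interval, zero beyond.  Vectorised over r.
switched_power_force <- function(r, alpha, p, r_switch, r_cut) {
  d <- r_cut - r_switch
  A <- -alpha * ((p + 4) * r_cut - (p + 1) * r_switch) / (r_cut^(p + 2) * d^2)
  B <- alpha * ((p + 3) * r_cut - (p + 1) * r_switch) / (r_cut^(p + 2) * d^3)
  f <- alpha / r^(p + 1)
  sw <- r > r_switch & r <= r_cut
  if (is.matrix(r)) {
    rs <- r[sw] - r_switch
    f[sw] <- f[sw] + A * rs^2 + B * rs^3
  } else {
    rs <- pmax(r - r_switch, 0)
    f <- f + (A * rs^2 + B * rs^3) * (r <= r_cut)
  }
  f * (r <= r_cut)
}

# Signed radial magnitude (positive = repulsive) of the short-range nonbonded
# force between two atoms at separation r.  Vectorised over all arguments.
nb_radial_force <- function(r, qq, sigma, epsilon, r_switch, r_cut) {
  fc <- ifelse(r <= r_cut, KE_COULOMB * qq / r^2, 0)
  c6 <- 4 * epsilon * sigma^6
  c12 <- 4 * epsilon * sigma^12
  flj <- switched_power_force(r, 12 * c12, 12, r_switch, r_cut) -
    switched_power_force(r, 6 * c6, 6, r_switch, r_cut)
  fc + flj
}

#' Short-range nonbonded force between two atoms
#'
#' Force on atom `a` due to atom `b` under the minimum-image convention in an
#' orthorhombic box: truncated Coulomb (conversion factor
#' 138.935458 kJ mol^-1 nm e^-2) plus Lennard-Jones with a force switch
#' between `r_switch` and `r_cut`.  Identically zero beyond `r_cut` and
#' antisymmetric under exchange of the two atoms.
#'
#' @param pos_a,pos_b positions (nm), numeric length-3 vectors.
#' @param q_a,q_b partial charges (e).
#' @param sigma,epsilon Lennard-Jones parameters of the pair (nm, kJ/mol);
#'   any combination rule is assumed to have been applied already.
#' @param box orthorhombic box edge lengths (nm), length-3.
#' @param scheme cutoff scheme, see [cutoff_scheme()].
#' @return numeric length-3 force vector (kJ mol^-1 nm^-1) acting on atom a.
#' @export
pair_atom_force <- function(pos_a, pos_b, q_a, q_b, sigma, epsilon, box,
                            scheme = cutoff_scheme()) {
  check_box(box)
  d <- min_image1(pos_a - pos_b, box)
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("singular geometry: zero interatomic distance",
                      call. = FALSE)
  if (r > scheme$r_cut) return(c(0, 0, 0))
  fmag <- nb_radial_force(r, q_a * q_b, sigma, epsilon,
                          scheme$r_switch, scheme$r_cut)
  fmag / r * d
}

# Pairwise force components between two atom sets, vectorised.
# Returns list(fx, fy, fz): n_a x n_b matrices of the force on each atom of
# set a due to each atom of set b.  Lorentz-Berthelot combination applied.
pair_force_matrix <- function(pos_a, pos_b, q_a, q_b, sig_a, sig_b,
                              eps_a, eps_b, box, scheme) {
  dx <- min_image1(outer(pos_a[, 1], pos_b[, 1], "-"), box[1])
  dy <- min_image1(outer(pos_a[, 2], pos_b[, 2], "-"), box[2])
  dz <- min_image1(outer(pos_a[, 3], pos_b[, 3], "-"), box[3])
  r <- sqrt(dx^2 + dy^2 + dz^2)
  within <- r <= scheme$r_cut
  if (any(within & r < 1e-12)) {
    stop("singular geometry: zero interatomic distance", call. = FALSE)
  }
  qq <- outer(q_a, q_b)
  sig <- outer(sig_a, sig_b, "+") / 2
  eps <- sqrt(outer(eps_a, eps_b))
  f_over_r <- matrix(0, nrow(r), ncol(r))
  idx <- which(within)
  f_over_r[idx] <- nb_radial_force(r[idx], qq[idx], sig[idx], eps[idx],
                                   scheme$r_switch, scheme$r_cut) / r[idx]
  list(fx = f_over_r * dx, fy = f_over_r * dy, fz = f_over_r * dz)
}

#' Net force between a protein residue and a lipid molecule
#'
#' Vector sum of the short-range nonbonded atom-pair forces over the
#' Cartesian product of the residue's atoms and the lipid's atoms.
#' Lennard-Jones parameters are combined per pair with the
#' Lorentz-Berthelot rule (arithmetic sigma, geometric epsilon).
#'
#' @param system a [toy_system] (or compatible list).
#' @param frame_coords optional N x 3 coordinate matrix replacing the
#'   system's own positions.
#' @param residue_index index of a protein residue of the system.
#' @param lipid_index index (molecule id) of a lipid molecule.
#' @param scheme cutoff scheme, see [cutoff_scheme()].
#' @return list with `residue_index`, `lipid_index` and `force`, the net
#'   length-3 force vector (kJ mol^-1 nm^-1) on the residue.
#' @export
residue_lipid_force <- function(system, frame_coords = NULL, residue_index,
                                lipid_index, scheme = cutoff_scheme()) {
  pos <- frame_positions(system, frame_coords)
  ia <- which(system$group == "protein" & system$residue == residue_index)
  ib <- which(system$group == "lipid" & system$molecule == lipid_index)
  if (length(ia) == 0L) stop("no protein residue with index ", residue_index,
                             call. = FALSE)
  if (length(ib) == 0L) stop("no lipid molecule with index ", lipid_index,
                             call. = FALSE)
  fm <- pair_force_matrix(pos[ia, , drop = FALSE], pos[ib, , drop = FALSE],
                          system$charge[ia], system$charge[ib],
                          system$sigma[ia], system$sigma[ib],
                          system$epsilon[ia], system$epsilon[ib],
                          system$box, scheme)
  list(residue_index = residue_index, lipid_index = lipid_index,
       force = c(sum(fm$fx), sum(fm$fy), sum(fm$fz)))
}

frame_positions <- function(system, frame_coords) {
  if (is.null(frame_coords)) return(system$positions)
  frame_coords <- as.matrix(frame_coords)
  if (!identical(dim(frame_coords), dim(system$positions))) {
    stop("frame coordinate dimensions do not match the system (",
         nrow(system$positions), " x 3 expected)", call. = FALSE)
  }
  frame_coords
}

#' Per-residue punctual stress
#'
#' For each protein residue i, the scalar sum over lipid molecules j of the
#' magnitudes |F_ij| of the net residue-lipid force: the punctual stress
#' PS_i = sum_j |F_ij|.  Note the order of operations: forces are summed as
#' vectors over all atom pairs within one residue-lipid pair, the magnitude
#' is taken, and magnitudes are then summed across lipids.  Two lipids
#' pulling a residue in opposite directions therefore add, not cancel.
#'
#' @inheritParams residue_lipid_force
#' @return named numeric vector of PS_i (kJ mol^-1 nm^-1), one entry per
#'   protein residue, in increasing residue-index order.  All entries are
#'   zero when the system has no lipids.
#' @export
punctual_stress <- function(system, frame_coords = NULL,
                            scheme = cutoff_scheme()) {
  pos <- frame_positions(system, frame_coords)
  ip <- which(system$group == "protein")
  il <- which(system$group == "lipid")
  res <- sort(unique(system$residue[ip]))
  if (length(res) == 0L) stop("system has no protein residues", call. = FALSE)
  ps <- stats::setNames(numeric(length(res)), res)
  if (length(il) == 0L) return(ps)
  fm <- pair_force_matrix(pos[ip, , drop = FALSE], pos[il, , drop = FALSE],
                          system$charge[ip], system$charge[il],
                          system$sigma[ip], system$sigma[il],
                          system$epsilon[ip], system$epsilon[il],
                          system$box, scheme)
  rg <- factor(system$residue[ip], levels = res)
  lg <- factor(system$molecule[il])
  # residue x lipid matrices of net force components
  agg <- function(m) t(rowsum(t(rowsum(m, rg)), lg))
  fx <- agg(fm$fx); fy <- agg(fm$fy); fz <- agg(fm$fz)
  ps[] <- rowSums(sqrt(fx^2 + fy^2 + fz^2))
  ps
}

#' Punctual stress along a trajectory
#'
#' Applies [punctual_stress()] to every frame of a trajectory, producing the
#' frames x residues feature matrix used as the PLS-FMA input space.
#'
#' @inheritParams punctual_stress
#' @param frames a list of N x 3 coordinate matrices, or an N x 3 x T array.
#' @param stride_ps time between stored frames (ps); frame times are
#'   `(0, 1, 2, ...) * stride_ps`.  Default 40 ps.
#' @return object of class `punctual_stress_series`: list with `values`
#'   (frames x residues matrix), `residue_ids` (data.frame with columns
#'   `residue` and `chain`) and `frame_times` (ps).
#' @export
stress_trajectory <- function(system, frames, stride_ps = 40,
                              scheme = cutoff_scheme()) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  }
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a nonempty list of coordinate matrices",
         call. = FALSE)
  }
  rows <- lapply(frames, function(f) punctual_stress(system, f, scheme))
  values <- do.call(rbind, rows)
  res <- sort(unique(system$residue[system$group == "protein"]))
  chain <- if (!is.null(system$chain)) system$chain[res] else rep("none",
                                                                  length(res))
  structure(list(
    values = values,
    residue_ids = data.frame(residue = res, chain = chain,
                             stringsAsFactors = FALSE),
    frame_times = (seq_along(frames) - 1) * stride_ps
  ), class = "punctual_stress_series")
}

#' @export
print.punctual_stress_series <- function(x, ...) {
  cat("Punctual stress series:", nrow(x$values), "frames x",
      ncol(x$values), "residues\n")
  cat("  time range:", x$frame_times[1], "-",
      x$frame_times[length(x$frame_times)], "ps\n")
  cat("  stress range:", signif(min(x$values), 4), "-",
      signif(max(x$values), 4), "kJ mol^-1 nm^-1\n")
  invisible(x)
}
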