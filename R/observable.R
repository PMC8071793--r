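#' Least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` with the rotation + translation
#' (no reflection) minimizing the RMSD over a selection of atoms, using the
#' Kabsch singular-value-decomposition construction.  The transform is
#' estimated on the selection and applied to all atoms.
#'
#' @param mobile,reference N x 3 coordinate matrices (nm) with identical
#'   atom ordering.
#' @param selection integer indices of the atoms used for fitting; default
#'   all atoms.  At least 3 non-collinear atoms are required.
#' @return list with `coords` (transformed mobile coordinates), `rmsd`
#'   (post-fit RMSD over the selection, nm), `rotation` and `translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop("mobile and reference must have identical dimensions",
         call. = FALSE)
  }
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) {
    stop("degenerate geometry: need at least 3 atoms in the selection",
         call. = FALSE)
  }
  ms <- mobile[selection, , drop = FALSE]
  rs <- reference[selection, , drop = FALSE]
  mc <- colMeans(ms)
  rc <- colMeans(rs)
  msc <- sweep(ms, 2, mc)
  rsc <- sweep(rs, 2, rc)
  h <- crossprod(msc, rsc)                 # 3x3 covariance
  sv <- svd(h)
  # collinear (or coincident) selections leave the rotation about the line
  # undetermined
  spread <- svd(msc, nu = 0, nv = 0)$d
  if (spread[2] < 1e-8 * max(spread[1], 1e-30)) {
    stop("degenerate geometry: selected atoms are collinear", call. = FALSE)
  }
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  coords <- sweep(sweep(mobile, 2, mc) %*% rot, 2, rc, "+")
  rmsd <- sqrt(mean(rowSums((coords[selection, , drop = FALSE] - rs)^2)))
  list(coords = coords, rmsd = rmsd, rotation = rot,
       translation = rc - mc %*% rot)
}

#' Up/down reference pair for the difference-vector observable
#'
#' Stores the backbone coordinates of the two reference conformations, the
#' up structure fitted onto the down structure over the backbone selection
#' (the down state is the fitting reference for all frames), their exact
#' midpoint, and the up-minus-down displacement onto which frames are
#' projected.
#'
#' @param r_up,r_down full coordinate matrices (nm) of the two reference
#'   structures, identical atom ordering.
#' @param backbone_selection ordered atom indices of the backbone atoms used
#'   for both fitting and projection.
#' @param fit superpose `r_up` onto `r_down` first?  Set `FALSE` if the two
#'   structures are already in a common frame.
#' @return object of class `reference_pair` with elements `r_up`, `r_down`,
#'   `r_avg` (selection-restricted coordinate matrices), `delta`
#'   (`r_up - r_down`), `selection` and `delta_sq` (sum of squared
#'   displacements, nm^2).
#' @export
reference_pair <- function(r_up, r_down, backbone_selection = NULL,
                           fit = TRUE) {
  r_up <- as.matrix(r_up)
  r_down <- as.matrix(r_down)
  if (!identical(dim(r_up), dim(r_down))) {
    stop("up and down references must have identical atom counts",
         call. = FALSE)
  }
  if (is.null(backbone_selection)) backbone_selection <- seq_len(nrow(r_up))
  if (fit) r_up <- superpose(r_up, r_down, backbone_selection)$coords
  up <- r_up[backbone_selection, , drop = FALSE]
  down <- r_down[backbone_selection, , drop = FALSE]
  delta <- up - down
  structure(list(r_up = up, r_down = down, r_avg = (up + down) / 2,
                 delta = delta, selection = backbone_selection,
                 delta_sq = sum(delta^2)),
            class = "reference_pair")
}

#' Difference-vector projection of one frame
#'
#' The scalar conformational observable: the projection of the frame's
#' backbone deviation from the up/down midpoint onto the up-minus-down
#' displacement, `x = sum_i (r_i - r_i_avg) . (r_i_up - r_i_down)` in nm^2.
#' The frame is assumed to be already superposed onto the down reference;
#' use [difference_series()] to fit and project a whole trajectory.
#'
#' @param frame_coords full coordinate matrix of the frame (nm).
#' @param refs a [reference_pair()].
#' @return scalar x (nm^2); positive values lie on the up side.
#' @export
difference_projection <- function(frame_coords, refs) {
  frame_coords <- as.matrix(frame_coords)
  if (max(refs$selection) > nrow(frame_coords)) {
    stop("frame has fewer atoms than the backbone selection", call. = FALSE)
  }
  f <- frame_coords[refs$selection, , drop = FALSE]
  if (!identical(dim(f), dim(refs$r_avg))) {
    stop("frame/reference shape mismatch", call. = FALSE)
  }
  sum((f - refs$r_avg) * refs$delta)
}

#' Binary state labels from the difference-vector observable
#'
#' @param x numeric vector of observable values.
#' @param threshold separatrix; the midpoint reference makes 0 the natural
#'   default.
#' @return integer vector, 1 where `x > threshold` (up side), else 0.
#' @export
label_states <- function(x, threshold = 0) as.integer(x > threshold)

#' Difference-vector observable along a trajectory
#'
#' Superposes every frame onto the down reference over the backbone
#' selection, computes the difference-vector projection and derives binary
#' state labels.
#'
#' @param frames list of N x 3 coordinate matrices.
#' @param refs a [reference_pair()].
#' @param stride_ps time between frames (ps); default 40.
#' @param threshold state-labelling threshold on x.
#' @param fit superpose each frame onto the down reference first (default);
#'   set `FALSE` for frames already in the reference frame.
#' @param normalize divide x by the squared norm of the up-minus-down
#'   displacement, mapping down to -1/2 and up to +1/2 (plotting aid)?
#' @return object of class `difference_vector_series`: list with `x`
#'   (nm^2, or dimensionless if normalized), `labels`, `frame_times`,
#'   `threshold` and `normalized`.
#' @export
difference_series <- function(frames, refs, stride_ps = 40, threshold = 0,
                              fit = TRUE, normalize = FALSE) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("frames must be a nonempty list", call. = FALSE)
  }
  x <- vapply(frames, function(f) {
    if (fit) f <- superpose_selection_only(as.matrix(f), refs)
    difference_projection(f, refs)
  }, numeric(1))
  if (normalize) x <- x / refs$delta_sq
  structure(list(x = x, labels = label_states(x, threshold),
                 frame_times = (seq_along(frames) - 1) * stride_ps,
                 threshold = threshold, normalized = normalize),
            class = "difference_vector_series")
}

# Fit a frame onto the down reference using only the selection (the
# reference_pair stores selection-restricted reference coordinates).
superpose_selection_only <- function(frame, refs) {
  sel <- refs$selection
  fs <- frame[sel, , drop = FALSE]
  fit <- superpose(fs, refs$r_down)
  frame_out <- frame
  frame_out[sel, ] <- fit$coords
  frame_out
}

#' @export
print.difference_vector_series <- function(x, ...) {
  cat("Difference-vector series:", length(x$x), "frames; x in [",
      signif(min(x$x), 4), ",", signif(max(x$x), 4),
      if (x$normalized) "] (normalized)\n" else "] nm^2\n")
  n_up <- sum(x$labels)
  cat("  frames on up side:", n_up, "/", length(x$labels),
      if (n_up == 0) "(no transition)\n" else "\n")
  invisible(x)
}

#' Write a difference-vector series as a delimited table
#'
#' Columns: frame, time_ps, x, label.
#'
#' @param series a `difference_vector_series`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_difference_series <- function(series, file) {
  df <- data.frame(frame = seq_along(series$x) - 1,
                   time_ps = series$frame_times, x = series$x,
                   label = series$labels)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
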