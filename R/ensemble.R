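#' Specification of a synthetic force ensemble
#'
#' Defines the shape and calibration of a synthetic ensemble of per-frame
#' force-feature vectors with a latent down-to-up transition.  The defaults
#' mirror the replica structure of a tension-driven channel-gating study:
#' 10 replicas (7 transitioning under tension, 3 quiescent controls) of 500
#' frames each, a 521-dimensional per-residue feature vector with 20 hotspot
#' residues of unit amplitude and mixed signs, and Gaussian feature noise of
#' standard deviation 2.0.
#'
#' @param n_replicas_transition,n_replicas_control replica counts.
#' @param n_frames frames per replica.
#' @param n_features feature-space dimension (one entry per residue).
#' @param n_hotspots number of nonzero entries of the true coefficient
#'   vector; must satisfy `n_features >= n_hotspots >= 1`.
#' @param hotspot_amplitude magnitude of each nonzero true coefficient;
#'   positive entries mean stronger force in the down state, negative
#'   entries stronger force in the up state.
#' @param noise_sigma standard deviation of i.i.d. Gaussian feature noise.
#' @param transition_window frame-index interval from which each transition
#'   replica's switch midpoint is drawn uniformly; defaults to the central
#'   30-70% of the trajectory (frames 150-350 at the default length).
#' @param ramp_frames width (frames) of the logistic switching ramp.
#' @param observable_scale scale of the noiseless observable.
#' @param observable_noise_sigma standard deviation of observable noise.
#' @param seed integer RNG seed; identical specs yield identical ensembles.
#' @return list of class `synthetic_ensemble_spec`.
#' @export
synthetic_ensemble_spec <- function(n_replicas_transition = 7,
                                    n_replicas_control = 3,
                                    n_frames = 500,
                                    n_features = 521,
                                    n_hotspots = 20,
                                    hotspot_amplitude = 1.0,
                                    noise_sigma = 2.0,
                                    transition_window = NULL,
                                    ramp_frames = 20,
                                    observable_scale = 1.0,
                                    observable_noise_sigma = 0.1,
                                    seed = 1) {
  if (is.null(transition_window)) {
    transition_window <- round(c(0.3, 0.7) * n_frames)
  }
  spec <- list(n_replicas_transition = as.integer(n_replicas_transition),
               n_replicas_control = as.integer(n_replicas_control),
               n_frames = as.integer(n_frames),
               n_features = as.integer(n_features),
               n_hotspots = as.integer(n_hotspots),
               hotspot_amplitude = hotspot_amplitude,
               noise_sigma = noise_sigma,
               transition_window = as.integer(transition_window),
               ramp_frames = ramp_frames,
               observable_scale = observable_scale,
               observable_noise_sigma = observable_noise_sigma,
               seed = as.integer(seed))
  if (spec$n_features < spec$n_hotspots || spec$n_hotspots < 1) {
    stop("need n_features >= n_hotspots >= 1", call. = FALSE)
  }
  if (spec$noise_sigma < 0 || spec$observable_noise_sigma < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (spec$n_frames < 2 || spec$n_replicas_transition < 0 ||
      spec$n_replicas_control < 0) {
    stop("invalid replica/frame counts", call. = FALSE)
  }
  if (length(spec$transition_window) != 2L ||
      spec$transition_window[1] > spec$transition_window[2] ||
      spec$transition_window[1] < 1 ||
      spec$transition_window[2] > spec$n_frames) {
    stop("transition_window must lie within [1, n_frames]", call. = FALSE)
  }
  class(spec) <- "synthetic_ensemble_spec"
  spec
}

#' Generate a synthetic force ensemble with a latent transition
#'
#' Each replica carries a latent conformational coordinate s(t): identically
#' -1 for control replicas, and for transition replicas a logistic ramp from
#' -1 to +1 centered at a frame drawn uniformly from the spec's transition
#' window.  Features are `baseline + true_coefficients * s(t) + noise`, with
#' per-feature baselines drawn once per ensemble from N(10, 2) to emulate
#' nonzero resting stress; the observable is
#' `observable_scale * s(t) + noise` and state labels are the indicator
#' s(t) > 0.  The true coefficient vector has `n_hotspots` nonzero entries
#' of magnitude `hotspot_amplitude`, half positive and half negative.
#'
#' @param spec a [synthetic_ensemble_spec()].
#' @return object of class `synthetic_ensemble`: list with `replicas` (each
#'   a list with `X`, `y`, `labels`, `kind`, `id`), `true_coefficients`,
#'   `baseline` and the generating `spec`.
#' @export
generate_force_ensemble <- function(spec = synthetic_ensemble_spec()) {
  if (!inherits(spec, "synthetic_ensemble_spec")) {
    spec <- do.call(synthetic_ensemble_spec, spec)
  }
  set.seed(spec$seed)
  p <- spec$n_features

  hot <- sort(sample.int(p, spec$n_hotspots))
  signs <- rep(c(1, -1), length.out = spec$n_hotspots)
  beta <- numeric(p)
  beta[hot] <- signs * spec$hotspot_amplitude
  baseline <- stats::rnorm(p, mean = 10, sd = 2)

  n_rep <- spec$n_replicas_transition + spec$n_replicas_control
  kinds <- rep(c("tension", "control"),
               c(spec$n_replicas_transition, spec$n_replicas_control))
  tt <- seq_len(spec$n_frames)
  replicas <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    if (kinds[r] == "tension") {
      t0 <- stats::runif(1, spec$transition_window[1],
                         spec$transition_window[2])
      s <- 2 * stats::plogis((tt - t0) / (spec$ramp_frames / 4)) - 1
    } else {
      s <- rep(-1, spec$n_frames)
    }
    noise <- matrix(stats::rnorm(spec$n_frames * p, sd = spec$noise_sigma),
                    spec$n_frames, p)
    X <- matrix(baseline, spec$n_frames, p, byrow = TRUE) +
      outer(s, beta) + noise
    y <- spec$observable_scale * s +
      stats::rnorm(spec$n_frames, sd = spec$observable_noise_sigma)
    replicas[[r]] <- list(X = X, y = y, labels = as.integer(s > 0),
                          kind = kinds[r], id = r)
  }
  structure(list(replicas = replicas, true_coefficients = beta,
                 hotspots = hot, baseline = baseline, spec = spec),
            class = "synthetic_ensemble")
}

#' @export
print.synthetic_ensemble <- function(x, ...) {
  kinds <- vapply(x$replicas, `[[`, "", "kind")
  cat("Synthetic force ensemble:", length(x$replicas), "replicas (",
      sum(kinds == "tension"), "tension,", sum(kinds == "control"),
      "control ),", x$spec$n_frames, "frames x", x$spec$n_features,
      "features\n")
  cat("  hotspots:", length(x$hotspots), "of amplitude",
      x$spec$hotspot_amplitude, "; feature noise sd", x$spec$noise_sigma,
      "\n")
  invisible(x)
}

#' Write a synthetic ensemble to disk
#'
#' One comma-delimited feature matrix per replica (with `y` and `label`
#' columns appended) plus a JSON manifest holding the generating spec, the
#' replica kinds and the true coefficient vector.
#'
#' @param ensemble a `synthetic_ensemble`.
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest path.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(ensemble$replicas))
  for (i in seq_along(ensemble$replicas)) {
    r <- ensemble$replicas[[i]]
    df <- as.data.frame(r$X)
    names(df) <- paste0("f", seq_len(ncol(r$X)))
    df$y <- r$y
    df$label <- r$labels
    files[i] <- file.path(dir, sprintf("replica_%02d.csv", r$id))
    utils::write.csv(df, files[i], row.names = FALSE)
  }
  manifest <- list(spec = unclass(ensemble$spec),
                   replica_files = basename(files),
                   replica_kinds = vapply(ensemble$replicas, `[[`, "",
                                          "kind"),
                   true_coefficients = ensemble$true_coefficients,
                   hotspots = ensemble$hotspots)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a synthetic ensemble written by [write_ensemble()]
#'
#' @param dir directory containing `manifest.json` and the replica files.
#' @return a `synthetic_ensemble`.
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  replicas <- vector("list", length(manifest$replica_files))
  for (i in seq_along(replicas)) {
    df <- utils::read.csv(file.path(dir, manifest$replica_files[i]))
    fcols <- grep("^f[0-9]+$", names(df))
    replicas[[i]] <- list(X = as.matrix(df[, fcols]), y = df$y,
                          labels = as.integer(df$label),
                          kind = manifest$replica_kinds[i], id = i)
  }
  structure(list(replicas = replicas,
                 true_coefficients = manifest$true_coefficients,
                 hotspots = manifest$hotspots,
                 baseline = NULL,
                 spec = do.call(synthetic_ensemble_spec,
                                manifest$spec[names(manifest$spec) != ""])),
            class = "synthetic_ensemble")
}
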