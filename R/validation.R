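#' ROC area under the curve (Mann-Whitney formulation)
#'
#' Fraction of (positive, negative) frame pairs in which the positive frame
#' scores higher, ties counted one half.  Computed from midranks, which is
#' algebraically identical to the pair count.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Per-fold prediction table for one held-out replica at each component
# truncation 1..K.
fold_predictions <- function(model, X) {
  vapply(seq_len(model$n_components),
         function(k) predict(model, X, ncomp = k),
         numeric(nrow(X)))
}

#' Leave-one-trajectory-out cross-validation of PLS-FMA
#'
#' Holds out each replica in turn, fits the PLS model on the remaining
#' replicas and evaluates on the held-out one.  For replicas containing a
#' transition (both state labels present) the ROC AUC of the predicted
#' observable against the held-out labels and the Pearson correlation
#' between predicted and observed observable are reported; for control
#' replicas (single-class labels) AUC is undefined and the per-frame
#' false-positive fraction - the fraction of frames whose predicted
#' observable exceeds the state threshold - is reported instead.
#'
#' When `n_components` is `NULL` the number of components is chosen by the
#' default policy: the smallest K at which the cross-validated mean Pearson
#' correlation (over transition replicas) stops improving by at least
#' `improve_tol` over K-1, capped at `max_components`.
#'
#' @param replicas list of replicas, each a list with `X` (frames x p),
#'   `y` (observable), `labels` (binary states) and optionally `kind` and
#'   `id`.  A [generate_force_ensemble()] result may be passed directly.
#' @param n_components number of PLS components, or `NULL` for the default
#'   selection policy.
#' @param threshold state threshold on the predicted observable.
#' @param max_components cap for the selection policy.
#' @param improve_tol minimal correlation improvement that justifies one
#'   more component.
#' @return object of class `validation_report`: list with `per_replica`
#'   (data.frame: replica_id, kind, auc, pearson_r,
#'   false_positive_fraction), `n_components`, `ensemble_vector` (the
#'   sign-aligned average of the per-fold coefficient vectors),
#'   `vector_similarity` (pairwise cosine matrix of the fold vectors),
#'   `first_component_contribution` (per fold, on its training data),
#'   `r_path` (mean held-out correlation at each candidate K) and
#'   `predictions` (per replica, the held-out predicted observable at the
#'   selected K).
#' @export
cross_validate <- function(replicas, n_components = NULL, threshold = 0,
                           max_components = 20, improve_tol = 0.01) {
  if (inherits(replicas, "synthetic_ensemble")) replicas <- replicas$replicas
  m <- length(replicas)
  if (m < 2L) stop("need at least 2 replicas", call. = FALSE)
  replicas <- lapply(seq_len(m), function(i) {
    r <- replicas[[i]]
    r$X <- as.matrix(r$X)
    r$labels <- as.integer(r$labels)
    if (is.null(r$id)) r$id <- i
    if (is.null(r$kind)) {
      r$kind <- if (length(unique(r$labels)) > 1L) "tension" else "control"
    }
    r
  })

  k_fit <- if (is.null(n_components)) max_components else n_components
  n_min <- min(vapply(replicas, function(r) nrow(r$X), integer(1)))
  k_fit <- min(k_fit, (m - 1L) * n_min - 1L)

  models <- vector("list", m)
  preds <- vector("list", m)     # held-out predictions at each K
  contrib1 <- numeric(m)
  for (f in seq_len(m)) {
    train <- replicas[-f]
    Xtr <- do.call(rbind, lapply(train, `[[`, "X"))
    ytr <- unlist(lapply(train, `[[`, "y"))
    fit <- suppressWarnings(fit_pls(Xtr, ytr, k_fit))
    models[[f]] <- fit
    preds[[f]] <- fold_predictions(fit, replicas[[f]]$X)
    contrib1[f] <- component_contribution(fit, Xtr, ytr)[1]
  }

  k_avail <- min(vapply(models, `[[`, integer(1), "n_components"))
  transition <- vapply(replicas, function(r)
    length(unique(r$labels)) > 1L, logical(1))
  r_path <- vapply(seq_len(k_avail), function(k) {
    mean(vapply(which(transition), function(f)
      stats::cor(preds[[f]][, k], replicas[[f]]$y), numeric(1)))
  }, numeric(1))

  if (is.null(n_components)) {
    k_sel <- k_avail
    for (k in seq_len(k_avail)[-1]) {
      if (r_path[k] - r_path[k - 1] < improve_tol) { k_sel <- k - 1L; break }
    }
    if (k_avail == 1L) k_sel <- 1L
  } else {
    k_sel <- min(n_components, k_avail)
  }

  per <- data.frame(replica_id = vapply(replicas, `[[`, integer(1), "id"),
                    kind = vapply(replicas, `[[`, character(1), "kind"),
                    auc = NA_real_, pearson_r = NA_real_,
                    false_positive_fraction = NA_real_)
  for (f in seq_len(m)) {
    yhat <- preds[[f]][, k_sel]
    if (stats::sd(replicas[[f]]$y) > 0) {
      per$pearson_r[f] <- stats::cor(yhat, replicas[[f]]$y)
    }
    if (transition[f]) {
      per$auc[f] <- roc_auc(yhat, replicas[[f]]$labels)
    } else {
      per$false_positive_fraction[f] <- mean(yhat > threshold)
    }
  }

  vecs <- lapply(models, function(mod) mod$coef_path[, k_sel])
  avg <- ensemble_average_vectors(vecs)
  structure(list(per_replica = per, n_components = k_sel,
                 ensemble_vector = avg$average,
                 vector_similarity = avg$similarity,
                 first_component_contribution = contrib1,
                 r_path = r_path, fold_vectors = vecs,
                 predictions = lapply(preds, function(pm) pm[, k_sel]),
                 threshold = threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Leave-one-trajectory-out validation (", x$n_components,
      "PLS components )\n")
  per <- x$per_replica
  tr <- per[!is.na(per$auc), ]
  co <- per[is.na(per$auc), ]
  if (nrow(tr) > 0) {
    cat(sprintf("  transition replicas: AUC %.3f-%.3f, Pearson r %.3f-%.3f\n",
                min(tr$auc), max(tr$auc), min(tr$pearson_r),
                max(tr$pearson_r)))
  }
  if (nrow(co) > 0) {
    cat("  control replicas: false-positive fractions",
        paste(sprintf("%.1f%%", 100 * co$false_positive_fraction),
              collapse = ", "), "\n")
  }
  cat(sprintf("  first-component contribution: %.1f%% (mean over folds)\n",
              100 * mean(x$first_component_contribution)))
  invisible(x)
}

#' Chain-symmetry comparison of coefficient vectors
#'
#' For a homodimer, compares the per-residue coefficients of chain A with
#' those of the equivalent residues of chain B.  Returns the paired
#' coefficients, their Pearson correlation and, for the top-k residues of
#' each chain and sign, the rank the partner residue attains in the other
#' chain.
#'
#' @param coefficients named numeric vector (names = residue ids).
#' @param residue_ids character vector of residue ids matching
#'   `coefficients`; ignored if `coefficients` is already named.
#' @param pairing data.frame (or two-column matrix) mapping chain-A residue
#'   ids to chain-B residue ids.
#' @param k number of top residues per sign to examine.
#' @return list with `pairs` (data.frame id_a, id_b, coef_a, coef_b),
#'   `pearson_r`, `top` (data.frame: direction, rank, id_a, coef_a, id_b,
#'   coef_b, partner_rank) and `unpaired` (ids without a usable partner,
#'   excluded from the correlation).
#' @export
chain_symmetry <- function(coefficients, residue_ids = NULL, pairing,
                           k = 5) {
  if (!is.null(residue_ids)) names(coefficients) <- as.character(residue_ids)
  if (is.null(names(coefficients))) {
    stop("coefficients must carry residue ids", call. = FALSE)
  }
  pairing <- as.data.frame(pairing)
  ida <- as.character(pairing[[1]])
  idb <- as.character(pairing[[2]])
  ok <- ida %in% names(coefficients) & idb %in% names(coefficients)
  unpaired <- unique(c(ida[!ok], idb[!ok]))
  ida <- ida[ok]; idb <- idb[ok]
  if (length(ida) < 2L) stop("fewer than 2 usable residue pairs",
                             call. = FALSE)
  pairs <- data.frame(id_a = ida, id_b = idb,
                      coef_a = unname(coefficients[ida]),
                      coef_b = unname(coefficients[idb]),
                      stringsAsFactors = FALSE)
  r <- stats::cor(pairs$coef_a, pairs$coef_b)

  rank_desc <- function(v) rank(-v, ties.method = "first")
  rank_asc <- function(v) rank(v, ties.method = "first")
  top <- do.call(rbind, lapply(c("positive", "negative"), function(dir) {
    ra <- if (dir == "positive") rank_desc(pairs$coef_a)
          else rank_asc(pairs$coef_a)
    rb <- if (dir == "positive") rank_desc(pairs$coef_b)
          else rank_asc(pairs$coef_b)
    sel <- order(ra)[seq_len(min(k, nrow(pairs)))]
    data.frame(direction = dir, rank = ra[sel], id_a = pairs$id_a[sel],
               coef_a = pairs$coef_a[sel], id_b = pairs$id_b[sel],
               coef_b = pairs$coef_b[sel], partner_rank = rb[sel],
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, pearson_r = r, top = top, unpaired = unpaired)
}

#' Top force-hotspot residues of a coefficient vector
#'
#' The k most positive (stronger lipid force in the down state) and k most
#' negative (stronger force after the transition to the up state)
#' coefficients, each ordered by magnitude; ties are broken by residue
#' position, ascending.
#'
#' @param coefficients numeric vector of per-residue coefficients.
#' @param residue_ids residue identifiers; default positional indices.
#' @param k list length per sign (default 5).
#' @return list with data.frames `positive` and `negative`, each with
#'   columns `residue` and `coefficient`.
#' @export
top_residues <- function(coefficients, residue_ids = NULL, k = 5) {
  p <- length(coefficients)
  if (k > p / 2) stop("k must not exceed half the number of residues",
                      call. = FALSE)
  if (is.null(residue_ids)) residue_ids <- seq_len(p)
  pos <- order(-coefficients, seq_len(p))[seq_len(k)]
  neg <- order(coefficients, seq_len(p))[seq_len(k)]
  list(positive = data.frame(residue = residue_ids[pos],
                             coefficient = coefficients[pos]),
       negative = data.frame(residue = residue_ids[neg],
                             coefficient = coefficients[neg]))
}

#' Write a validation report to disk
#'
#' A JSON file with the full report plus a human-readable tab-delimited
#' per-replica summary and a two-column residue/coefficient table for the
#' ensemble-averaged PLS vector.
#'
#' @param report a [cross_validate()] result.
#' @param dir output directory, created if needed.
#' @param residue_ids optional residue ids for the coefficient table.
#' @return invisibly, the JSON path.
#' @export
write_validation_report <- function(report, dir, residue_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "validation_report.json")
  obj <- list(per_replica = report$per_replica,
              n_components = report$n_components,
              ensemble_vector = report$ensemble_vector,
              vector_similarity = report$vector_similarity,
              first_component_contribution =
                report$first_component_contribution,
              r_path = report$r_path, threshold = report$threshold)
  jsonlite::write_json(obj, jpath, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor", dataframe = "columns",
                       na = "null")
  utils::write.table(report$per_replica,
                     file.path(dir, "per_replica_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (is.null(residue_ids)) {
    residue_ids <- seq_along(report$ensemble_vector)
  }
  utils::write.table(
    data.frame(residue_id = residue_ids,
               coefficient = report$ensemble_vector),
    file.path(dir, "ensemble_coefficients.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(jpath)
}
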