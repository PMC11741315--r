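# Model Fit Score, penalty-grid ensembles, top-model selection, Group
# Sparsity Scores, and candidate-locus ranking.

#' Model Fit Score
#'
#' Root mean squared difference between the ±1 trait values and the model's
#' predicted trait values on its own training species, with predicted trait
#' value `2*sigma(SPS) - 1` (sigma the logistic function), so predictions are
#' bounded in (-1, 1) in the manner of a Brier score. MFS lies in [0, 2];
#' lower is better, and the all-zero model on balanced data scores exactly 1.
#'
#' @param model An `esl_model`.
#' @param X Training feature matrix the model was fitted on.
#' @param y Training ±1 responses.
#' @param scale `"probability"` (default, the bounded form) or `"raw"` to use
#'   the raw SPS as the predicted trait value.
#' @return The MFS, a non-negative scalar.
#' @export
model_fit_score <- function(model, X, y, scale = c("probability", "raw")) {
  scale <- match.arg(scale)
  s <- predict_sps(model, X)
  yhat <- if (scale == "probability") 2 * stats::plogis(s) - 1 else s
  sqrt(mean((y - yhat)^2))
}

#' Fit a grid ensemble of sparse-group models
#'
#' Fits one model per penalty setting (fractions of the maximum non-trivial
#' penalties) and computes each model's MFS. Consecutive fits are
#' warm-started along the grid; every fit still satisfies the solver
#' tolerance on its own.
#'
#' @param features An `esl_features` built on the training species.
#' @param y ±1 response vector aligned to the feature rows.
#' @param grid Data frame from [penalty_grid()].
#' @param weights Optional locus weights; defaults to
#'   [group_penalty_weights()] of the encoded variable-site counts.
#' @param tol,max_iter Passed to [fit_sgl()].
#' @param warm_start Warm start along the grid (default TRUE).
#' @return An `esl_ensemble`: `models`, `mfs`, `grid`, `penalty_max`,
#'   `weights`, `feature_map`, `selected` (initially all models).
#' @export
build_ensemble <- function(features, y, grid = penalty_grid(),
                           weights = NULL, tol = 1e-7, max_iter = 10000L,
                           warm_start = TRUE) {
  stopifnot(nrow(grid) >= 1)
  X <- features$X
  groups <- features$feature_map$locus
  if (is.null(weights))
    weights <- group_penalty_weights(variable_site_counts(features))
  pm <- penalty_max(X, y, groups, weights)
  L <- max(eigen(tcrossprod(cbind(1, X)), symmetric = TRUE,
                 only.values = TRUE)$values) / (4 * nrow(X))
  models <- vector("list", nrow(grid))
  mfs <- numeric(nrow(grid))
  init <- NULL
  for (k in seq_len(nrow(grid))) {
    pen <- list(site_fraction = grid$site_fraction[k],
                group_fraction = grid$group_fraction[k],
                site_lambda = grid$site_fraction[k] * pm$site_lambda_max,
                group_lambda = grid$group_fraction[k] * pm$group_lambda_max)
    m <- fit_sgl(X, y, pen$site_lambda, pen$group_lambda, groups, weights,
                 penalty = pen, tol = tol, max_iter = max_iter, init = init,
                 lipschitz = L)
    if (warm_start) init <- list(intercept = m$intercept, beta = m$beta)
    models[[k]] <- m
    mfs[k] <- model_fit_score(m, X, y)
  }
  structure(list(models = models, mfs = mfs, grid = grid, penalty_max = pm,
                 weights = weights, feature_map = features$feature_map,
                 selected = seq_len(nrow(grid))),
            class = "esl_ensemble")
}

#' @export
print.esl_ensemble <- function(x, ...) {
  cat("esl_ensemble: ", length(x$models), " models (",
      length(x$selected), " selected); MFS range [",
      signif(min(x$mfs), 4), ", ", signif(max(x$mfs), 4), "]\n", sep = "")
  invisible(x)
}

#' Select the best-fitting fraction of an ensemble
#'
#' Retains the `ceiling(fraction * n)` models with lowest MFS (default the
#' top 5%); ties at the cutoff are broken by grid order. Selected indices are
#' stored sorted by MFS ascending.
#'
#' @param ensemble An `esl_ensemble`.
#' @param fraction Fraction of models to keep, in (0, 1].
#' @return The ensemble with an updated `selected` index set.
#' @export
select_top_models <- function(ensemble, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  n_keep <- ceiling(fraction * length(ensemble$models))
  ord <- order(ensemble$mfs, seq_along(ensemble$mfs))
  ensemble$selected <- ord[seq_len(n_keep)]
  ensemble
}

#' Ensemble predictions and classification metrics
#'
#' The ensemble SPS of a species is the unweighted mean of the selected
#' models' SPS. The predicted label is its sign; an exactly zero ensemble
#' SPS is reported unclassified and counts as an error in the true-positive
#' and true-negative rates.
#'
#' @param ensemble An `esl_ensemble` (after [select_top_models()] if
#'   desired).
#' @param X_new Encoded matrix, one row per species, aligned to the model
#'   feature space.
#' @param true_labels Optional named ±1 vector of known labels (NA for
#'   unknown).
#' @return List of class `esl_predictions`: `table` (species, `sps`,
#'   `predicted`, `true`), `per_model` SPS matrix, `tpr`, `tnr`,
#'   `balanced_accuracy` (NA when no labels).
#' @export
ensemble_predict <- function(ensemble, X_new, true_labels = NULL) {
  if (!length(ensemble$selected)) stop("ensemble has no selected models")
  sel <- ensemble$models[ensemble$selected]
  per_model <- vapply(sel, function(m) predict_sps(m, X_new),
                      numeric(nrow(X_new)))
  per_model <- matrix(per_model, nrow = nrow(X_new),
                      dimnames = list(rownames(X_new), NULL))
  sps <- rowMeans(per_model)
  predicted <- sign(sps)
  true <- rep(NA_real_, nrow(X_new))
  if (!is.null(true_labels)) {
    idx <- match(rownames(X_new), names(true_labels))
    true <- as.numeric(true_labels[idx])
  }
  tpr <- tnr <- ba <- NA_real_
  if (any(!is.na(true))) {
    npos <- sum(true == 1, na.rm = TRUE)
    nneg <- sum(true == -1, na.rm = TRUE)
    if (npos) tpr <- sum(predicted == 1 & !is.na(true) & true == 1) / npos
    if (nneg) tnr <- sum(predicted == -1 & !is.na(true) & true == -1) / nneg
    if (npos && nneg) ba <- (tpr + tnr) / 2
  }
  structure(list(
    table = data.frame(species = rownames(X_new), sps = sps,
                       predicted = predicted, true = true,
                       stringsAsFactors = FALSE, row.names = NULL),
    per_model = per_model, tpr = tpr, tnr = tnr, balanced_accuracy = ba),
    class = "esl_predictions")
}

#' @export
print.esl_predictions <- function(x, ...) {
  print(x$table, ...)
  if (!is.na(x$balanced_accuracy))
    cat("TPR ", signif(x$tpr, 4), ", TNR ", signif(x$tnr, 4),
        ", balanced accuracy ", signif(x$balanced_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Group Sparsity Scores of one model
#'
#' GSS of a locus is the sum of absolute coefficient values over its
#' selected positions; loci contributing no selected position score 0. The
#' GSS values over all loci sum to the L1 norm of the coefficient vector.
#'
#' @param model An `esl_model`.
#' @param loci Optional character vector fixing the locus universe (loci
#'   absent from the model's feature space score 0).
#' @return Named numeric vector, locus -> GSS.
#' @export
group_sparsity_scores <- function(model, loci = NULL) {
  gss <- rowsum(abs(model$beta), model$groups, reorder = FALSE)[, 1]
  if (!is.null(loci)) {
    out <- stats::setNames(numeric(length(loci)), loci)
    out[names(gss)] <- gss
    return(out)
  }
  gss
}

# per-model competition ranks (ties share the best rank) over loci with
# nonzero GSS; loci at zero get NA
.gss_ranks <- function(gss) {
  r <- rep(NA_real_, length(gss))
  nz <- which(gss > 0)
  if (length(nz)) r[nz] <- rank(-gss[nz], ties.method = "min")
  names(r) <- names(gss)
  r
}

#' Rank candidate loci from one ensemble
#'
#' Within each model, loci are ranked by GSS descending with competition
#' ranking (ties share a rank). A locus's overall rank is the best per-model
#' rank it attains anywhere in the ensemble; ties are ordered by the maximum
#' GSS attained in any model, then by locus id. Loci never selected rank
#' last and are flagged.
#'
#' @param ensemble An `esl_ensemble`. All models are used (selection by MFS
#'   applies to prediction, not to candidate discovery).
#' @return Data frame `locus`, `best_rank`, `max_gss`, `selected`,
#'   `final_rank`, ordered best first.
#' @export
rank_candidates_single <- function(ensemble) {
  loci <- unique(ensemble$feature_map$locus)
  best_rank <- stats::setNames(rep(Inf, length(loci)), loci)
  max_gss <- stats::setNames(numeric(length(loci)), loci)
  for (m in ensemble$models) {
    gss <- group_sparsity_scores(m, loci)
    r <- .gss_ranks(gss)
    hit <- !is.na(r)
    best_rank[hit] <- pmin(best_rank[hit], r[hit])
    max_gss <- pmax(max_gss, gss)
  }
  out <- data.frame(locus = loci, best_rank = unname(best_rank),
                    max_gss = unname(max_gss),
                    selected = unname(is.finite(best_rank)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_rank, -out$max_gss, out$locus), , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# per-combination summary used by the multi-combination integration
.combo_summary <- function(ensemble) {
  loci <- unique(ensemble$feature_map$locus)
  best_rank <- stats::setNames(rep(Inf, length(loci)), loci)
  max_gss <- stats::setNames(numeric(length(loci)), loci)
  top1 <- stats::setNames(rep(FALSE, length(loci)), loci)
  for (m in ensemble$models) {
    gss <- group_sparsity_scores(m, loci)
    r <- .gss_ranks(gss)
    hit <- !is.na(r)
    best_rank[hit] <- pmin(best_rank[hit], r[hit])
    max_gss <- pmax(max_gss, gss)
    n_ranked <- sum(hit)
    if (n_ranked)
      top1 <- top1 | (!is.na(r) & r <= ceiling(0.01 * n_ranked))
  }
  list(loci = loci, best_rank = best_rank, max_gss = max_gss,
       nonzero = is.finite(best_rank), top1 = top1)
}

#' Integrate candidate rankings across species combinations
#'
#' Loci are ordered by the number of species combinations in which they
#' received a nonzero GSS in at least one model; ties are resolved by the
#' number of combinations in which they ranked in the top 1% of loci with
#' nonzero GSS, then by the best rank ever attained, then by the highest GSS
#' ever attained, then by locus id.
#'
#' @param ensembles List of at least two `esl_ensemble` objects, one per
#'   species combination.
#' @return Data frame `locus`, `n_combos_nonzero`, `n_combos_top1pct`,
#'   `best_rank`, `max_gss`, `final_rank`, ordered best first.
#' @export
integrate_rankings_multi <- function(ensembles) {
  if (length(ensembles) < 2L)
    stop("need at least two species-combination ensembles")
  sums <- lapply(ensembles, .combo_summary)
  loci <- sort(unique(unlist(lapply(sums, `[[`, "loci"))))
  acc <- data.frame(locus = loci, n_combos_nonzero = 0L,
                    n_combos_top1pct = 0L, best_rank = Inf, max_gss = 0,
                    stringsAsFactors = FALSE)
  for (s in sums) {
    i <- match(s$loci, acc$locus)
    acc$n_combos_nonzero[i] <- acc$n_combos_nonzero[i] + as.integer(s$nonzero)
    acc$n_combos_top1pct[i] <- acc$n_combos_top1pct[i] + as.integer(s$top1)
    acc$best_rank[i] <- pmin(acc$best_rank[i], s$best_rank)
    acc$max_gss[i] <- pmax(acc$max_gss[i], s$max_gss)
  }
  acc <- acc[order(-acc$n_combos_nonzero, -acc$n_combos_top1pct,
                   acc$best_rank, -acc$max_gss, acc$locus), , drop = FALSE]
  acc$final_rank <- seq_len(nrow(acc))
  rownames(acc) <- NULL
  acc
}

#' Export the MFS surface over the penalty grid
#'
#' @param ensemble An `esl_ensemble`.
#' @param path Optional TSV path; when given, writes columns
#'   `site_fraction`, `group_fraction`, `mfs`.
#' @return Data frame of the grid with MFS, invisibly when written.
#' @export
mfs_grid <- function(ensemble, path = NULL) {
  out <- cbind(ensemble$grid, mfs = ensemble$mfs)
  if (!is.null(path)) {
    utils::write.table(format(out, digits = 6, trim = TRUE), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
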