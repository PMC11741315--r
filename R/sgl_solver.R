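# Bilevel sparse (site + locus) penalized logistic regression.
#
# Objective, for responses y in {-1,+1} and binary indicator matrix X with
# columns partitioned into loci g:
#
#   F(b0, b) = (1/N) sum_i log(1 + exp(-y_i (b0 + x_i . b)))
#              + lambda_site * sum_j |b_j|
#              + lambda_group * sum_g w_g ||b_g||_2
#
# with the intercept b0 unpenalized. Minimized by accelerated proximal
# gradient descent (FISTA with adaptive restart); the proximal operator of
# the combined penalty is elementwise soft-thresholding followed by a
# groupwise Euclidean shrink, which yields exact zeros at both levels.

# log(1 + exp(z)) without overflow
.log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# internal fast paths use integer group codes (gi in 1..n_groups) and a
# weight vector gww aligned to those codes
.sgl_objective <- function(eta, y, beta, gi, lam1, lam2, gww) {
  loss <- mean(.log1pexp(-y * eta))
  pen1 <- lam1 * sum(abs(beta))
  gn <- sqrt(rowsum(beta^2, gi, reorder = FALSE))
  loss + pen1 + lam2 * sum(gww * gn)
}

.soft <- function(u, t) sign(u) * pmax(abs(u) - t, 0)

# prox of t * (lam1 ||.||_1 + lam2 sum_g w_g ||.||_2), separable by group
.sgl_prox <- function(u, t, lam1, lam2, gi, gww) {
  v <- .soft(u, t * lam1)
  if (lam2 > 0) {
    gn <- sqrt(rowsum(v^2, gi, reorder = FALSE))[, 1]
    shrink <- pmax(0, 1 - t * lam2 * gww / pmax(gn, .Machine$double.eps))
    shrink[gn == 0] <- 0
    v <- v * shrink[gi]
  }
  v
}

#' Locus-level penalty weights
#'
#' The weight of each locus scales linearly with its number of variable
#' sites plus a constant equal to the median variable-site count over loci
#' with at least one variable site: `w_g = v_g + median(v)`. Fully invariant
#' loci are excluded from both the median and the model. Compared with the
#' conventional square-root-of-group-size weight, this keeps highly conserved
#' loci with a few strongly trait-associated sites competitive.
#'
#' @param variable_site_counts Named integer vector, locus -> number of
#'   variable sites among training species (see [variable_site_counts()]).
#' @return Named numeric vector of positive weights over loci with
#'   `v_g > 0`; the median used is stored in attribute `median`.
#' @export
group_penalty_weights <- function(variable_site_counts) {
  v <- variable_site_counts[variable_site_counts > 0]
  if (!length(v))
    stop("all loci are invariant among training species; no signal to model")
  m <- stats::median(v)
  w <- v + m
  attr(w, "median") <- m
  w
}

#' Smallest penalties forcing the all-zero model
#'
#' With the unpenalized intercept at its null optimum (0 for balanced ±1
#' responses), the gradient of the mean logistic loss at zero coefficients is
#' `g_j = -(1/(2N)) sum_i y_i x_ij`. The site penalty maximum is `max_j
#' |g_j|`; the locus penalty maximum is `max_g ||g_g||_2 / w_g`. Each is the
#' smallest value of that penalty which yields the trivial all-zero solution
#' when the other penalty is zero.
#'
#' @param X Feature matrix (rows = training species).
#' @param y Balanced ±1 response vector.
#' @param groups Locus id per column of `X`.
#' @param weights Named locus weights from [group_penalty_weights()].
#' @return List `site_lambda_max`, `group_lambda_max`.
#' @export
penalty_max <- function(X, y, groups, weights) {
  stopifnot(nrow(X) == length(y), ncol(X) == length(groups))
  g <- as.vector(crossprod(X, y)) / (-2 * nrow(X))
  if (max(abs(g)) == 0)
    stop("degenerate signal: no feature column covaries with the response")
  gn <- sqrt(rowsum(g^2, groups, reorder = FALSE))[, 1]
  list(site_lambda_max = max(abs(g)),
       group_lambda_max = max(gn / weights[names(gn)]))
}

#' Log-spaced grid of penalty fractions
#'
#' Fractions of the respective maximum non-trivial penalty, log-spaced on
#' `[lo, hi]` (default 1%-99%) for the site and locus axes, combined as a
#' Cartesian product in site-major order. A degenerate axis with a single
#' value returns the lower endpoint.
#'
#' @param n_site,n_group Number of values per axis.
#' @param lo,hi Fraction range, `0 < lo < hi < 1`.
#' @return Data frame `site_fraction`, `group_fraction` with
#'   `n_site * n_group` rows.
#' @export
penalty_grid <- function(n_site = 20, n_group = 20, lo = 0.01, hi = 0.99) {
  if (n_site < 1 || n_group < 1) stop("grid dimensions must be >= 1")
  if (!(lo > 0 && lo < hi && hi < 1)) stop("need 0 < lo < hi < 1")
  logspace <- function(n) if (n == 1L) lo else exp(seq(log(lo), log(hi), length.out = n))
  sf <- logspace(n_site); gf <- logspace(n_group)
  data.frame(site_fraction = rep(sf, each = n_group),
             group_fraction = rep(gf, times = n_site))
}

#' Fit one sparse-group logistic model
#'
#' Minimizes the bilevel-sparsity objective (see the package overview) by
#' accelerated proximal gradient descent from a zero start (or a supplied
#' warm start). Coefficients outside the active set are exactly zero.
#'
#' @param X Feature matrix, rows = training species in configuration order.
#' @param y ±1 response vector.
#' @param site_lambda,group_lambda Penalty levels (absolute, not fractions).
#' @param groups Locus id per column of `X`.
#' @param weights Named locus weights.
#' @param penalty Optional list with `site_fraction`/`group_fraction`
#'   recorded on the model for bookkeeping.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Iteration cap; non-convergence returns the current iterate
#'   with `converged = FALSE` and a warning.
#' @param init Optional warm start, list `intercept`, `beta`.
#' @param lipschitz Optional precomputed Lipschitz bound of the loss
#'   gradient (reused across an ensemble's fits on the same matrix).
#' @return An `esl_model`: `intercept`, `beta` (full-length numeric with
#'   exact zeros), `penalty`, `converged`, `n_iter`, `objective`.
#' @export
fit_sgl <- function(X, y, site_lambda, group_lambda, groups, weights,
                    penalty = NULL, tol = 1e-7, max_iter = 10000L,
                    init = NULL, lipschitz = NULL) {
  if (!all(is.finite(X))) stop("X contains NaN or Inf")
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y),
            ncol(X) == length(groups))
  N <- nrow(X); p <- ncol(X)
  groups <- as.character(groups)
  glev <- unique(groups)
  gi <- match(groups, glev)               # integer codes, appearance order
  gww <- unname(weights[glev])
  if (anyNA(gww)) stop("weights missing for group(s): ",
                       paste(glev[is.na(gww)], collapse = ", "))
  # Lipschitz bound for the logistic loss gradient, intercept included
  L <- lipschitz %||%
    (max(eigen(tcrossprod(cbind(1, X)), symmetric = TRUE,
               only.values = TRUE)$values) / (4 * N))
  t_step <- 1 / L
  b0 <- if (is.null(init)) 0 else init$intercept
  b <- if (is.null(init)) numeric(p) else init$beta
  z0 <- b0; z <- b
  theta <- 1
  eta <- as.vector(b0 + X %*% b)
  obj <- .sgl_objective(eta, y, b, gi, site_lambda, group_lambda, gww)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta_z <- as.vector(z0 + X %*% z)
    s <- -y * stats::plogis(-y * eta_z)      # d/d_eta of the logistic loss
    grad0 <- mean(s)
    grad <- as.vector(crossprod(X, s)) / N
    b0_new <- z0 - t_step * grad0
    b_new <- .sgl_prox(z - t_step * grad, t_step, site_lambda, group_lambda,
                       gi, gww)
    eta_new <- as.vector(b0_new + X %*% b_new)
    obj_new <- .sgl_objective(eta_new, y, b_new, gi, site_lambda,
                              group_lambda, gww)
    if (obj_new > obj) {            # adaptive restart: drop momentum
      z0 <- b0; z <- b; theta <- 1
      eta_z <- as.vector(z0 + X %*% z)
      s <- -y * stats::plogis(-y * eta_z)
      b0_new <- z0 - t_step * mean(s)
      b_new <- .sgl_prox(z - t_step * as.vector(crossprod(X, s)) / N, t_step,
                         site_lambda, group_lambda, gi, gww)
      eta_new <- as.vector(b0_new + X %*% b_new)
      obj_new <- .sgl_objective(eta_new, y, b_new, gi, site_lambda,
                                group_lambda, gww)
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    mom <- (theta - 1) / theta_new
    z0 <- b0_new + mom * (b0_new - b0)
    z <- b_new + mom * (b_new - b)
    done <- abs(obj - obj_new) <= tol * max(1, abs(obj))
    b0 <- b0_new; b <- b_new; obj <- obj_new; theta <- theta_new
    if (done) {
      # objective change alone can stall on flat FISTA stretches; also require
      # the proximal-gradient mapping at the accepted point to be stationary
      s <- -y * stats::plogis(-y * eta_new)
      g0 <- mean(s)
      gb <- as.vector(crossprod(X, s)) / N
      pb <- .sgl_prox(b - t_step * gb, t_step, site_lambda, group_lambda,
                      gi, gww)
      res <- max(abs(g0), max(abs(pb - b)) / t_step)
      if (res <= 100 * tol * max(1, abs(obj))) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("sparse-group fit did not converge in ", max_iter, " iterations")
  names(b) <- colnames(X)
  structure(list(intercept = b0, beta = b, groups = groups,
                 penalty = penalty %||% list(site_lambda = site_lambda,
                                             group_lambda = group_lambda),
                 site_lambda = site_lambda, group_lambda = group_lambda,
                 converged = converged, n_iter = it, objective = obj),
            class = "esl_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.esl_model <- function(x, ...) {
  cat("esl_model: ", sum(x$beta != 0), "/", length(x$beta),
      " nonzero coefficients, intercept ", signif(x$intercept, 4),
      ", objective ", signif(x$objective, 6),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Sequence prediction score
#'
#' The linear score `SPS = b0 + x . beta` of an encoded species under one
#' fitted model. A positive SPS predicts the trait-positive state, negative
#' the trait-negative state.
#'
#' @param model An `esl_model`.
#' @param x Encoded 0/1 vector (or matrix, species in rows) aligned to the
#'   model's feature space; see [encode_for_prediction()].
#' @return Numeric score(s).
#' @export
predict_sps <- function(model, x) {
  if (is.matrix(x)) {
    if (ncol(x) != length(model$beta))
      stop("feature-space mismatch: ", ncol(x), " columns vs ",
           length(model$beta), " model coefficients")
    return(as.vector(model$intercept + x %*% model$beta))
  }
  if (length(x) != length(model$beta))
    stop("feature-space mismatch: ", length(x), " features vs ",
         length(model$beta), " model coefficients")
  model$intercept + sum(x * model$beta)
}

#' Serialize a fitted model
#'
#' Writes the nonzero coefficients as TSV (`column_index`, `locus`,
#' `site_1based`, `residue`, `coefficient`) plus a JSON sidecar holding the
#' intercept, penalty setting, and convergence metadata.
#'
#' @param model An `esl_model`.
#' @param features The `esl_features` the model was fitted on.
#' @param aln The `esl_concat` behind the features.
#' @param path Output TSV path; the sidecar gets extension `.json`.
#' @export
write_model <- function(model, features, aln, path) {
  fm <- features$feature_map
  gm <- aln$group_map
  start_of <- stats::setNames(gm$start, gm$locus)
  nz <- which(model$beta != 0)
  out <- data.frame(column_index = fm$column[nz],
                    locus = fm$locus[nz],
                    site_1based = fm$site[nz] - start_of[fm$locus[nz]] + 1L,
                    residue = fm$residue[nz],
                    coefficient = unname(model$beta[nz]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(intercept = model$intercept, penalty = model$penalty,
               converged = model$converged, n_iter = model$n_iter,
               objective = model$objective)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
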