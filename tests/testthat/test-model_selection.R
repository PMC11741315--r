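# build a minimal fitted-model stub
stub_model <- function(beta, groups, intercept = 0) {
  structure(list(intercept = intercept, beta = beta, groups = groups),
            class = "esl_model")
}

# build a minimal ensemble from a list of coefficient vectors
stub_ensemble <- function(betas, groups, mfs = NULL) {
  models <- lapply(betas, stub_model, groups = groups)
  structure(list(models = models,
                 mfs = mfs %||% seq_along(models),
                 grid = data.frame(site_fraction = seq_along(models),
                                   group_fraction = 1),
                 feature_map = data.frame(column = seq_along(groups),
                                          locus = groups,
                                          site = seq_along(groups),
                                          residue = "A"),
                 selected = seq_along(models)),
            class = "esl_ensemble")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the Model Fit Score is calibrated on the probability scale", {
  X <- diag(4)
  y <- c(1, -1, 1, -1)
  zero <- stub_model(rep(0, 4), rep("G1", 4))
  expect_identical(model_fit_score(zero, X, y), 1)  # sigma(0) = 1/2 exactly
  # s = (+2.2, -2.2, +2.2, -2.2): predicted trait = tanh(1.1), frozen from
  # direct evaluation of 2*sigma(2.2) - 1
  sep <- stub_model(c(2.2, -2.2, 2.2, -2.2), rep("G1", 4))
  expect_equal(model_fit_score(sep, X, y), 0.1995009782, tolerance = 1e-9)
  # raw scale uses the SPS itself
  expect_equal(model_fit_score(sep, X, y, scale = "raw"), 1.2)
  # MFS tends to 0 as separation grows
  big <- stub_model(c(50, -50, 50, -50), rep("G1", 4))
  expect_lt(model_fit_score(big, X, y), 1e-10)
  # and is bounded by 2 (maximally wrong model)
  wrong <- stub_model(c(-50, 50, -50, 50), rep("G1", 4))
  expect_lte(model_fit_score(wrong, X, y), 2)
  expect_gt(model_fit_score(wrong, X, y), 1.99)
})

test_that("grid ensembles are deterministic and sized by the grid", {
  toy <- make_toy_fixture()
  cc <- concatenate_alignments(toy$alignments, sort(names(toy$traits)))
  cfg <- training_configuration(toy$pairs)
  f <- one_hot_encode(cc, cfg$species, filter_training_sites(cc, cfg$species))
  e1 <- build_ensemble(f, cfg$response, grid = penalty_grid(4, 4))
  expect_length(e1$models, 16)
  e2 <- build_ensemble(f, cfg$response, grid = penalty_grid(4, 4))
  expect_identical(e1$mfs, e2$mfs)        # bitwise reproducible
  # warm-started and cold-started fits agree in objective
  e3 <- build_ensemble(f, cfg$response, grid = penalty_grid(4, 4),
                       warm_start = FALSE)
  expect_equal(vapply(e1$models, `[[`, numeric(1), "objective"),
               vapply(e3$models, `[[`, numeric(1), "objective"),
               tolerance = 1e-5)
})

test_that("top-model selection keeps the ceiling of the MFS fraction", {
  e400 <- stub_ensemble(rep(list(c(0, 0)), 400), c("G1", "G1"),
                        mfs = rev(seq_len(400)) / 400)
  expect_length(select_top_models(e400, 0.05)$selected, 20)
  # the best-MFS models are the chosen ones
  expect_setequal(select_top_models(e400, 0.05)$selected, 381:400)
  e16 <- stub_ensemble(rep(list(c(0, 0)), 16), c("G1", "G1"))
  expect_length(select_top_models(e16, 0.05)$selected, 1)
  expect_equal(select_top_models(e16, 0.05)$selected, 1L)
  expect_length(select_top_models(e16, 1)$selected, 16)
  # ties at the cutoff break by grid order
  etie <- stub_ensemble(rep(list(c(0, 0)), 4), c("G1", "G1"),
                        mfs = c(0.5, 0.2, 0.2, 0.2))
  expect_equal(select_top_models(etie, 0.5)$selected, c(2L, 3L))
})

test_that("ensemble predictions average SPS and score known labels", {
  ens <- stub_ensemble(list(c(0.4, 0), c(0.8, 0)), c("G1", "G1"))
  X <- rbind(sp1 = c(1, 0), sp2 = c(0, 1))
  p <- ensemble_predict(ens, X, c(sp1 = 1, sp2 = -1))
  expect_equal(p$table$sps, c(0.6, 0))
  expect_equal(p$table$predicted, c(1, 0)) # exact zero is unclassified
  expect_equal(p$tpr, 1)
  expect_equal(p$tnr, 0)                   # unclassified counts as an error
  expect_equal(p$balanced_accuracy, 0.5)
  # perfect two-species case
  ens2 <- stub_ensemble(list(c(0.5, -0.3)), c("G1", "G1"))
  p2 <- ensemble_predict(ens2, X, c(sp1 = 1, sp2 = -1))
  expect_equal(p2$balanced_accuracy, 1)
  # all-zero models leave every species unclassified
  ens0 <- stub_ensemble(list(c(0, 0)), c("G1", "G1"))
  p0 <- ensemble_predict(ens0, X, c(sp1 = 1, sp2 = -1))
  expect_equal(p0$table$predicted, c(0, 0))
  expect_equal(p0$balanced_accuracy, 0)
})

test_that("group sparsity scores sum absolute coefficients per locus", {
  m <- stub_model(c(0.5, -0.25, 0, 0.1), c("G1", "G1", "G2", "G3"))
  gss <- group_sparsity_scores(m)
  expect_equal(gss[["G1"]], 0.75)
  expect_equal(gss[["G2"]], 0)
  # absent loci score zero when a universe is supplied
  gss2 <- group_sparsity_scores(m, loci = c("G1", "G2", "G3", "G4"))
  expect_equal(gss2[["G4"]], 0)
  # partition identity: GSS totals the L1 norm
  expect_equal(sum(gss), sum(abs(m$beta)))
})

test_that("single-combination ranking uses best rank, then max GSS, then id", {
  ens <- stub_ensemble(
    list(c(0.9, 0, 0.2, 0), c(0, 0.7, 0.3, 0)),
    groups = c("G1", "G2", "G3", "G4"))
  rk <- rank_candidates_single(ens)
  # G1 best rank 1 (gss .9), G2 best rank 1 (gss .7), G3 best rank 2
  expect_equal(rk$locus, c("G1", "G2", "G3", "G4"))
  expect_equal(rk$best_rank[1:3], c(1, 1, 2))
  expect_false(rk$selected[4])             # all-zero locus flagged, ranked last
  expect_equal(rk$final_rank, 1:4)
})

test_that("single-combination ranking matches a brute-force sort oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n_loci <- 6
    groups <- paste0("G", rep(1:n_loci, each = 2))
    betas <- lapply(1:4, function(i) {
      b <- round(stats::rnorm(length(groups)), 2)
      b[sample(length(b), 5)] <- 0
      b
    })
    ens <- stub_ensemble(betas, groups)
    got <- rank_candidates_single(ens)
    # oracle: recompute per-model competition ranks from scratch
    loci <- paste0("G", 1:n_loci)
    per_model <- lapply(betas, function(b) {
      gss <- vapply(loci, function(l) sum(abs(b[groups == l])), numeric(1))
      r <- rep(NA, n_loci)
      nz <- gss > 0
      r[nz] <- rank(-gss[nz], ties.method = "min")
      list(gss = gss, rank = r)
    })
    best <- apply(do.call(rbind, lapply(per_model, `[[`, "rank")), 2,
                  function(z) if (all(is.na(z))) Inf else min(z, na.rm = TRUE))
    mx <- apply(do.call(rbind, lapply(per_model, `[[`, "gss")), 2, max)
    ord <- order(best, -mx, loci)
    expect_equal(got$locus, loci[ord])
  }
})

test_that("multi-combination integration follows the documented key order", {
  mk <- function(betas, groups) stub_ensemble(betas, groups)
  groups <- c("G1", "G2", "G3")
  # combo 1: G1 and G2 nonzero; combo 2: G1 only; combo 3: G1, G2, G3
  e1 <- mk(list(c(1, 0.5, 0)), groups)
  e2 <- mk(list(c(0.2, 0, 0)), groups)
  e3 <- mk(list(c(0.1, 0.4, 0.3)), groups)
  out <- integrate_rankings_multi(list(e1, e2, e3))
  expect_equal(out$locus, c("G1", "G2", "G3"))
  expect_equal(out$n_combos_nonzero, c(3, 2, 1))
  expect_error(integrate_rankings_multi(list(e1)), "at least two")
})

test_that("multi-combination ordering matches a brute-force oracle", {
  set.seed(9)
  groups <- paste0("G", rep(1:5, each = 2))
  loci <- paste0("G", 1:5)
  enss <- lapply(1:3, function(c) {
    betas <- lapply(1:3, function(i) {
      b <- round(stats::rnorm(length(groups)), 2)
      b[sample(length(b), 6)] <- 0
      b
    })
    stub_ensemble(betas, groups)
  })
  got <- integrate_rankings_multi(enss)
  # oracle recomputation
  summ <- lapply(enss, function(e) {
    gssm <- sapply(e$models, function(m)
      vapply(loci, function(l) sum(abs(m$beta[groups == l])), numeric(1)))
    ranks <- apply(gssm, 2, function(g) {
      r <- rep(NA, length(g)); nz <- g > 0
      r[nz] <- rank(-g[nz], ties.method = "min"); r
    })
    top1 <- sapply(seq_len(ncol(gssm)), function(j) {
      nr <- sum(!is.na(ranks[, j]))
      !is.na(ranks[, j]) & ranks[, j] <= ceiling(0.01 * nr)
    })
    list(nonzero = apply(gssm, 1, function(z) any(z > 0)),
         top1 = apply(top1, 1, any),
         best = apply(ranks, 1, function(z)
           if (all(is.na(z))) Inf else min(z, na.rm = TRUE)),
         mx = apply(gssm, 1, max))
  })
  ncz <- rowSums(sapply(summ, `[[`, "nonzero"))
  nt1 <- rowSums(sapply(summ, `[[`, "top1"))
  bst <- apply(sapply(summ, `[[`, "best"), 1, min)
  mxg <- apply(sapply(summ, `[[`, "mx"), 1, max)
  ord <- order(-ncz, -nt1, bst, -mxg, loci)
  expect_equal(got$locus, loci[ord])
})

test_that("an all-zero locus never perturbs the relative order of others", {
  groups <- c("G1", "G2")
  base <- stub_ensemble(list(c(0.9, 0.4), c(0.2, 0.8)), groups)
  with_dead <- stub_ensemble(list(c(0.9, 0.4, 0), c(0.2, 0.8, 0)),
                             c(groups, "G0"))
  r1 <- rank_candidates_single(base)
  r2 <- rank_candidates_single(with_dead)
  expect_equal(r1$locus, setdiff(r2$locus, "G0"))
})
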