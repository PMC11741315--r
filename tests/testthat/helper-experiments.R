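# Simulation experiments shared by the acceptance tests: each takes a seed
# and returns summary statistics computed with the package's public surface.

`%||%` <- function(a, b) if (is.null(a)) b else a

# fit a PSC ensemble on a benchmark dataset and predict its held-out species
fit_and_predict <- function(bench, config, grid, top_fraction = 0.05,
                            concat = NULL) {
  cc <- concat %||% concatenate_alignments(bench$alignments,
                                           sort(names(bench$traits)))
  feats <- one_hot_encode(cc, config$species,
                          filter_training_sites(cc, config$species))
  ens <- select_top_models(build_ensemble(feats, config$response, grid = grid),
                           top_fraction)
  Xh <- do.call(rbind, lapply(bench$heldout, encode_for_prediction, aln = cc,
                              feature_map = feats$feature_map))
  rownames(Xh) <- bench$heldout
  list(ensemble = ens, features = feats, concat = cc,
       prediction = ensemble_predict(ens, Xh, bench$traits))
}

# convergent-locus recovery under penetrance 1 (trees of 8-16 leaves,
# 3-10 loci), at the default 20x20 penalty grid
recovery_experiment <- function(seed) {
  n_pairs <- 3 + seed %% 4               # 3..6 contrast pairs (cherry clades)
  n_heldout <- 1 + seed %% 2
  n_loci <- 3 + seed %% 8                # 3..10 loci
  bench <- make_benchmark_dataset(seed, n_clades = n_pairs,
                                  n_heldout = n_heldout, n_loci = n_loci,
                                  penetrance = 1, paired_siblings = FALSE,
                                  n_convergent_loci = 1)
  cfg <- training_configuration(bench$pairs)
  res <- fit_and_predict(bench, cfg, penalty_grid(20, 20))
  rk <- rank_candidates_single(res$ensemble)
  implanted <- unique(bench$ground_truth$convergent$locus)
  top <- rk$locus[seq_along(implanted)]
  pos_held <- bench$heldout[bench$traits[bench$heldout] > 0]
  tab <- res$prediction$table
  list(recovered = setequal(top, implanted),
       heldout_ba = res$prediction$balanced_accuracy,
       pos_sps = tab$sps[match(pos_held, tab$species)])
}

# aggregate SPS over a list of selected ensembles and classify held-out
# species; used by both null constructions
aggregate_null_ba <- function(ensembles_and_feats, bench) {
  sps <- 0; n_models <- 0
  for (ef in ensembles_and_feats) {
    cc <- ef$concat
    Xh <- do.call(rbind, lapply(bench$heldout, encode_for_prediction, aln = cc,
                                feature_map = ef$features$feature_map))
    rownames(Xh) <- bench$heldout
    p <- ensemble_predict(ef$ensemble, Xh)
    k <- length(ef$ensemble$selected)
    sps <- sps + rowSums(p$per_model); n_models <- n_models + k
  }
  mean_sps <- sps / n_models
  truth <- bench$traits[bench$heldout]
  pred <- sign(mean_sps)
  tpr <- mean(pred[truth > 0] == 1)
  tnr <- mean(pred[truth < 0] == -1)
  (tpr + tnr) / 2
}

# response-flipped and pair-randomized null ensembles on one simulated
# dataset; returns held-out balanced accuracy for each construction
null_experiment <- function(seed, grid = penalty_grid(5, 5)) {
  bench <- make_benchmark_dataset(seed, n_clades = 4, n_heldout = 3,
                                  penetrance = 1)
  cc <- concatenate_alignments(bench$alignments, sort(names(bench$traits)))
  cfg <- training_configuration(bench$pairs)
  flips <- enumerate_response_flips(cfg, 2)
  flip_runs <- lapply(flips, function(nc) {
    feats <- one_hot_encode(cc, nc$species,
                            filter_training_sites(cc, nc$species))
    ens <- select_top_models(build_ensemble(feats, nc$response, grid = grid))
    list(ensemble = ens, features = feats, concat = cc)
  })
  rand_runs <- lapply(1:3, function(r) {
    rnd <- pair_randomize(cc, cfg$pairs, seed = seed * 100 + r)
    feats <- one_hot_encode(rnd, cfg$species,
                            filter_training_sites(rnd, cfg$species))
    ens <- select_top_models(build_ensemble(feats, cfg$response, grid = grid))
    list(ensemble = ens, features = feats, concat = rnd)
  })
  list(flip_ba = aggregate_null_ba(flip_runs, bench),
       rand_ba = aggregate_null_ba(rand_runs, bench))
}

# PSC versus naive training configurations on data with clade-concentrated
# confound sites; returns held-out true-positive rates
psc_vs_naive_experiment <- function(seed, grid = penalty_grid(5, 5)) {
  bench <- make_benchmark_dataset(seed, n_clades = 4, n_heldout = 3,
                                  penetrance = 0.9, n_confound = 4)
  cc <- concatenate_alignments(bench$alignments, sort(names(bench$traits)))
  psc_cfg <- training_configuration(bench$pairs)
  psc <- fit_and_predict(bench, psc_cfg, grid, concat = cc)
  pool <- unlist(lapply(bench$slots, function(s) c(s$positive, s$negative)))
  naive_cfg <- sample_naive_configuration(bench$traits, 4, 4, pool,
                                          seed = seed + 500)
  naive <- fit_and_predict(bench, naive_cfg, grid, concat = cc)
  c(psc_tpr = psc$prediction$tpr, naive_tpr = naive$prediction$tpr)
}
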