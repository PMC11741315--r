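# End-to-end pipeline: validate -> filter -> encode -> weights -> grid ->
# fit -> MFS -> select -> GSS/rank -> predict (-> nulls), with a manifest
# capturing every seed and setting.

#' Assemble a run configuration
#'
#' @param alignments_dir Directory of per-locus FASTA files.
#' @param tree_path Newick file with the rooted species tree.
#' @param traits_path Trait table TSV (species, +1/-1).
#' @param pairs_path Pair-slot TSV (`slot_id`, `role`, `species`).
#' @param out_dir Output directory.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param n_site,n_group Penalty-grid dimensions.
#' @param top_fraction Fraction of models kept for the predictive ensemble.
#' @param combinations `"single"` (first choice per slot) or `"enumerate"`
#'   (all valid species combinations, with cross-combination ranking).
#' @param null_mode `"off"`, `"response-flip"`, or `"pair-randomize"`.
#' @param null_replicates Replicates for the pair-randomized null / cap for
#'   sampled response-flip configurations.
#' @param exclude_loci Locus ids dropped before encoding (e.g. to test the
#'   effect of removing a dominant locus).
#' @param seed Seed recorded in the manifest and used for any sampling.
#' @return A `run_config` list, validated against the file system.
#' @export
run_config <- function(alignments_dir, tree_path, traits_path, pairs_path,
                       out_dir, alphabet = "protein", n_site = 20,
                       n_group = 20, top_fraction = 0.05,
                       combinations = c("single", "enumerate"),
                       null_mode = c("off", "response-flip", "pair-randomize"),
                       null_replicates = 10, exclude_loci = character(0),
                       seed = 1) {
  combinations <- match.arg(combinations)
  null_mode <- match.arg(null_mode)
  for (p in c(alignments_dir, tree_path, traits_path, pairs_path))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(alignments_dir = alignments_dir, tree_path = tree_path,
                 traits_path = traits_path, pairs_path = pairs_path,
                 out_dir = out_dir, alphabet = alphabet, n_site = n_site,
                 n_group = n_group, top_fraction = top_fraction,
                 combinations = combinations, null_mode = null_mode,
                 null_replicates = null_replicates,
                 exclude_loci = exclude_loci, seed = seed),
            class = "run_config")
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# fit + select + predict for one training configuration
.run_one_combo <- function(concat, config, traits, grid, top_fraction) {
  mask <- filter_training_sites(concat, config$species)
  features <- one_hot_encode(concat, config$species, mask)
  ens <- build_ensemble(features, config$response, grid = grid)
  ens <- select_top_models(ens, top_fraction)
  others <- setdiff(concat$species, config$species)
  pred <- NULL
  if (length(others)) {
    Xnew <- do.call(rbind, lapply(others, encode_for_prediction, aln = concat,
                                  feature_map = features$feature_map))
    rownames(Xnew) <- others
    pred <- ensemble_predict(ens, Xnew, traits)
  }
  list(ensemble = ens, features = features, prediction = pred)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the inputs referenced by the configuration and
#' writes predictions, candidate rankings, the MFS grid, the best model's
#' coefficients, and a JSON manifest. Identical configuration and inputs
#' produce identical outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the in-memory results (`ensembles`,
#'   `ranking`, `predictions`, `null`); outputs are written under
#'   `config$out_dir`.
#' @export
run_eslpsc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tree <- stage("read-tree", read_species_tree(config$tree_path))
  traits <- stage("read-traits", read_trait_table(config$traits_path))
  slots <- stage("read-pairs", read_pair_slots(config$pairs_path))
  alns <- stage("read-alignments",
                read_alignment_dir(config$alignments_dir, config$alphabet))
  if (length(config$exclude_loci))
    alns <- alns[setdiff(names(alns), config$exclude_loci)]
  concat <- stage("concatenate",
                  concatenate_alignments(alns, sort(names(traits))))
  configs <- stage("psc-design", {
    if (config$combinations == "enumerate") enumerate_combinations(tree, slots)
    else {
      pairs <- contrast_pairs(
        vapply(slots, function(s) sort(s$positive)[1], character(1)),
        vapply(slots, function(s) sort(s$negative)[1], character(1)))
      rep <- validate_psc_pairs(tree, pairs)
      if (!all(rep$valid))
        stop("invalid contrast pair(s): ",
             paste(rep$pos[!rep$valid], rep$neg[!rep$valid],
                   sep = "/", collapse = ", "))
      list(training_configuration(pairs))
    }
  })
  grid <- penalty_grid(config$n_site, config$n_group)
  runs <- stage("fit", lapply(configs, .run_one_combo, concat = concat,
                              traits = traits, grid = grid,
                              top_fraction = config$top_fraction))
  ranking <- stage("rank", {
    if (length(runs) >= 2L)
      integrate_rankings_multi(lapply(runs, `[[`, "ensemble"))
    else rank_candidates_single(runs[[1]]$ensemble)
  })
  .write_tsv(ranking, file.path(config$out_dir, "rankings.tsv"))
  mfs_grid(runs[[1]]$ensemble, file.path(config$out_dir, "mfs_grid.tsv"))
  best <- runs[[1]]$ensemble$models[[runs[[1]]$ensemble$selected[1]]]
  write_model(best, runs[[1]]$features, concat,
              file.path(config$out_dir, "best_model.tsv"))
  pred <- runs[[1]]$prediction
  if (!is.null(pred))
    .write_tsv(pred$table, file.path(config$out_dir, "predictions.tsv"))
  null_out <- NULL
  if (config$null_mode == "response-flip") {
    base <- configs[[1]]
    nulls <- enumerate_response_flips(base, nrow(base$pairs) %/% 2,
                                      max_count = config$null_replicates,
                                      seed = config$seed)
    null_out <- lapply(nulls, function(nc) {
      mask <- filter_training_sites(concat, nc$species)
      feats <- one_hot_encode(concat, nc$species, mask)
      ens <- select_top_models(build_ensemble(feats, nc$response, grid = grid),
                               config$top_fraction)
      list(flipped = attr(nc, "flipped_pairs"), ensemble = ens, features = feats)
    })
    manifest_null <- lapply(null_out, function(x)
      list(flipped_pairs = x$flipped))
  } else if (config$null_mode == "pair-randomize") {
    base <- configs[[1]]
    seeds <- config$seed + seq_len(config$null_replicates)
    null_out <- lapply(seeds, function(s) {
      rnd <- pair_randomize(concat, base$pairs, seed = s)
      mask <- filter_training_sites(rnd, base$species)
      feats <- one_hot_encode(rnd, base$species, mask)
      ens <- select_top_models(build_ensemble(feats, base$response, grid = grid),
                               config$top_fraction)
      list(seed = s, ensemble = ens, features = feats)
    })
    manifest_null <- lapply(null_out, function(x) list(seed = x$seed))
  } else manifest_null <- NULL
  manifest <- list(
    config = unclass(config),
    version = as.character(utils::packageVersion("eslpsc")),
    n_combinations = length(configs),
    n_models_per_combination = nrow(grid),
    null = manifest_null,
    complete = TRUE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(ensembles = lapply(runs, `[[`, "ensemble"),
                 ranking = ranking,
                 predictions = pred, null = null_out, concat = concat,
                 configs = configs))
}

#' Command-line interface
#'
#' Dispatches the subcommands `simulate`, `validate-pairs`, `run`, `null`
#' and `rank`. Installed as the script `cli/esl_psc.R`; see the package
#' README for usage.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
eslpsc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: esl_psc.R <simulate|validate-pairs|run|null|rank> [options]",
    "  simulate       --out DIR [--seed N] [--n-clades N] [--penetrance X]",
    "  validate-pairs --tree FILE --pairs FILE",
    "  run|null|rank  --alignments DIR --tree FILE --traits FILE --pairs FILE",
    "                 --out DIR [--alphabet protein|nucleotide]",
    "                 [--n-site N] [--n-group N] [--top-fraction X]",
    "                 [--enumerate] [--null-mode MODE] [--null-replicates N]",
    "                 [--exclude-loci L1,L2] [--seed N]", sep = "\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    rest[i[1] + 1L]
  }
  has <- function(flag) flag %in% rest
  if (cmd == "simulate") {
    out <- opt("--out"); if (is.null(out)) stop("simulate requires --out")
    seed <- as.integer(opt("--seed", "1"))
    bench <- make_benchmark_dataset(
      seed, n_clades = as.integer(opt("--n-clades", "4")),
      penetrance = as.numeric(opt("--penetrance", "1")))
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_alignment_dir(bench$alignments, file.path(out, "alignments"))
    ape::write.tree(bench$tree, file.path(out, "tree.nwk"))
    utils::write.table(data.frame(names(bench$traits), bench$traits),
                       file.path(out, "traits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    slot_df <- do.call(rbind, lapply(names(bench$slots), function(id)
      rbind(data.frame(slot = id, role = "pos",
                       species = bench$slots[[id]]$positive),
            data.frame(slot = id, role = "neg",
                       species = bench$slots[[id]]$negative))))
    utils::write.table(slot_df, file.path(out, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(bench$ground_truth,
                         file.path(out, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    message("simulated dataset written to ", out)
    return(invisible(0L))
  }
  if (cmd == "validate-pairs") {
    tree <- read_species_tree(opt("--tree"))
    slots <- read_pair_slots(opt("--pairs"))
    pairs <- contrast_pairs(
      vapply(slots, function(s) sort(s$positive)[1], character(1)),
      vapply(slots, function(s) sort(s$negative)[1], character(1)))
    rep <- validate_psc_pairs(tree, pairs)
    utils::write.table(rep, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(if (all(rep$valid)) 0L else 1L))
  }
  if (cmd %in% c("run", "null", "rank")) {
    cfg <- run_config(
      alignments_dir = opt("--alignments"), tree_path = opt("--tree"),
      traits_path = opt("--traits"), pairs_path = opt("--pairs"),
      out_dir = opt("--out"), alphabet = opt("--alphabet", "protein"),
      n_site = as.integer(opt("--n-site", "20")),
      n_group = as.integer(opt("--n-group", "20")),
      top_fraction = as.numeric(opt("--top-fraction", "0.05")),
      combinations = if (has("--enumerate") || cmd == "rank") "enumerate" else "single",
      null_mode = if (cmd == "null") opt("--null-mode", "response-flip") else "off",
      null_replicates = as.integer(opt("--null-replicates", "10")),
      exclude_loci = if (is.null(opt("--exclude-loci"))) character(0)
                     else strsplit(opt("--exclude-loci"), ",")[[1]],
      seed = as.integer(opt("--seed", "1")))
    run_eslpsc(cfg)
    message("run complete; outputs in ", cfg$out_dir)
    return(invisible(0L))
  }
  stop("unknown subcommand '", cmd, "'\n", usage)
}
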