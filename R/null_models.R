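# Two negative controls: response-flipped training configurations and
# pair-randomized alignments.

#' Enumerate response-flipped null configurations
#'
#' Flipping a contrast pair negates the responses of both its species. For
#' 2n pairs, flipping n of them is the largest scrambling of the phenotype
#' designations: both the shared phylogenetic signal and any genuine
#' convergent signal cancel. There are then `choose(2n, n) / 2` distinct
#' configurations, because a flip set and its complement yield responses
#' differing only by a global sign; complements are deduplicated by keeping
#' the set that does not contain the first pair. For other flip counts all
#' `choose(n_pairs, n_flip)` subsets are returned.
#'
#' @param config An `esl_config` from [training_configuration()].
#' @param n_flip Number of pairs to flip.
#' @param max_count Optional cap; a seeded uniform sample without
#'   replacement is drawn when the full enumeration exceeds it.
#' @param seed Seed for the optional subsampling.
#' @return List of `esl_config` objects, each with attribute
#'   `flipped_pairs` (1-based indices of flipped pairs).
#' @export
enumerate_response_flips <- function(config, n_flip, max_count = NULL,
                                     seed = NULL) {
  n_pairs <- nrow(config$pairs)
  if (n_flip < 1 || n_flip > n_pairs)
    stop("n_flip must be between 1 and the number of pairs (", n_pairs, ")")
  sets <- utils::combn(n_pairs, n_flip, simplify = FALSE)
  if (2L * n_flip == n_pairs) {
    # complement pairs are one configuration: keep the set without pair 1
    sets <- Filter(function(s) !(1L %in% s), sets)
  }
  if (!is.null(max_count) && length(sets) > max_count) {
    if (is.null(seed)) stop("subsampling null configurations requires a seed")
    set.seed(seed)
    sets <- sets[sort(sample(length(sets), max_count))]
  }
  lapply(sets, function(s) {
    cfg <- config
    flip_species <- c(rbind(config$pairs$pos[s], config$pairs$neg[s]))
    cfg$response <- ifelse(cfg$species %in% flip_species,
                           -cfg$response, cfg$response)
    attr(cfg, "flipped_pairs") <- s
    cfg
  })
}

#' Pair-randomize an alignment
#'
#' For every retained variable site and every contrast pair, an independent
#' fair coin decides whether the residues of the two pair members are
#' swapped. Phylogenetic structure within the alignment is preserved, but
#' averaged over replicates any correlation between residues and the trait
#' contrast is destroyed. Rows of species outside the pairs and sites
#' outside the mask are untouched, and the per-site residue multiset within
#' each pair is conserved.
#'
#' @param aln An `esl_concat`.
#' @param pairs Data frame from [contrast_pairs()].
#' @param mask Optional logical site mask restricting which sites may be
#'   swapped; defaults to sites that pass [filter_training_sites()] for the
#'   pair species and are variable among them.
#' @param seed Integer seed; output is reproducible given the seed.
#' @param swap_prob Coin probability (0.5 for the fair flip; exposed for
#'   sensitivity analysis).
#' @return A new `esl_concat` with swapped residues.
#' @export
pair_randomize <- function(aln, pairs, mask = NULL, seed, swap_prob = 0.5) {
  sp <- c(pairs$pos, pairs$neg)
  .check_species(aln, sp)
  if (is.null(mask)) {
    mask <- filter_training_sites(aln, sp)
    sub <- aln$matrix[sp, , drop = FALSE]
    n_distinct <- apply(sub, 2, function(col) length(unique(col)))
    mask <- mask & n_distinct > 1L
  }
  stopifnot(length(mask) == ncol(aln$matrix))
  sites <- which(mask)
  set.seed(seed)
  out <- aln
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$pos[i]; b <- pairs$neg[i]
    coins <- stats::runif(length(sites)) < swap_prob
    sw <- sites[coins]
    if (length(sw)) {
      tmp <- out$matrix[a, sw]
      out$matrix[a, sw] <- out$matrix[b, sw]
      out$matrix[b, sw] <- tmp
    }
  }
  out
}
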