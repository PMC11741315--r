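# Paired species contrast (PSC) design: pair validation against the
# phylogeny, enumeration of allowable training configurations, and naive
# (non-PSC) sampling for comparison experiments.

#' Read a rooted species tree
#'
#' @param path Newick file with a single rooted tree.
#' @return An `ape` `phylo` object.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree, got several")
  .check_tree(tree)
  tree
}

.check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. with an outgroup) before use — ",
         "most recent common ancestors are undefined on unrooted trees")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  invisible(tree)
}

.check_tips <- function(tree, species) {
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not found in tree: ", paste(unknown, collapse = ", "))
}

.clade_tips <- function(tree, pair) {
  node <- ape::getMRCA(tree, pair)
  ape::extract.clade(tree, node)$tip.label
}

#' Build a contrast-pair table
#'
#' @param pos,neg Character vectors of trait-positive and trait-negative
#'   species, matched by position.
#' @return Data frame with columns `pos` and `neg`.
#' @export
contrast_pairs <- function(pos, neg) {
  stopifnot(length(pos) == length(neg))
  if (any(pos == neg)) stop("a pair cannot contrast a species with itself")
  data.frame(pos = pos, neg = neg, stringsAsFactors = FALSE)
}

#' Read a contrast-pair table
#'
#' Tab-separated columns `slot_id`, `role` (`pos` or `neg`), `species`, no
#' header. Slots with several species per role describe alternative
#' (interchangeable) pair members for [enumerate_combinations()].
#'
#' @param path TSV path.
#' @return Named list of slots, each `list(positive = ..., negative = ...)`.
#' @export
read_pair_slots <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("slot_id", "role", "species"))
  if (!all(df$role %in% c("pos", "neg")))
    stop("role column must be 'pos' or 'neg'")
  slots <- lapply(split(df, factor(df$slot_id, levels = unique(df$slot_id))),
                  function(s) list(positive = sort(s$species[s$role == "pos"]),
                                   negative = sort(s$species[s$role == "neg"])))
  empty <- names(slots)[vapply(slots, function(s)
    !length(s$positive) || !length(s$negative), logical(1))]
  if (length(empty))
    stop("slot(s) missing a pos or neg species: ", paste(empty, collapse = ", "))
  slots
}

#' Validate contrast pairs against the phylogeny
#'
#' A pair is valid iff the clade under the most recent common ancestor of its
#' two members contains no other selected species — equivalently, the MRCA of
#' the pair is more recent than the MRCA of either member with any other
#' selected species. This guarantees that shared ancestry cancels within each
#' contrast.
#'
#' @param tree Rooted `phylo` tree.
#' @param pairs Data frame from [contrast_pairs()].
#' @return Data frame `pos`, `neg`, `valid`, `offending` (comma-separated
#'   selected species found inside the pair's clade).
#' @export
validate_psc_pairs <- function(tree, pairs) {
  .check_tree(tree)
  if (!nrow(pairs)) stop("need at least one contrast pair")
  selected <- c(pairs$pos, pairs$neg)
  .check_tips(tree, selected)
  if (anyDuplicated(selected))
    stop("species appear in more than one pair: ",
         paste(unique(selected[duplicated(selected)]), collapse = ", "))
  report <- pairs
  report$valid <- logical(nrow(pairs))
  report$offending <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    clade <- .clade_tips(tree, c(pairs$pos[i], pairs$neg[i]))
    off <- intersect(clade, setdiff(selected, c(pairs$pos[i], pairs$neg[i])))
    report$valid[i] <- length(off) == 0L
    report$offending[i] <- paste(sort(off), collapse = ",")
  }
  report
}

#' Build a training configuration from contrast pairs
#'
#' Species are ordered pair by pair, positive before negative, and the ±1
#' response vector follows that order, giving a balanced training set by
#' construction.
#'
#' @param pairs Data frame from [contrast_pairs()].
#' @return An `esl_config` object with fields `pairs`, `species`, `response`.
#' @export
training_configuration <- function(pairs) {
  species <- as.vector(rbind(pairs$pos, pairs$neg))
  if (anyDuplicated(species))
    stop("species appear more than once across pairs: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  structure(list(pairs = pairs, species = species,
                 response = rep(c(1, -1), nrow(pairs))),
            class = "esl_config")
}

#' @export
print.esl_config <- function(x, ...) {
  cat("esl_config: ", nrow(x$pairs), " contrast pair(s); species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate valid training configurations over pair slots
#'
#' Takes the Cartesian product of per-slot (positive x negative) choices and
#' keeps configurations whose pairs all pass [validate_psc_pairs()].
#' Ordering is deterministic: choices are sorted lexicographically by species
#' names within each slot, and slots vary slowest to fastest in input order.
#'
#' @param tree Rooted `phylo` tree.
#' @param slots List of slots, each `list(positive = ..., negative = ...)`.
#' @return List of `esl_config` objects.
#' @export
enumerate_combinations <- function(tree, slots) {
  .check_tree(tree)
  if (!length(slots)) stop("need at least one slot")
  choice_list <- lapply(slots, function(s) {
    if (!length(s$positive) || !length(s$negative))
      stop("slot with empty positive or negative choice set")
    if (length(intersect(s$positive, s$negative)))
      stop("slot positive and negative sets must be disjoint")
    ch <- expand.grid(neg = sort(s$negative), pos = sort(s$positive),
                      stringsAsFactors = FALSE)
    ch[order(ch$pos, ch$neg), c("pos", "neg")]
  })
  idx <- lapply(choice_list, function(ch) seq_len(nrow(ch)))
  grid <- rev(expand.grid(rev(idx)))
  configs <- list()
  for (r in seq_len(nrow(grid))) {
    pairs <- do.call(rbind, Map(function(ch, i) ch[i, , drop = FALSE],
                                choice_list, as.integer(grid[r, ])))
    rownames(pairs) <- NULL
    if (anyDuplicated(c(pairs$pos, pairs$neg))) next
    rep <- validate_psc_pairs(tree, pairs)
    if (all(rep$valid)) configs[[length(configs) + 1L]] <- training_configuration(pairs)
  }
  if (!length(configs))
    stop("no valid configuration can be formed from the given slots")
  configs
}

#' Sample a naive (non-PSC) training configuration
#'
#' Draws trait-positive and trait-negative species uniformly from a pool
#' without the paired-contrast constraint. Used to contrast PSC-designed
#' ensembles with phylogenetically naive ones.
#'
#' @param trait_table Named numeric vector of +1/-1 trait values.
#' @param n_pos,n_neg Numbers of positive and negative species to draw.
#' @param pool Candidate species (subset of `names(trait_table)`).
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @return An `esl_config` with `naive = TRUE`; "pairs" are an arbitrary
#'   positional pairing retained only for interface compatibility.
#' @export
sample_naive_configuration <- function(trait_table, n_pos, n_neg, pool, seed) {
  pool <- intersect(pool, names(trait_table))
  pos_pool <- sort(pool[trait_table[pool] > 0])
  neg_pool <- sort(pool[trait_table[pool] < 0])
  if (length(pos_pool) < n_pos || length(neg_pool) < n_neg)
    stop("insufficient species in pool: need ", n_pos, " positive and ", n_neg,
         " negative, have ", length(pos_pool), " and ", length(neg_pool))
  set.seed(seed)
  pos <- sort(sample(pos_pool, n_pos))
  neg <- sort(sample(neg_pool, n_neg))
  species <- c(rbind(pos[seq_len(min(n_pos, n_neg))], neg[seq_len(min(n_pos, n_neg))]))
  extra <- c(if (n_pos > n_neg) pos[(n_neg + 1):n_pos] else character(0),
             if (n_neg > n_pos) neg[(n_pos + 1):n_neg] else character(0))
  species <- c(species, extra)
  cfg <- structure(list(
    pairs = data.frame(pos = pos[seq_len(min(n_pos, n_neg))],
                       neg = neg[seq_len(min(n_pos, n_neg))],
                       stringsAsFactors = FALSE),
    species = species,
    response = unname(trait_table[species]),
    naive = TRUE), class = "esl_config")
  cfg
}

#' Rank alternative pair members by evolutionary proximity
#'
#' Convenience utility for choosing among interchangeable siblings: orders
#' candidate species by patristic distance to an anchor species (requires
#' branch lengths) and, optionally, by their gap count in an alignment.
#' Advisory only; pair validity itself is purely topological.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param anchor Species the candidates are compared against.
#' @param candidates Candidate species names.
#' @param aln Optional `esl_concat` used to count gaps/missing residues.
#' @return Data frame `species`, `distance`, `n_gaps`, sorted best first.
#' @export
rank_pair_candidates <- function(tree, anchor, candidates, aln = NULL) {
  .check_tree(tree)
  .check_tips(tree, c(anchor, candidates))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; distance ranking requires them")
  d <- ape::cophenetic.phylo(tree)[anchor, candidates]
  n_gaps <- rep(NA_integer_, length(candidates))
  if (!is.null(aln)) {
    bad <- .missing_chars(aln$alphabet)
    n_gaps <- vapply(candidates, function(sp)
      sum(aln$matrix[sp, ] %in% bad), integer(1))
  }
  out <- data.frame(species = candidates, distance = unname(d),
                    n_gaps = n_gaps, stringsAsFactors = FALSE)
  out[order(out$distance, out$n_gaps, out$species), , drop = FALSE]
}
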