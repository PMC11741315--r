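# Phylogenetic alignment simulator with implanted convergent and
# clade-confounded sites, plus bundled fixture/benchmark generators.
#
# Background sites evolve under the simplest symmetric single-rate
# substitution process (Jukes-Cantor-like over the chosen alphabet) from a
# random root sequence; designated sites are overwritten afterwards, so the
# ground truth is exact. The simulator emulates the structure of real
# comparative datasets (many loci, trait-positive/negative sibling pairs in
# independent clades, trait-correlated sites, clade-confounded sites, gaps
# and missing data), not evolutionary realism.

#' Build a simulation configuration
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param traits Named ±1 vector of true trait labels for every tip.
#' @param n_loci Number of loci to simulate.
#' @param sites_per_locus Integer, or length-2 range sampled uniformly per
#'   locus.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param convergent_sites Data frame `locus` (1-based index), `site`
#'   (1-based within locus), `residue`, `penetrance` in `[0, 1]`: each
#'   trait-positive tip receives the derived residue with probability
#'   penetrance, independently.
#' @param confound_sites Data frame `locus`, `site`, `residue`, `clade`
#'   (comma-separated tip names whose MRCA defines the clade): every tip in
#'   the clade receives the derived residue, regardless of trait.
#' @param gap_fraction,missing_fraction Fractions of non-designated cells
#'   replaced by gaps / missing symbols.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(tree, traits, n_loci = 6, sites_per_locus = 30,
                              substitution_rate = 0.4,
                              alphabet = c("protein", "nucleotide"),
                              convergent_sites = NULL, confound_sites = NULL,
                              gap_fraction = 0.02, missing_fraction = 0.01,
                              seed) {
  alphabet <- match.arg(alphabet)
  .check_tree(tree)
  if (is.null(tree$edge.length)) stop("simulation tree needs branch lengths")
  if (missing(seed)) stop("a seed is mandatory for simulation")
  if (!setequal(names(traits), tree$tip.label))
    stop("traits must label exactly the tree tips")
  if (!all(traits %in% c(-1, 1))) stop("traits must be +1 or -1")
  if (!is.null(convergent_sites) &&
      any(convergent_sites$penetrance < 0 | convergent_sites$penetrance > 1))
    stop("penetrance must lie in [0, 1]")
  for (df in list(convergent_sites, confound_sites)) {
    if (is.null(df)) next
    if (any(df$locus < 1 | df$locus > n_loci))
      stop("designated site references locus outside 1..n_loci")
  }
  structure(list(tree = tree, traits = traits, n_loci = n_loci,
                 sites_per_locus = sites_per_locus,
                 substitution_rate = substitution_rate, alphabet = alphabet,
                 convergent_sites = convergent_sites,
                 confound_sites = confound_sites,
                 gap_fraction = gap_fraction,
                 missing_fraction = missing_fraction, seed = seed),
            class = "sim_config")
}

# evolve one locus along the tree: symmetric single-rate substitutions,
# Poisson-distributed per branch
.evolve_locus <- function(tree, L, rate, core) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample(core, L, replace = TRUE)
  edges <- tree$edge
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  for (e in ord) {
    par <- edges[e, 1]; child <- edges[e, 2]
    s <- seqs[[par]]
    nsub <- stats::rpois(1, rate * tree$edge.length[e] * L)
    if (nsub > 0) {
      pos <- sample.int(L, nsub, replace = TRUE)
      for (p in pos) s[p] <- sample(setdiff(core, s[p]), 1)
    }
    seqs[[child]] <- s
  }
  tips <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(tips) <- tree$tip.label
  tips
}

#' Simulate per-locus alignments with known ground truth
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return List `alignments` (list of `esl_alignment`), `ground_truth`
#'   (designated-site tables with resolved species sets and the true trait
#'   labels), `traits` (named ±1 vector). Fully reproducible given the
#'   config seed.
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  core <- switch(config$alphabet, protein = .PROTEIN_CORE, nucleotide = .NT_CORE)
  miss_sym <- .missing_symbol(config$alphabet)
  tree <- config$tree
  spl <- config$sites_per_locus
  lens <- if (length(spl) == 2L)
    sample(seq.int(spl[1], spl[2]), config$n_loci, replace = TRUE)
  else rep(as.integer(spl), config$n_loci)
  locus_ids <- sprintf("L%02d", seq_len(config$n_loci))
  mats <- lapply(seq_len(config$n_loci), function(i)
    .evolve_locus(tree, lens[i], config$substitution_rate, core))
  designated <- matrix(FALSE, nrow = 0, ncol = 2)
  pos_tips <- names(config$traits)[config$traits > 0]
  cs <- config$convergent_sites
  if (!is.null(cs)) for (i in seq_len(nrow(cs))) {
    li <- cs$locus[i]; si <- cs$site[i]
    if (si > lens[li]) stop("convergent site beyond locus length")
    carriers <- pos_tips[stats::runif(length(pos_tips)) < cs$penetrance[i]]
    mats[[li]][carriers, si] <- cs$residue[i]
    designated <- rbind(designated, c(li, si))
  }
  fs <- config$confound_sites
  confound_resolved <- NULL
  if (!is.null(fs)) for (i in seq_len(nrow(fs))) {
    li <- fs$locus[i]; si <- fs$site[i]
    if (si > lens[li]) stop("confound site beyond locus length")
    clade_sp <- strsplit(fs$clade[i], ",", fixed = TRUE)[[1]]
    .check_tips(tree, clade_sp)
    tips <- if (length(clade_sp) > 1L) .clade_tips(tree, clade_sp) else clade_sp
    mats[[li]][tips, si] <- fs$residue[i]
    designated <- rbind(designated, c(li, si))
    confound_resolved <- rbind(confound_resolved,
      data.frame(locus = locus_ids[li], site = si, residue = fs$residue[i],
                 species = paste(tips, collapse = ","),
                 stringsAsFactors = FALSE))
  }
  # inject gaps and missing symbols, never on designated sites
  for (li in seq_len(config$n_loci)) {
    open <- setdiff(seq_len(lens[li]),
                    designated[designated[, 1] == li, 2])
    ncell <- length(tree$tip.label) * length(open)
    for (frac_sym in list(c(config$gap_fraction, "-"),
                          c(config$missing_fraction, miss_sym))) {
      frac <- as.numeric(frac_sym[1])
      if (frac <= 0 || !ncell) next
      n_inj <- round(frac * ncell)
      if (!n_inj) next
      cells <- sample.int(ncell, n_inj)
      rows <- (cells - 1L) %% length(tree$tip.label) + 1L
      cols <- open[(cells - 1L) %/% length(tree$tip.label) + 1L]
      mats[[li]][cbind(rows, cols)] <- frac_sym[2]
    }
  }
  alignments <- lapply(seq_len(config$n_loci), function(i) {
    seqs <- apply(mats[[i]], 1, paste, collapse = "")
    esl_alignment(locus_ids[i], seqs, config$alphabet)
  })
  names(alignments) <- locus_ids
  conv_resolved <- NULL
  if (!is.null(cs))
    conv_resolved <- data.frame(locus = locus_ids[cs$locus], site = cs$site,
                                residue = cs$residue,
                                penetrance = cs$penetrance,
                                stringsAsFactors = FALSE)
  list(alignments = alignments,
       ground_truth = list(convergent = conv_resolved,
                           confound = confound_resolved,
                           traits = config$traits),
       traits = config$traits)
}

# tree of `n_clades` training clades ((p.1,p.2),(n.1,n.2)) plus
# `n_heldout` held-out cherries (hp, hn), all on unit-ish branch lengths
.benchmark_tree <- function(n_clades, n_heldout, paired_siblings = TRUE) {
  clade <- if (paired_siblings) function(i)
    sprintf("((p%d_1:0.3,p%d_2:0.3):0.7,(n%d_1:0.3,n%d_2:0.3):0.7):1",
            i, i, i, i)
  else function(i) sprintf("(p%d_1:0.5,n%d_1:0.5):1", i, i)
  held <- function(i) sprintf("(hp%d:0.5,hn%d:0.5):1.2", i, i)
  parts <- c(vapply(seq_len(n_clades), clade, character(1)),
             vapply(seq_len(n_heldout), held, character(1)))
  # ladderize so the root is strictly bifurcating
  txt <- Reduce(function(acc, p) paste0("(", acc, ",", p, "):1", sep = ""), parts)
  ape::read.tree(text = paste0(sub(":1$", "", txt), ";"))
}

#' Generate a benchmark dataset with PSC structure
#'
#' Builds a tree of `n_clades` independent training clades — each holding
#' two trait-positive siblings and two trait-negative siblings, so pair
#' members are interchangeable — plus `n_heldout` held-out cherries of one
#' trait-positive and one trait-negative species. Convergent sites are
#' implanted across trait-positive tips at the given penetrance; optionally,
#' clade-confounded sites mark every species of the first training clade.
#'
#' @param seed Integer seed.
#' @param n_clades Training clades (default 4, giving 4 contrast pairs).
#' @param n_heldout Held-out cherries (default 2).
#' @param n_loci,sites_per_locus,substitution_rate,gap_fraction,missing_fraction
#'   Passed to [simulation_config()].
#' @param n_convergent Convergent sites, spread over the first
#'   `n_convergent_loci` loci.
#' @param n_convergent_loci Number of loci carrying convergent sites
#'   (default 2). When several loci carry interchangeable perfect signal the
#'   group penalty concentrates coefficients in one of them, so recovery
#'   experiments that score locus ranks typically implant into one locus.
#' @param penetrance Penetrance of each convergent site.
#' @param n_confound Clade-confounded sites (0 to disable), placed in the
#'   last locus over the first training clade.
#' @param paired_siblings If `TRUE` (default) each training clade holds two
#'   interchangeable siblings per trait state; if `FALSE` clades are plain
#'   positive/negative cherries, allowing more contrast pairs on small trees.
#' @return List `alignments`, `tree`, `traits`, `slots` (per-clade
#'   interchangeable pair members), `pairs` (the canonical first-choice
#'   pairs), `heldout` (species names), `ground_truth`.
#' @export
make_benchmark_dataset <- function(seed, n_clades = 4, n_heldout = 2,
                                   n_loci = 6, sites_per_locus = 30,
                                   substitution_rate = 0.4,
                                   n_convergent = 2, penetrance = 1,
                                   n_confound = 0, gap_fraction = 0.02,
                                   missing_fraction = 0.01,
                                   paired_siblings = TRUE,
                                   n_convergent_loci = 2) {
  tree <- .benchmark_tree(n_clades, n_heldout, paired_siblings)
  sib <- if (paired_siblings) 1:2 else 1L
  pos <- c(t(outer(seq_len(n_clades), sib, function(i, j) sprintf("p%d_%d", i, j))),
           sprintf("hp%d", seq_len(n_heldout)))
  traits <- stats::setNames(rep(-1, length(tree$tip.label)), tree$tip.label)
  traits[pos] <- 1
  n_sig <- max(1, min(n_convergent_loci, n_convergent, n_loci - 1))
  conv <- data.frame(locus = rep(seq_len(n_sig), length.out = n_convergent),
                     site = 3 + seq_len(n_convergent),
                     residue = rep(c("W", "H", "K", "F", "Y", "M"),
                                   length.out = n_convergent),
                     penetrance = penetrance, stringsAsFactors = FALSE)
  conf <- NULL
  if (n_confound > 0)
    conf <- data.frame(locus = n_loci,
                       site = 10 + seq_len(n_confound),
                       residue = rep(c("R", "E", "Q", "D", "N", "S"),
                                     length.out = n_confound),
                       clade = "p1_1,n1_1", stringsAsFactors = FALSE)
  cfg <- simulation_config(tree, traits, n_loci = n_loci,
                           sites_per_locus = sites_per_locus,
                           substitution_rate = substitution_rate,
                           convergent_sites = conv, confound_sites = conf,
                           gap_fraction = gap_fraction,
                           missing_fraction = missing_fraction, seed = seed)
  sim <- simulate_alignments(cfg)
  slots <- lapply(seq_len(n_clades), function(i)
    list(positive = sprintf("p%d_%d", i, sib),
         negative = sprintf("n%d_%d", i, sib)))
  names(slots) <- sprintf("slot%d", seq_len(n_clades))
  pairs <- contrast_pairs(sprintf("p%d_1", seq_len(n_clades)),
                          sprintf("n%d_1", seq_len(n_clades)))
  heldout <- c(sprintf("hp%d", seq_len(n_heldout)),
               sprintf("hn%d", seq_len(n_heldout)))
  list(alignments = sim$alignments, tree = tree, traits = sim$traits,
       slots = slots, pairs = pairs, heldout = heldout,
       ground_truth = sim$ground_truth)
}

#' Deterministic toy fixture
#'
#' An 8-leaf tree of three valid contrast pairs `(p1,n1)`, `(p2,n2)`,
#' `(p3,n3)` and a held-out cherry `(q1,q2)` with `q1` trait-positive; 3
#' protein loci of 20 sites; two convergent sites at penetrance 1 (loci L01
#' and L02) and two clade-confounded sites in L03 (one marking the `(p1,n1)`
#' clade, one the held-out cherry). Used throughout the unit tests and
#' documentation examples.
#'
#' @return The same structure as [make_benchmark_dataset()].
#' @export
make_toy_fixture <- function() {
  txt <- paste0("(((p1:0.5,n1:0.5):1,(p2:0.5,n2:0.5):1):1,",
                "((p3:0.5,n3:0.5):1,(q1:0.5,q2:0.5):1):1);")
  tree <- ape::read.tree(text = txt)
  traits <- stats::setNames(rep(-1, 8), tree$tip.label)
  traits[c("p1", "p2", "p3", "q1")] <- 1
  conv <- data.frame(locus = c(1L, 2L), site = c(5L, 10L),
                     residue = c("W", "H"), penetrance = 1,
                     stringsAsFactors = FALSE)
  conf <- data.frame(locus = c(3L, 3L), site = c(3L, 15L),
                     residue = c("K", "R"),
                     clade = c("p1,n1", "q1,q2"), stringsAsFactors = FALSE)
  cfg <- simulation_config(tree, traits, n_loci = 3, sites_per_locus = 20,
                           substitution_rate = 0.1, convergent_sites = conv,
                           confound_sites = conf, gap_fraction = 0.02,
                           missing_fraction = 0.01, seed = 20260901)
  sim <- simulate_alignments(cfg)
  pairs <- contrast_pairs(c("p1", "p2", "p3"), c("n1", "n2", "n3"))
  slots <- list(slot1 = list(positive = "p1", negative = "n1"),
                slot2 = list(positive = "p2", negative = "n2"),
                slot3 = list(positive = "p3", negative = "n3"))
  list(alignments = sim$alignments, tree = tree, traits = sim$traits,
       slots = slots, pairs = pairs, heldout = c("q1", "q2"),
       ground_truth = sim$ground_truth)
}
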