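# Independent reference implementations used as oracles. Kept deliberately
# simple and separate from the package's code paths.

# Reference minimizer of the sparse-group logistic objective: plain
# (unaccelerated) proximal gradient with a fixed conservative step, run to a
# tight tolerance.
oracle_sgl <- function(X, y, lam1, lam2, groups, gw, max_iter = 200000,
                       tol = 1e-12) {
  N <- nrow(X); p <- ncol(X)
  groups <- as.character(groups)
  glev <- unique(groups)
  gidx <- split(seq_len(p), factor(groups, levels = glev))
  Xa <- cbind(1, X)
  L <- max(eigen(tcrossprod(Xa), symmetric = TRUE, only.values = TRUE)$values) / (4 * N)
  t <- 0.9 / L
  b0 <- 0; b <- numeric(p)
  objective <- function(b0, b) {
    eta <- b0 + as.vector(X %*% b)
    z <- -y * eta
    loss <- mean(pmax(z, 0) + log1p(exp(-abs(z))))
    gn <- vapply(gidx, function(ix) sqrt(sum(b[ix]^2)), numeric(1))
    loss + lam1 * sum(abs(b)) + lam2 * sum(gw[glev] * gn)
  }
  obj <- objective(b0, b)
  for (it in seq_len(max_iter)) {
    eta <- b0 + as.vector(X %*% b)
    s <- -y / (1 + exp(y * eta))
    b0 <- b0 - t * mean(s)
    u <- b - t * as.vector(crossprod(X, s)) / N
    v <- sign(u) * pmax(abs(u) - t * lam1, 0)
    for (g in seq_along(gidx)) {
      ix <- gidx[[g]]
      nrm <- sqrt(sum(v[ix]^2))
      v[ix] <- if (nrm <= t * lam2 * gw[glev[g]]) 0 else
        v[ix] * (1 - t * lam2 * gw[glev[g]] / nrm)
    }
    b <- v
    if (it %% 200 == 0) {
      obj_new <- objective(b0, b)
      if (abs(obj - obj_new) <= tol * max(1, abs(obj))) break
      obj <- obj_new
    }
  }
  list(intercept = b0, beta = b, objective = objective(b0, b))
}

# MRCA via root paths, and pair validity straight from the definition: the
# pair's MRCA must be a strict descendant of the MRCA of either member with
# every other selected species.
oracle_pair_validity <- function(tree, pairs) {
  root_path <- function(tip_label) {
    node <- which(tree$tip.label == tip_label)
    path <- node
    repeat {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      if (!length(parent)) break
      path <- c(path, parent)
      node <- parent
    }
    path
  }
  mrca2 <- function(a, b) {
    pa <- root_path(a); pb <- root_path(b)
    pa[pa %in% pb][1]     # deepest shared ancestor
  }
  is_strict_descendant <- function(node, anc) {
    node != anc && anc %in% {
      path <- node
      while (TRUE) {
        parent <- tree$edge[tree$edge[, 2] == path[length(path)], 1]
        if (!length(parent)) break
        path <- c(path, parent)
      }
      path
    }
  }
  selected <- c(pairs$pos, pairs$neg)
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$pos[i]; b <- pairs$neg[i]
    m <- mrca2(a, b)
    others <- setdiff(selected, c(a, b))
    all(vapply(others, function(s)
      is_strict_descendant(m, mrca2(a, s)) &&
        is_strict_descendant(m, mrca2(b, s)), logical(1)))
  }, logical(1))
}

# Brute-force fourfold-degeneracy: substitute all four bases at the third
# position and translate each resulting codon.
oracle_fourfold <- function(concat, training) {
  sub <- concat$matrix[training, , drop = FALSE]
  mask <- logical(ncol(sub))
  gm <- concat$group_map
  for (i in seq_len(nrow(gm))) {
    for (c0 in seq.int(gm$start[i] + 1L, gm$end[i], by = 3L)) {
      b1 <- unique(sub[, c0]); b2 <- unique(sub[, c0 + 1L])
      if (length(b1) != 1L || length(b2) != 1L) next
      if (!b1 %in% c("A", "C", "G", "T") || !b2 %in% c("A", "C", "G", "T")) next
      aas <- vapply(c("A", "C", "G", "T"),
                    function(d) seqinr::translate(c(b1, b2, d)), character(1))
      mask[c0 + 2L] <- length(unique(aas)) == 1L
    }
  }
  mask
}

# Random small fitting problems for solver checks: binary indicator blocks
# grouped into loci, balanced +-1 response.
random_instance <- function(seed) {
  set.seed(seed)
  N <- 2 * sample(3:6, 1)                 # 6..12 species, balanced
  n_groups <- sample(2:5, 1)
  y <- rep(c(1, -1), N / 2)
  cols <- list(); groups <- character(0)
  p <- 0
  for (g in seq_len(n_groups)) {
    n_sites <- sample(1:3, 1)
    for (s in seq_len(n_sites)) {
      n_res <- sample(2:3, 1)             # residues at this site
      res <- sample(n_res, N, replace = TRUE)
      for (r in seq_len(n_res)) {
        cols[[length(cols) + 1]] <- as.numeric(res == r)
        groups <- c(groups, paste0("G", g))
      }
      p <- p + n_res
      if (p >= 30) break
    }
    if (p >= 30) break
  }
  X <- do.call(cbind, cols)
  keep <- colSums(X) > 0 & colSums(X) < N  # drop constant columns
  X <- X[, keep, drop = FALSE]
  groups <- groups[keep]
  v <- table(groups)                      # proxy variable-site counts
  gw <- as.numeric(v) + stats::median(as.numeric(v))
  names(gw) <- names(v)
  list(X = X, y = y, groups = groups, gw = gw)
}
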