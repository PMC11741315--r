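# Alignment ingestion, site filtering, one-hot encoding, and the
# fourfold-degenerate-site control.

.PROTEIN_CORE <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y")
.PROTEIN_AMBIG <- c("X", "B", "Z")
.NT_CORE <- c("A", "C", "G", "T")
.NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.GAP <- "-"

.alphabet_chars <- function(alphabet) {
  switch(alphabet,
    protein = c(.PROTEIN_CORE, .PROTEIN_AMBIG, .GAP),
    nucleotide = c(.NT_CORE, .NT_AMBIG, .GAP),
    stop("unknown alphabet: ", alphabet)
  )
}

# Gap and ambiguity symbols are treated alike as missing data when filtering
# training sites.
.missing_chars <- function(alphabet) {
  switch(alphabet,
    protein = c(.PROTEIN_AMBIG, .GAP),
    nucleotide = c(.NT_AMBIG, .GAP),
    stop("unknown alphabet: ", alphabet)
  )
}

.missing_symbol <- function(alphabet) {
  switch(alphabet, protein = "X", nucleotide = "N")
}

#' Construct a single-locus alignment object
#'
#' @param locus_id Locus identifier (typically the FASTA file stem).
#' @param sequences Named character vector of equal-length residue strings;
#'   names are species.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return An object of class `esl_alignment`.
#' @export
esl_alignment <- function(locus_id, sequences, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be a named character vector (names are species)")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L)
    stop("malformed alignment '", locus_id, "': unequal sequence lengths (",
         paste(unique(lens), collapse = ", "), ")")
  if (anyDuplicated(names(sequences)))
    stop("duplicate species record(s) in alignment '", locus_id, "': ",
         paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  allowed <- .alphabet_chars(alphabet)
  for (sp in names(sequences)) {
    chars <- strsplit(sequences[[sp]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad))
      stop("alphabet error in alignment '", locus_id, "', species '", sp,
           "': character '", chars[bad[1]], "' at position ", bad[1])
  }
  structure(
    list(locus_id = locus_id, sequences = sequences,
         length = unname(lens[1]), alphabet = alphabet),
    class = "esl_alignment"
  )
}

#' @export
print.esl_alignment <- function(x, ...) {
  cat("esl_alignment '", x$locus_id, "': ", length(x$sequences),
      " species x ", x$length, " ", x$alphabet, " sites\n", sep = "")
  invisible(x)
}

#' Read a directory of per-locus FASTA alignments
#'
#' Each FASTA file becomes one alignment; the locus identifier is the file
#' stem. Residues are uppercased and validated against the declared alphabet.
#'
#' @param path Directory containing FASTA files (`.fa`, `.fasta`, `.faa`,
#'   `.fna`, `.fas`).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A list of [esl_alignment()] objects, sorted by file name.
#' @export
read_alignment_dir <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!dir.exists(path)) stop("alignment directory does not exist: ", path)
  files <- sort(list.files(path, pattern = "\\.(fa|fasta|faa|fna|fas)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) {
    warning("no FASTA files found in ", path)
    return(list())
  }
  alns <- lapply(files, function(f) {
    recs <- seqinr::read.fasta(f, seqtype = "AA", as.string = TRUE, seqonly = FALSE)
    if (length(recs) < 2L)
      stop("alignment file '", basename(f), "' has fewer than 2 records")
    seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
    names(seqs) <- vapply(recs, function(r) attr(r, "name"), character(1))
    esl_alignment(tools::file_path_sans_ext(basename(f)), seqs, alphabet)
  })
  names(alns) <- vapply(alns, `[[`, character(1), "locus_id")
  alns
}

#' Concatenate per-locus alignments into one residue matrix
#'
#' Loci are laid out left to right in input order; a locus-to-column map uses
#' 0-based half-open intervals. Species absent from a locus are filled with
#' the alphabet's missing symbol.
#'
#' @param alignments List of [esl_alignment()] objects sharing one alphabet.
#' @param species Ordered character vector of species names (the row order).
#' @return An object of class `esl_concat` with fields `species`, `matrix`
#'   (character, rows = species, columns = sites), `group_map` (data frame
#'   `locus`, `start`, `end`) and `alphabet`.
#' @export
concatenate_alignments <- function(alignments, species) {
  if (!length(species)) stop("species list must be non-empty")
  if (anyDuplicated(species)) stop("species names must be unique")
  if (!length(alignments)) stop("need at least one alignment")
  alphabet <- alignments[[1]]$alphabet
  if (!all(vapply(alignments, `[[`, character(1), "alphabet") == alphabet))
    stop("all alignments must share one alphabet")
  miss <- .missing_symbol(alphabet)
  lens <- vapply(alignments, `[[`, numeric(1), "length")
  total <- sum(lens)
  mat <- matrix(miss, nrow = length(species), ncol = total,
                dimnames = list(species, NULL))
  start <- 0L
  gm <- data.frame(locus = character(0), start = integer(0), end = integer(0),
                   stringsAsFactors = FALSE)
  for (aln in alignments) {
    cols <- seq.int(start + 1L, start + aln$length)
    present <- intersect(species, names(aln$sequences))
    if (length(present)) {
      sub <- t(vapply(aln$sequences[present],
                      function(s) strsplit(s, "", fixed = TRUE)[[1]],
                      character(aln$length)))
      mat[present, cols] <- sub
    }
    gm <- rbind(gm, data.frame(locus = aln$locus_id, start = start,
                               end = start + aln$length, stringsAsFactors = FALSE))
    start <- start + as.integer(aln$length)
  }
  structure(list(species = species, matrix = mat, group_map = gm,
                 alphabet = alphabet),
            class = "esl_concat")
}

#' @export
print.esl_concat <- function(x, ...) {
  cat("esl_concat: ", length(x$species), " species x ", ncol(x$matrix),
      " sites over ", nrow(x$group_map), " loci (", x$alphabet, ")\n", sep = "")
  invisible(x)
}

.check_species <- function(aln, species) {
  unknown <- setdiff(species, aln$species)
  if (length(unknown))
    stop("species not present in alignment: ", paste(unknown, collapse = ", "))
}

#' Mask sites usable for a given training set
#'
#' A site is retained iff no training species carries a gap or a
#' missing/ambiguity symbol there. Held-out species may have gaps at retained
#' sites; only training rows are consulted.
#'
#' @param aln An `esl_concat`.
#' @param training_species Character vector of training species.
#' @return Logical vector over concatenated columns with a `provenance`
#'   attribute.
#' @export
filter_training_sites <- function(aln, training_species) {
  .check_species(aln, training_species)
  sub <- aln$matrix[training_species, , drop = FALSE]
  bad <- .missing_chars(aln$alphabet)
  mask <- colSums(matrix(sub %in% bad, nrow = length(training_species))) == 0L
  attr(mask, "provenance") <- "training-gap-filter"
  mask
}

#' One-hot encode training species over retained variable sites
#'
#' Each retained site contributes one indicator column per residue observed
#' among the training species at that site; sites monomorphic in training
#' contribute no columns (a constant column can never enter a penalized
#' model). Row blocks therefore sum to exactly 1 at every encoded site.
#'
#' @param aln An `esl_concat`.
#' @param training_species Character vector, row order of the result.
#' @param mask Site mask from [filter_training_sites()] on the same set.
#' @return An `esl_features` object: `X` (0/1 matrix, rows = training
#'   species), `feature_map` (data frame `column`, `locus`, `site` 0-based
#'   concatenated column, `residue`).
#' @export
one_hot_encode <- function(aln, training_species, mask) {
  .check_species(aln, training_species)
  stopifnot(length(mask) == ncol(aln$matrix))
  sub <- aln$matrix[training_species, , drop = FALSE]
  keep <- which(mask)
  locus_of <- .locus_of_column(aln$group_map, ncol(aln$matrix))
  cols <- vector("list", length(keep))
  maps <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    j <- keep[k]
    res <- sub[, j]
    uniq <- sort(unique(res))
    if (length(uniq) < 2L) next
    ind <- vapply(uniq, function(r) as.numeric(res == r),
                  numeric(length(training_species)))
    cols[[k]] <- ind
    maps[[k]] <- data.frame(locus = locus_of[j], site = j - 1L,
                            residue = uniq, stringsAsFactors = FALSE)
  }
  cols <- cols[!vapply(cols, is.null, logical(1))]
  maps <- maps[!vapply(maps, is.null, logical(1))]
  if (!length(cols))
    stop("no variable sites remain after filtering; check inputs ",
         "(training species, gaps/ambiguity, alignment content)")
  X <- do.call(cbind, cols)
  rownames(X) <- training_species
  fm <- do.call(rbind, maps)
  fm <- data.frame(column = seq_len(nrow(fm)), fm, stringsAsFactors = FALSE)
  rownames(fm) <- NULL
  colnames(X) <- paste0(fm$locus, ":", fm$site + 1L, ":", fm$residue)
  structure(list(X = X, feature_map = fm, alphabet = aln$alphabet),
            class = "esl_features")
}

#' @export
print.esl_features <- function(x, ...) {
  cat("esl_features: ", nrow(x$X), " training species x ", ncol(x$X),
      " indicator columns (", length(unique(x$feature_map$locus)), " loci, ",
      length(unique(x$feature_map$site)), " variable sites)\n", sep = "")
  invisible(x)
}

.locus_of_column <- function(group_map, ncol_total) {
  out <- character(ncol_total)
  for (i in seq_len(nrow(group_map)))
    out[(group_map$start[i] + 1L):group_map$end[i]] <- group_map$locus[i]
  out
}

#' Number of encoded variable sites per locus
#'
#' Counts, for each locus with at least one encoded column, the distinct
#' variable sites present in a feature map.
#'
#' @param features An `esl_features` object.
#' @return Named integer vector, locus -> variable-site count.
#' @export
variable_site_counts <- function(features) {
  fm <- unique(features$feature_map[, c("locus", "site")])
  tab <- table(fm$locus)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Encode any species into a trained model's feature space
#'
#' An indicator is 1 iff the species carries that residue at that site. A
#' residue unseen in training, a gap, or a missing symbol yields 0 across the
#' whole site block, so the site contributes nothing to the prediction score.
#'
#' @param aln An `esl_concat` containing the species.
#' @param species Single species name.
#' @param feature_map Feature map from [one_hot_encode()].
#' @return Numeric 0/1 vector aligned to the feature map columns.
#' @export
encode_for_prediction <- function(aln, species, feature_map) {
  .check_species(aln, species)
  res <- aln$matrix[species, feature_map$site + 1L]
  as.numeric(res == feature_map$residue)
}

# Dinucleotide codon families whose four third-position variants encode the
# same amino acid, derived from the standard genetic code.
.fourfold_prefixes <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      nts <- c("A", "C", "G", "T")
      pre <- character(0)
      for (a in nts) for (b in nts) {
        aas <- vapply(nts, function(d) seqinr::translate(c(a, b, d)), character(1))
        if (length(unique(aas)) == 1L) pre <- c(pre, paste0(a, b))
      }
      val <<- pre
    }
    val
  }
})

#' Mask fourfold-degenerate third codon positions
#'
#' For codon-aligned nucleotide data (reading frame starting at each locus's
#' first column), marks third codon positions where all training species have
#' identical, ungapped bases at positions 1 and 2 and that dinucleotide
#' prefix is fourfold degenerate under the standard genetic code. Restricting
#' an analysis to these near-neutral sites is a negative control: models
#' built from them should carry no trait signal.
#'
#' @param aln An `esl_concat` of nucleotide alignments.
#' @param training_species Character vector of training species.
#' @return Logical site mask with provenance `"fourfold-degenerate"`.
#' @export
fourfold_degenerate_mask <- function(aln, training_species) {
  if (aln$alphabet != "nucleotide")
    stop("fourfold-degenerate masking requires a nucleotide alignment")
  .check_species(aln, training_species)
  gm <- aln$group_map
  bad_len <- gm$locus[(gm$end - gm$start) %% 3L != 0L]
  if (length(bad_len))
    stop("locus length not divisible by 3 (frame error): ",
         paste(bad_len, collapse = ", "))
  sub <- aln$matrix[training_species, , drop = FALSE]
  mask <- logical(ncol(sub))
  ff <- .fourfold_prefixes()
  for (i in seq_len(nrow(gm))) {
    for (c0 in seq.int(gm$start[i] + 1L, gm$end[i], by = 3L)) {
      b1 <- unique(sub[, c0]); b2 <- unique(sub[, c0 + 1L])
      if (length(b1) == 1L && length(b2) == 1L &&
          b1 %in% .NT_CORE && b2 %in% .NT_CORE &&
          paste0(b1, b2) %in% ff)
        mask[c0 + 2L] <- TRUE
    }
  }
  attr(mask, "provenance") <- "fourfold-degenerate"
  mask
}

#' Export a feature map as a tab-separated table
#'
#' Writes columns `locus`, `site_1based` (position within the locus),
#' `residue`, `column_index`.
#'
#' @param features An `esl_features` object.
#' @param aln The `esl_concat` the features were built from.
#' @param path Output TSV path.
#' @export
write_feature_map <- function(features, aln, path) {
  fm <- features$feature_map
  gm <- aln$group_map
  start_of <- stats::setNames(gm$start, gm$locus)
  out <- data.frame(locus = fm$locus,
                    site_1based = fm$site - start_of[fm$locus] + 1L,
                    residue = fm$residue,
                    column_index = fm$column,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a species trait table
#'
#' Two tab-separated columns: species name and trait value (+1 or -1), no
#' header.
#'
#' @param path TSV path.
#' @return Named numeric vector of +1/-1 trait values.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("species", "trait"))
  if (!all(df$trait %in% c(-1, 1)))
    stop("trait values must be +1 or -1")
  stats::setNames(as.numeric(df$trait), df$species)
}

#' Write per-locus alignments to FASTA files
#'
#' @param alignments List of `esl_alignment` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_alignment_dir <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(alignments, function(a) {
    p <- file.path(dir, paste0(a$locus_id, ".fasta"))
    seqinr::write.fasta(as.list(a$sequences), names = names(a$sequences),
                        file.out = p, as.string = TRUE, nbchar = 80)
    p
  }, character(1))
  invisible(paths)
}
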