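# Reading, validating, partitioning and preprocessing protein sequence datasets.
#
# A dataset is a plain data.frame with columns
#   id          unique protein identifier (FASTA header token before whitespace)
#   sequence    upper-case string over the 20 standard amino acids
#   species     free-text species tag
#   label       1 = RBP, 0 = non-RBP, NA = unlabeled
#   description remainder of the FASTA header, "" when absent

#' The 20 standard amino acids
#'
#' One-letter codes in alphabetical order. This ordering is used for every
#' matrix column, PSSM profile and feature block in the package; mixing
#' orderings is the classic silent bug this constant prevents.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Clean a raw amino-acid string
#'
#' Enforces the 20-standard-residue alphabet. `drop_nonstandard` (the default)
#' silently removes every character outside the alphabet (including B, Z, X,
#' U, O and `*`); `map_to_X_then_drop` first maps nonstandard characters to X
#' and then drops all X; `reject` raises an error naming the first offending
#' character.
#'
#' @param raw Nonempty character scalar; case-insensitive.
#' @param policy One of `"drop_nonstandard"`, `"reject"`, `"map_to_X_then_drop"`.
#' @return Cleaned upper-case sequence.
#' @export
clean_sequence <- function(raw,
                           policy = c("drop_nonstandard", "reject",
                                      "map_to_X_then_drop")) {
  policy <- match.arg(policy)
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    stop("`raw` must be a nonempty character scalar")
  }
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  ok <- chars %in% aa_alphabet()
  if (policy == "reject") {
    if (!all(ok)) {
      stop(sprintf("nonstandard residue '%s' at position %d (policy 'reject')",
                   chars[which(!ok)[1L]], which(!ok)[1L]))
    }
    return(up)
  }
  # map_to_X_then_drop maps nonstandard -> X, then drops X; net effect on the
  # retained set is identical to drop_nonstandard, kept as a distinct policy
  # so callers can log how many residues were masked vs removed.
  cleaned <- paste0(chars[ok], collapse = "")
  if (!nzchar(cleaned)) {
    stop("sequence empty after cleaning (no standard residues present)")
  }
  cleaned
}

#' Read a protein FASTA file
#'
#' Parses a FASTA file into a protein dataset data.frame. The id is the
#' header token before the first whitespace; the remainder of the header is
#' kept as `description`. Sequences are upper-cased and passed through
#' [clean_sequence()] under `policy`.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag attached to every record.
#' @param policy Residue-cleaning policy, see [clean_sequence()].
#' @return data.frame with columns id, sequence, species, label, description.
#' @export
read_fasta <- function(path, species = NA_character_,
                       policy = c("drop_nonstandard", "reject",
                                  "map_to_X_then_drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning(sprintf("empty FASTA file: %s", path))
    return(empty_protein_set())
  }
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: line %d contains sequence data before any '>' header",
                 first))
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  cleaned <- vapply(as.character(seqs), clean_sequence, character(1L),
                    policy = policy, USE.NAMES = FALSE)
  data.frame(id = ids, sequence = cleaned,
             species = rep(species, length(ids)),
             label = NA_real_, description = desc,
             stringsAsFactors = FALSE)
}

empty_protein_set <- function() {
  data.frame(id = character(), sequence = character(), species = character(),
             label = numeric(), description = character(),
             stringsAsFactors = FALSE)
}

#' Write a protein dataset to FASTA
#'
#' Sequence lines are wrapped at 80 columns.
#'
#' @param records Protein dataset data.frame.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- ifelse(nzchar(records$description) & !is.na(records$description),
                     paste(records$id, records$description),
                     records$id)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a label manifest
#'
#' TSV with header columns `id`, `label`, `species`. Labels are merged onto
#' `records` by id when supplied.
#'
#' @param path Manifest path.
#' @param records Optional dataset to annotate; ids missing from the manifest
#'   keep `NA` labels, manifest ids absent from `records` raise an error.
#' @return The manifest data.frame, or the annotated dataset when `records`
#'   is given.
#' @export
read_manifest <- function(path, records = NULL) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "label", "species")
  if (!all(need %in% names(man))) {
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  }
  if (is.null(records)) return(man)
  extra <- setdiff(man$id, records$id)
  if (length(extra)) {
    stop(sprintf("manifest ids absent from dataset: %s",
                 paste(utils::head(extra, 5L), collapse = ", ")))
  }
  idx <- match(records$id, man$id)
  hit <- !is.na(idx)
  records$label[hit] <- man$label[idx[hit]]
  records$species[hit] <- man$species[idx[hit]]
  records
}

#' Write a label manifest
#'
#' @param records Protein dataset data.frame.
#' @param path Output TSV path.
#' @export
write_manifest <- function(records, path) {
  utils::write.table(records[, c("id", "label", "species")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Largest-remainder apportionment of n items over fractions
#'
#' Sizes are `floor(n * f)` plus one extra item per largest fractional
#' remainder until the sizes sum to `n`; remainder ties are broken toward the
#' earlier part (so toward the training part for split fractions).
#'
#' @param n Non-negative integer.
#' @param fractions Non-negative numeric vector summing to 1.
#' @return Integer vector of sizes summing to `n`.
#' @export
apportion <- function(n, fractions) {
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[take] <- sizes[take] + 1L
  }
  as.integer(sizes)
}

# Assign each element to one of length(fractions) parts, stratified by
# `strata`, such that the overall part sizes equal apportion(n, fractions)
# exactly and each stratum's part sizes are within one of its own
# apportionment (minimal transport repair between the two constraints).
stratified_assignment <- function(strata, fractions, seed) {
  n <- length(strata)
  target <- apportion(n, fractions)
  groups <- split(seq_len(n), strata)
  counts <- t(vapply(groups, function(ix) apportion(length(ix), fractions),
                     integer(length(fractions))))
  counts <- matrix(counts, nrow = length(groups))
  # repair column sums toward the overall target, moving from the stratum
  # whose cell is most over its exact share
  repeat {
    over <- which(colSums(counts) > target)
    if (length(over) == 0L) break
    j <- over[1L]
    k <- which(colSums(counts) < target)[1L]
    exact_j <- vapply(groups, length, integer(1L)) * fractions[j]
    cand <- which(counts[, j] > 0L)
    s <- cand[which.max(counts[cand, j] - exact_j[cand])]
    counts[s, j] <- counts[s, j] - 1L
    counts[s, k] <- counts[s, k] + 1L
  }
  assignment <- integer(n)
  with_seed(seed, {
    for (s in seq_along(groups)) {
      ix <- groups[[s]]
      ix <- ix[sample.int(length(ix))]
      parts <- rep.int(seq_along(fractions), counts[s, ])
      assignment[ix] <- parts
    }
  })
  assignment
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Split a dataset into train / validation / test parts
#'
#' Sizes follow largest-remainder apportionment of `nrow(records)` by
#' `fractions` (ties toward the training part). When labels are present the
#' split is stratified so each part's positive ratio matches the dataset's
#' within one record. Reproducible from `seed`.
#'
#' @param records Protein dataset data.frame (or any data.frame with an
#'   optional `label` column).
#' @param fractions Length-3 non-negative vector (train, validation, test)
#'   summing to 1.
#' @param seed Integer seed.
#' @return List of class `dataset_split` with elements `train`, `validation`,
#'   `test` and `fractions`.
#' @export
split_dataset <- function(records, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  if (nrow(records) == 0L) stop("cannot split an empty dataset")
  if (length(fractions) != 3L) stop("`fractions` must have length 3")
  strata <- if ("label" %in% names(records) && !all(is.na(records$label))) {
    ifelse(is.na(records$label), "NA", as.character(records$label))
  } else {
    rep("all", nrow(records))
  }
  part <- stratified_assignment(strata, fractions, seed)
  out <- list(train = records[part == 1L, , drop = FALSE],
              validation = records[part == 2L, , drop = FALSE],
              test = records[part == 3L, , drop = FALSE],
              fractions = fractions)
  class(out) <- "dataset_split"
  out
}

#' Split a feature matrix and label vector
#'
#' Matrix analogue of [split_dataset()] for featurized data: rows of `X` are
#' proteins, `y` the binary labels. Stratified, largest-remainder sizes,
#' reproducible.
#'
#' @param X Numeric matrix, one row per protein.
#' @param y Binary label vector, `length(y) == nrow(X)`.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test`, each a list `(X, y)`.
#' @export
split_xy <- function(X, y, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  stopifnot(nrow(X) == length(y))
  part <- stratified_assignment(as.character(y), fractions, seed)
  take <- function(p) list(X = X[part == p, , drop = FALSE], y = y[part == p])
  list(train = take(1L), validation = take(2L), test = take(3L),
       fractions = fractions)
}

#' Truncate over-length sequences
#'
#' Keeps the N-terminal prefix of at most `max_len` residues (genome-scale
#' screening preprocesses proteomes this way with `max_len = 6000`). Ids,
#' species and labels are unchanged; the number of truncated records is
#' reported via `message()`.
#'
#' @param records Protein dataset data.frame.
#' @param max_len Positive integer.
#' @return The dataset with truncated sequences.
#' @export
truncate_sequences <- function(records, max_len = 6000L) {
  if (max_len < 1L) stop("`max_len` must be >= 1")
  lens <- nchar(records$sequence)
  hit <- lens > max_len
  if (any(hit)) {
    records$sequence[hit] <- substr(records$sequence[hit], 1L, max_len)
    message(sprintf("truncated %d sequence(s) to %d residues (N-terminal prefix kept)",
                    sum(hit), max_len))
  }
  records
}

# k-mer set of a sequence; sequences shorter than k contribute themselves.
kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(seq)
  unique(substring(seq, 1:(L - k + 1L), k:L))
}

#' Greedy redundancy removal by approximate sequence identity
#'
#' Approximates identity-threshold clustering (as done with CD-HIT at 25%
#' identity for dataset construction) with a greedy longest-first pass over a
#' k-mer identity estimate: identity(a, b) = shared k-mers / k-mers of the
#' shorter sequence. A sequence joins the first existing cluster whose
#' representative it matches at `>= threshold`; otherwise it founds a new
#' cluster. The representative (the longest member; ties broken by id) of
#' each cluster is returned, so the result does not depend on input order.
#' This is a documented approximation, not a CD-HIT replication.
#'
#' @param records Protein dataset data.frame.
#' @param threshold Identity threshold in (0, 1].
#' @param k k-mer size for the identity estimate.
#' @return The retained representative records, in input order.
#' @export
dedup_by_identity <- function(records, threshold = 0.25, k = 3L) {
  if (threshold <= 0 || threshold > 1) stop("`threshold` must be in (0, 1]")
  if (nrow(records) <= 1L) return(records)
  message(sprintf(
    "dedup_by_identity: greedy %d-mer identity approximation at threshold %.2f (not CD-HIT)",
    k, threshold))
  ord <- order(-nchar(records$sequence), records$id)
  sets <- lapply(records$sequence[ord], kmer_set, k = k)
  reps <- integer(0)
  for (i in seq_along(ord)) {
    matched <- FALSE
    for (r in reps) {
      shared <- length(intersect(sets[[i]], sets[[r]]))
      ident <- shared / min(length(sets[[i]]), length(sets[[r]]))
      if (ident >= threshold) { matched <- TRUE; break }
    }
    if (!matched) reps <- c(reps, i)
  }
  keep <- sort(ord[reps])
  records[keep, , drop = FALSE]
}
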