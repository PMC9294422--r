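# Loader for externally produced protein language-model embeddings. The
# language models themselves (ProtT5-XL and kin) are never run here; their
# output is consumed as tables and presented through the same fixed-width
# feature contract as the hand-crafted encoders.

#' Load an embedding table
#'
#' Reads the TSV embedding dialect: header `id` followed by D numeric
#' columns. A file whose `id` column is unique is a per-protein table (one
#' D-vector per protein); repeated ids denote per-residue tables, in which
#' the rows of one id, in file order, are the residue vectors of that
#' protein.
#'
#' @param path TSV path.
#' @param source_name Name of the model that produced the embeddings,
#'   recorded on the table.
#' @return An `embedding_table`: list with `entries` (named list of numeric
#'   vectors or L x D matrices), `width`, `per_residue`, `source_name`.
#' @export
load_embeddings <- function(path, source_name = "unknown") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "id") stop("embedding TSV must start with an 'id' column")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    stop("embedding table has non-numeric or missing values (ragged widths?)")
  }
  D <- ncol(vals)
  per_residue <- anyDuplicated(df$id) > 0L
  entries <- if (per_residue) {
    lapply(split(seq_len(nrow(vals)), factor(df$id, levels = unique(df$id))),
           function(ix) vals[ix, , drop = FALSE])
  } else {
    stats::setNames(lapply(seq_len(nrow(vals)), function(i) vals[i, ]), df$id)
  }
  structure(list(entries = entries, width = D, per_residue = per_residue,
                 source_name = source_name),
            class = "embedding_table")
}

#' Write an embedding table
#'
#' Inverse of [load_embeddings()]; per-residue entries are written as one row
#' per residue with the id repeated.
#'
#' @param table An `embedding_table`, or a named list of vectors/matrices.
#' @param path Output TSV path.
#' @export
write_embeddings <- function(table, path) {
  entries <- if (inherits(table, "embedding_table")) table$entries else table
  mats <- lapply(entries, function(m) if (is.null(dim(m)))
    matrix(m, nrow = 1L) else m)
  ids <- rep(names(entries), vapply(mats, nrow, integer(1L)))
  df <- data.frame(id = ids, do.call(rbind, mats), check.names = FALSE,
                   row.names = NULL)
  names(df) <- c("id", paste0("e", seq_len(ncol(df) - 1L)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool a per-residue embedding into a per-protein representation
#'
#' @param entry L x D matrix (or a plain vector, treated as 1 x D).
#' @param mode `"mean"` (columnwise average), `"last"` (final residue row) or
#'   `"none"` (unchanged, for feeding the recurrent stack per residue).
#' @return Numeric vector (`mean`/`last`) or the L x D matrix (`none`).
#' @export
pool_residues <- function(entry, mode = c("mean", "last", "none")) {
  mode <- match.arg(mode)
  if (is.null(dim(entry))) entry <- matrix(entry, nrow = 1L)
  switch(mode,
         mean = colMeans(entry),
         last = entry[nrow(entry), ],
         none = entry)
}

#' Align an embedding table with a dataset
#'
#' Joins per-protein embeddings (pooling per-residue tables with `pool`)
#' to the given ids, erroring with the full list of missing ids.
#'
#' @param table An `embedding_table`.
#' @param ids Character vector of protein ids.
#' @param pool Pooling mode for per-residue tables, see [pool_residues()].
#' @return Numeric matrix `length(ids)` x D, rownames = ids.
#' @export
embeddings_to_matrix <- function(table, ids, pool = "mean") {
  missing <- setdiff(ids, names(table$entries))
  if (length(missing)) {
    stop(sprintf("ids missing from embedding table: %s",
                 paste(missing, collapse = ", ")))
  }
  m <- t(vapply(ids, function(id) pool_residues(table$entries[[id]], pool),
                numeric(table$width)))
  rownames(m) <- ids
  m
}
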