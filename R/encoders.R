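# Hand-crafted per-protein feature encoders: PSSM-400 (with BLOSUM62
# fallback), composition-transition-distribution (CTD), conjoint triad, and
# pseudo amino acid composition (PAAC). Every encoder emits a `feature_set`
# and every matrix column follows aa_alphabet() order.

feature_set <- function(protein_id, vector, encoder_name) {
  stopifnot(is.numeric(vector), all(is.finite(vector)))
  structure(list(protein_id = protein_id, vector = as.numeric(vector),
                 encoder_name = encoder_name, width = length(vector)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %s, width %d\n",
              x$protein_id, x$encoder_name, x$width))
  invisible(x)
}

pssm_profile <- function(protein_id, matrix, source) {
  stopifnot(ncol(matrix) == 20L, all(is.finite(matrix)))
  colnames(matrix) <- aa_alphabet()
  structure(list(protein_id = protein_id, matrix = matrix, source = source),
            class = "pssm_profile")
}

# BLOSUM62 subset to the 20 standard residues, alphabetical order both ways.
blosum62_20 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[aa_alphabet(), aa_alphabet()]
    }
    cache
  }
})

#' BLOSUM62 fallback profile
#'
#' When no PSI-BLAST PSSM is available for a protein, its profile is the
#' BLOSUM62 substitution-score rows of its residues: row t of the L x 20
#' matrix is the BLOSUM62 row of the residue at position t, columns in
#' alphabetical amino-acid order.
#'
#' @param sequence Cleaned amino-acid string.
#' @param protein_id Identifier stored in the profile.
#' @return A `pssm_profile` with `source = "blosum62_fallback"`.
#' @export
blosum62_profile <- function(sequence, protein_id = "protein") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, aa_alphabet())
  if (length(bad)) stop(sprintf("nonstandard residue(s): %s",
                                paste(bad, collapse = ", ")))
  m <- blosum62_20()[chars, , drop = FALSE]
  rownames(m) <- NULL
  pssm_profile(protein_id, m, "blosum62_fallback")
}

#' Read a PSSM profile file
#'
#' Auto-detects two dialects: the PSI-BLAST ASCII profile layout (header
#' lines, then one row per residue with position index, residue letter and at
#' least 20 integer score columns, of which the first 20 are taken) and a
#' plain whitespace-delimited L x 20 numeric matrix. PSI-BLAST score columns
#' are in PSI-BLAST residue order (ARNDCQEGHILKMFPSTWYV) and are reordered to
#' alphabetical; plain matrices are assumed already alphabetical.
#'
#' @param path Profile path.
#' @param protein_id Identifier stored in the profile.
#' @return A `pssm_profile` with `source = "psiblast"`.
#' @export
read_pssm <- function(path, protein_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1L]])
  is_psiblast <- any(vapply(toks, function(t) {
    length(t) >= 22L && grepl("^[0-9]+$", t[1L]) && t[2L] %in% aa_alphabet()
  }, logical(1L)))
  if (is_psiblast) {
    rows <- Filter(function(t) length(t) >= 22L && grepl("^[0-9]+$", t[1L]) &&
                     t[2L] %in% aa_alphabet(), toks)
    m <- t(vapply(rows, function(t) as.numeric(t[3:22]), numeric(20L)))
    psiblast_order <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1L]]
    m <- m[, match(aa_alphabet(), psiblast_order), drop = FALSE]
  } else {
    rows <- Filter(function(t) length(t) == 20L &&
                     !anyNA(suppressWarnings(as.numeric(t))), toks)
    if (length(rows) == 0L) stop(sprintf("unrecognized PSSM dialect: %s", path))
    m <- t(vapply(rows, as.numeric, numeric(20L)))
  }
  pssm_profile(protein_id, m, "psiblast")
}

#' Write a PSSM profile as a plain matrix file
#'
#' @param pssm A `pssm_profile`.
#' @param path Output path (whitespace-delimited L x 20 matrix, alphabetical
#'   column order).
#' @export
write_pssm <- function(pssm, path) {
  utils::write.table(pssm$matrix, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' PSSM-400 evolutionary feature
#'
#' Collapses an L x 20 PSSM profile into a fixed 400-dimensional vector: for
#' each residue type a, the 20-wide block for a is the elementwise sum of the
#' profile rows at positions where the sequence has residue a (a zero block
#' when a is absent); the 20 blocks are concatenated in alphabetical order.
#'
#' @param pssm A `pssm_profile` with `nrow == nchar(sequence)`.
#' @param sequence The protein sequence the profile belongs to.
#' @return `feature_set` of width 400.
#' @export
encode_pssm400 <- function(pssm, sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (nrow(pssm$matrix) != length(chars)) {
    stop(sprintf("PSSM has %d rows but sequence has %d residues",
                 nrow(pssm$matrix), length(chars)))
  }
  f <- factor(chars, levels = aa_alphabet())
  sums <- rowsum(pssm$matrix, f)                 # one row per residue present
  block <- matrix(0, nrow = 20L, ncol = 20L, dimnames = list(aa_alphabet(), NULL))
  block[rownames(sums), ] <- sums
  feature_set(pssm$protein_id, as.numeric(t(block)), "pssm400")
}

# --- CTD: 7 physicochemical properties, 3 classes each (Dubchak lineage) ----

ctd_groups <- list(
  hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  polarity = c("LIFWCMVY", "PATGS", "HQRKNED"),
  vdw_volume = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondary_structure = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_accessibility = c("ALFCGIVW", "RKQEND", "MSPTHY")
)

ctd_class_string <- function(chars, groups3) {
  cls <- integer(length(chars))
  for (g in 1:3) cls[chars %in% strsplit(groups3[g], "")[[1L]]] <- g
  cls
}

# Occurrence index for the distribution descriptor: the spec'd percentile
# convention is round-half-up of frac*count, floored at 1.
ctd_occurrence_index <- function(frac, count) max(1L, floor(frac * count + 0.5))

#' Composition-transition-distribution (CTD) feature
#'
#' For each physicochemical property the residues map into 3 classes
#' (polar/neutral/hydrophobic style groupings for hydrophobicity, polarity,
#' normalized van der Waals volume, polarizability, charge,
#' secondary-structure propensity and solvent-accessibility propensity; the
#' structure/accessibility groupings are residue propensity classes, no
#' structure predictor is run). Per property the descriptor is
#' composition (3 class frequencies), transition (3 adjacent-pair
#' class-change frequencies over L-1 pairs) and distribution (for each class
#' the sequence position, as percent of L, of its first, 25%, 50%, 75% and
#' 100% occurrence; 0 for absent classes). Width `7 * (3 + 3 + 15) = 147`
#' with all seven properties active.
#'
#' @param sequence Cleaned amino-acid string, length >= 1.
#' @param protein_id Identifier.
#' @param properties Names of the active property groupings.
#' @return `feature_set` of width `21 * length(properties)`.
#' @export
encode_ctd <- function(sequence, protein_id = "protein",
                       properties = names(ctd_groups)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 1L) stop("empty sequence")
  stopifnot(all(properties %in% names(ctd_groups)))
  out <- numeric(0)
  for (p in properties) {
    cls <- ctd_class_string(chars, ctd_groups[[p]])
    comp <- tabulate(cls, 3L) / L
    trans <- numeric(3L)
    if (L >= 2L) {
      a <- cls[-L]; b <- cls[-1L]
      pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
      for (i in 1:3) {
        trans[i] <- sum((a == pairs[i, 1L] & b == pairs[i, 2L]) |
                        (a == pairs[i, 2L] & b == pairs[i, 1L])) / (L - 1L)
      }
    }
    dist <- numeric(15L)
    for (g in 1:3) {
      pos <- which(cls == g)
      if (length(pos)) {
        idx <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                      function(fr) if (fr == 0) 1L else
                        ctd_occurrence_index(fr, length(pos)), numeric(1L))
        dist[(g - 1L) * 5L + 1:5] <- 100 * pos[idx] / L
      }
    }
    out <- c(out, comp, trans, dist)
  }
  feature_set(protein_id, out, paste0("ctd[", length(properties), "]"))
}

# --- Conjoint triad ---------------------------------------------------------

# Seven residue classes by dipole and side-chain volume (Shen et al. lineage).
conjoint_classes <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")

conjoint_class_of <- function(chars) {
  cls <- integer(length(chars))
  for (g in seq_along(conjoint_classes)) {
    cls[chars %in% strsplit(conjoint_classes[g], "")[[1L]]] <- g
  }
  cls
}

#' Conjoint triad feature
#'
#' Residues map into 7 classes clustering dipole and side-chain volume (so
#' charge and polarity of the side chain are what the encoding captures);
#' the feature counts all `7^3 = 343` class triads over the L-2 sliding
#' windows. By default counts are normalized by the maximum count (the
#' all-zero guard leaves an all-zero vector untouched); raw counts are
#' returned with `normalize = FALSE` since normalization conventions vary.
#'
#' @param sequence Cleaned amino-acid string of length >= 3.
#' @param protein_id Identifier.
#' @param normalize Divide by the maximum count (default) or keep raw counts.
#' @return `feature_set` of width 343; entry index of triad (a, b, c) is
#'   `(a-1)*49 + (b-1)*7 + c`.
#' @export
encode_conjoint_triad <- function(sequence, protein_id = "protein",
                                  normalize = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L < 3L) stop("conjoint triad requires sequence length >= 3")
  cls <- conjoint_class_of(chars)
  a <- cls[1:(L - 2L)]; b <- cls[2:(L - 1L)]; c_ <- cls[3:L]
  idx <- (a - 1L) * 49L + (b - 1L) * 7L + c_
  counts <- tabulate(idx, 343L)
  v <- if (normalize && max(counts) > 0) counts / max(counts) else counts
  feature_set(protein_id, v, if (normalize) "conjoint_triad" else
    "conjoint_triad_raw")
}

# --- PAAC -------------------------------------------------------------------

# Hydrophobicity, hydrophilicity and side-chain mass of the 20 residues
# (classic published tables of the pseudo amino acid composition method),
# alphabetical order.
paac_properties <- local({
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  hydrophobicity <- c(0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38,
                      -1.50, 1.06, 0.64, -0.78, 0.12, -0.85, -2.53, -0.18,
                      -0.05, 1.08, 0.81, 0.26)
  hydrophilicity <- c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
                      -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3)
  mass <- c(15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
            75, 58, 42, 72, 101, 31, 45, 43, 130, 107)
  norm <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  m <- rbind(norm(hydrophobicity), norm(hydrophilicity), norm(mass))
  colnames(m) <- aa
  m
})

#' Pseudo amino acid composition (type 1)
#'
#' The 20 amino-acid frequencies augmented with `lam` sequence-order
#' correlation factors. The tier-k factor is the average over all position
#' pairs (i, i+k) of the mean squared difference of three standardized
#' residue properties (hydrophobicity, hydrophilicity, side-chain mass).
#' All `20 + lam` entries are normalized by
#' `sum(frequencies) + weight * sum(correlation factors)`.
#' With `lam = 0` this is plain amino-acid composition. Defaults `lam = 30`,
#' `weight = 0.05` are the method's conventional defaults and are recorded in
#' `encoder_name`.
#'
#' @param sequence Cleaned amino-acid string with `nchar(sequence) > lam`.
#' @param protein_id Identifier.
#' @param lam Number of correlation tiers (non-negative integer).
#' @param weight Weight of the correlation factors (positive).
#' @return `feature_set` of width `20 + lam`.
#' @export
encode_paac <- function(sequence, protein_id = "protein", lam = 30L,
                        weight = 0.05) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  if (L <= lam) stop(sprintf("PAAC requires length > lam (L = %d, lam = %d)",
                             L, lam))
  if (weight <= 0) stop("`weight` must be positive")
  props <- paac_properties[, chars, drop = FALSE]          # 3 x L
  theta <- numeric(lam)
  if (lam > 0) {
    for (k in seq_len(lam)) {
      d <- props[, 1:(L - k), drop = FALSE] - props[, (1 + k):L, drop = FALSE]
      theta[k] <- mean(colMeans(d^2))
    }
  }
  freq <- tabulate(factor(chars, levels = aa_alphabet()), 20L) / L
  denom <- sum(freq) + weight * sum(theta)
  v <- c(freq, weight * theta) / denom
  feature_set(protein_id, v, sprintf("paac[lam=%d,w=%g]", lam, weight))
}

#' Concatenate feature sets of one protein
#'
#' @param parts List of `feature_set`s sharing one `protein_id`.
#' @return A `feature_set` whose vector is the concatenation in the given
#'   order and whose `encoder_name` records the recipe.
#' @export
concat_features <- function(parts) {
  stopifnot(length(parts) >= 1L)
  ids <- vapply(parts, `[[`, character(1L), "protein_id")
  if (length(unique(ids)) != 1L) {
    stop(sprintf("protein_id mismatch: %s", paste(unique(ids), collapse = " vs ")))
  }
  feature_set(ids[1L],
              unlist(lapply(parts, `[[`, "vector"), use.names = FALSE),
              paste(vapply(parts, `[[`, character(1L), "encoder_name"),
                    collapse = "+"))
}

#' Known encoder recipes
#'
#' The three composite schemes used in the hand-crafted-feature comparison
#' plus the individual encoders.
#'
#' @return Named list mapping recipe name to its encoder components.
#' @export
feature_recipes <- function() {
  list("pssm400+ctd+triad" = c("pssm400", "ctd", "triad"),
       "ctd+triad" = c("ctd", "triad"),
       "pssm400+ctd+paac" = c("pssm400", "ctd", "paac"),
       "pssm400" = "pssm400", "ctd" = "ctd", "triad" = "triad",
       "paac" = "paac")
}

#' Encode a dataset with a named recipe
#'
#' Applies a [feature_recipes()] recipe to every record. PSSM-based recipes
#' look profiles up in `pssms` (a named list of `pssm_profile`s keyed by
#' protein id); proteins without a profile fall back to [blosum62_profile()]
#' with a warning, mirroring the PSI-BLAST fallback rule.
#'
#' @param records Protein dataset data.frame.
#' @param recipe Recipe name, see [feature_recipes()].
#' @param pssms Optional named list of `pssm_profile`s.
#' @param paac_lam,paac_weight PAAC parameters for recipes containing PAAC.
#' @return Numeric matrix, one row per protein (rownames = ids).
#' @export
encode_recipe <- function(records, recipe, pssms = NULL, paac_lam = 30L,
                          paac_weight = 0.05) {
  recipes <- feature_recipes()
  if (!recipe %in% names(recipes)) {
    stop(sprintf("unknown recipe '%s'; known recipes: %s", recipe,
                 paste(names(recipes), collapse = ", ")))
  }
  comps <- recipes[[recipe]]
  if ("pssm400" %in% comps && is.null(pssms)) {
    warning("no PSSM profiles supplied; using the BLOSUM62 fallback profile")
  }
  one <- function(i) {
    id <- records$id[i]; s <- records$sequence[i]
    parts <- lapply(comps, function(comp) {
      switch(comp,
        pssm400 = {
          prof <- if (!is.null(pssms) && id %in% names(pssms)) pssms[[id]]
                  else blosum62_profile(s, id)
          encode_pssm400(prof, s)
        },
        ctd = encode_ctd(s, id),
        triad = encode_conjoint_triad(s, id),
        paac = encode_paac(s, id, lam = paac_lam, weight = paac_weight))
    })
    concat_features(parts)$vector
  }
  m <- t(vapply(seq_len(nrow(records)), one,
                numeric(length(one(1L)))))
  rownames(m) <- records$id
  m
}

#' Write a feature matrix as wide TSV
#'
#' @param X Feature matrix with protein ids as rownames.
#' @param path Output path (columns `id`, `f1..fD`).
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  names(df) <- c("id", paste0("f", seq_len(ncol(X))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
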