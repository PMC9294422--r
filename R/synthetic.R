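# Synthetic-data generators: domain-shifted labeled embedding datasets (the
# transfer-learning testbed), composition-biased toy sequences, and random
# PSSM profiles. All generators are pure functions of their spec + seed.

#' Specification of one synthetic embedding domain
#'
#' A domain emulates one labeled embedding dataset (e.g. the annotated
#' pre-training set or one species-specific set): labels are
#' Bernoulli(`pos_ratio`), features are `mu_y + sigma * noise` where the
#' class-mean difference `mu_1 - mu_0` has length `delta` along a unit
#' direction obtained by rotating the reference direction (first coordinate
#' axis) by `theta` within the fixed plane of the first two coordinates.
#' `theta` is the domain-shift knob: domains sharing a rotation share their
#' discriminative direction.
#'
#' @param name Domain name.
#' @param n_samples Number of proteins.
#' @param pos_ratio Positive fraction, default `1/11` (the ~1:10 RBP
#'   imbalance).
#' @param dim Embedding width D (>= 2).
#' @param delta Class-mean separation (effect size).
#' @param theta Rotation angle in `[0, pi/2]` relative to the reference
#'   domain.
#' @param sigma Isotropic Gaussian noise scale.
#' @param seed Integer seed.
#' @return List of class `domain_spec`.
#' @export
domain_spec <- function(name, n_samples, pos_ratio = 1 / 11, dim = 16L,
                        delta = 2.0, theta = 0, sigma = 1.0, seed = 1L) {
  stopifnot(pos_ratio > 0, pos_ratio < 1, dim >= 2L, theta >= 0,
            theta <= pi / 2, sigma > 0, n_samples >= 0L)
  structure(list(name = name, n_samples = n_samples, pos_ratio = pos_ratio,
                 dim = dim, delta = delta, theta = theta, sigma = sigma,
                 seed = seed),
            class = "domain_spec")
}

#' Generate one labeled embedding domain
#'
#' @param spec A [domain_spec()].
#' @return List with `X` (n x D matrix, rownames = synthetic protein ids),
#'   `y` (binary labels) and `spec`.
#' @export
gen_embedding_domain <- function(spec) {
  n <- spec$n_samples; D <- spec$dim
  u <- c(cos(spec$theta), sin(spec$theta), rep(0, D - 2L))
  with_seed(spec$seed, {
    y <- stats::rbinom(n, 1L, spec$pos_ratio)
    X <- matrix(stats::rnorm(n * D, sd = spec$sigma), n, D)
    X <- X + outer(y, spec$delta * u)
    rownames(X) <- sprintf("%s_%05d", spec$name, seq_len(max(n, 0L)))
    list(X = X, y = y, spec = spec)
  })
}

#' Default transfer-learning benchmark
#'
#' One large pre-training domain plus four species domains mirroring the
#' 1 + 4 layout (two data-rich "eukaryote-like" species sharing a small
#' rotation, two data-poor "prokaryote-like" species sharing a large one),
#' desk-scaled: pretrain n = 5000 at theta = 0; species A and B n = 600 at
#' theta = 0.15; species C n = 300 and D n = 200 at theta = 0.45; all with
#' pos_ratio 1/11, D = 16, delta = 2, sigma = 1.
#'
#' @param seed Integer seed; each domain derives its own sub-seed from it.
#' @return List with `pretrain` (one domain) and `species` (named list of 4
#'   domains), each as returned by [gen_embedding_domain()].
#' @export
gen_transfer_benchmark <- function(seed = 1L) {
  specs <- list(
    pretrain = domain_spec("pretrain", 5000L, theta = 0, seed = seed * 10L + 1L),
    A = domain_spec("A", 600L, theta = 0.15, seed = seed * 10L + 2L),
    B = domain_spec("B", 600L, theta = 0.15, seed = seed * 10L + 3L),
    C = domain_spec("C", 300L, theta = 0.45, seed = seed * 10L + 4L),
    D = domain_spec("D", 200L, theta = 0.45, seed = seed * 10L + 5L))
  doms <- lapply(specs, gen_embedding_domain)
  list(pretrain = doms$pretrain, species = doms[c("A", "B", "C", "D")])
}

#' Split a generated domain into a featurized train/validation/test split
#'
#' @param domain Output of [gen_embedding_domain()].
#' @param fractions Split fractions, default the 81/9/10 layout.
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` (each `list(X, y)`).
#' @export
split_domain <- function(domain, fractions = c(0.81, 0.09, 0.10), seed = 1L) {
  split_xy(domain$X, domain$y, fractions, seed)
}

#' Generate labeled toy sequences with class-dependent composition bias
#'
#' Negatives draw residues from a uniform background; positives from the
#' background perturbed by `class_bias`, a named vector of additive
#' probability mass per residue (normalized internally). The default biases
#' glutamate, serine and proline upward, echoing the residue preferences of
#' human RBPs.
#'
#' @param n Number of sequences.
#' @param length_range Inclusive (min, max) sequence lengths, drawn
#'   uniformly.
#' @param class_bias Named numeric vector over a subset of [aa_alphabet()];
#'   zero bias makes classes indistinguishable.
#' @param pos_ratio Positive fraction.
#' @param seed Integer seed.
#' @param species Species tag.
#' @return Protein dataset data.frame with labels.
#' @export
gen_sequences <- function(n, length_range = c(50L, 300L),
                          class_bias = c(E = 0.05, S = 0.05, P = 0.05),
                          pos_ratio = 0.5, seed = 1L, species = "synthetic") {
  if (n == 0L) return(empty_protein_set())
  stopifnot(all(names(class_bias) %in% aa_alphabet()))
  bg <- stats::setNames(rep(1 / 20, 20L), aa_alphabet())
  pos_p <- bg
  pos_p[names(class_bias)] <- pos_p[names(class_bias)] + class_bias
  pos_p <- pos_p / sum(pos_p)
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, pos_ratio)
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      p <- if (y[i] == 1L) pos_p else bg
      paste0(sample(aa_alphabet(), lens[i], replace = TRUE, prob = p),
             collapse = "")
    }, character(1L))
    data.frame(id = sprintf("syn_%05d", seq_len(n)), sequence = seqs,
               species = species, label = as.numeric(y), description = "",
               stringsAsFactors = FALSE)
  })
}

#' Generate a random PSSM profile for a sequence
#'
#' Integer-like L x 20 scores from a discretized normal, with the column of
#' the true residue elevated at every position (a diagonal-favoring profile,
#' as real evolutionary profiles are).
#'
#' @param sequence Cleaned amino-acid string.
#' @param seed Integer seed.
#' @param protein_id Identifier.
#' @param boost Score added to the true residue's column; the default keeps
#'   it strictly above every other entry of its row.
#' @return A `pssm_profile` with `source = "synthetic"`.
#' @export
gen_pssm <- function(sequence, seed = 1L, protein_id = "protein", boost = 11L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  with_seed(seed, {
    m <- matrix(pmax(-5, pmin(5, round(stats::rnorm(L * 20L, 0, 2)))), L, 20L)
    idx <- cbind(seq_len(L), match(chars, aa_alphabet()))
    m[idx] <- m[idx] + boost
    pssm_profile(protein_id, m, "synthetic")
  })
}
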