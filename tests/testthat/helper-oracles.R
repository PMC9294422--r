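# Independent brute-force oracles. Each is written as a naive loop (or a
# closed form) that shares no code with the package implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste0(sample(AA, len, TRUE), collapse = "")

# --- metrics ----------------------------------------------------------------

oracle_bce <- function(y, p, w = 1, eps = 1e-7) {
  total <- 0
  for (i in seq_along(y)) {
    pi <- min(max(p[i], eps), 1 - eps)
    total <- total + if (y[i] == 1) -w * log(pi) else -log(1 - pi)
  }
  total / length(y)
}

oracle_confusion <- function(y, p, thr) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y)) {
    pos <- p[i] >= thr
    if (pos && y[i] == 1) tp <- tp + 1L
    if (pos && y[i] == 0) fp <- fp + 1L
    if (!pos && y[i] == 1) fn <- fn + 1L
    if (!pos && y[i] == 0) tn <- tn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_auc_pairs <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  wins <- ties <- 0
  for (a in pos) for (b in neg) {
    if (a > b) wins <- wins + 1 else if (a == b) ties <- ties + 1
  }
  (wins + ties / 2) / (length(pos) * length(neg))
}

oracle_auprc_thresholds <- function(y, p) {
  thr <- sort(unique(p), decreasing = TRUE)
  area <- 0; r_prev <- 0
  for (t in thr) {
    pred <- p >= t
    prec <- sum(pred & y == 1) / sum(pred)
    rec <- sum(pred & y == 1) / sum(y == 1)
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# MCC as the Pearson correlation of label and prediction indicator vectors.
oracle_mcc_correlation <- function(y, pred) {
  if (stats::sd(y) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(y, pred)
}

# --- GRU --------------------------------------------------------------------

# Scalar-by-scalar evaluation of the four cell equations.
oracle_gru_cell <- function(x_t, h_prev, layer) {
  H <- length(h_prev)
  sig <- function(a) 1 / (1 + exp(-a))
  h_new <- numeric(H)
  z <- r <- cand <- numeric(H)
  for (j in 1:H) {
    az <- layer$b_z[j]; ar <- layer$b_r[j]
    v <- c(h_prev, x_t)
    for (k in seq_along(v)) {
      az <- az + layer$W_z[j, k] * v[k]
      ar <- ar + layer$W_r[j, k] * v[k]
    }
    z[j] <- sig(az); r[j] <- sig(ar)
  }
  for (j in 1:H) {
    ac <- layer$b[j]
    u <- c(r * h_prev, x_t)
    for (k in seq_along(u)) ac <- ac + layer$W[j, k] * u[k]
    cand[j] <- tanh(ac)
  }
  for (j in 1:H) h_new[j] <- (1 - z[j]) * h_prev[j] + z[j] * cand[j]
  h_new
}

# Full forward pass composed from the scalar cell oracle plus a hand-rolled
# eval-mode discriminator.
oracle_forward_eval <- function(inputs, params) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, nrow = 1)
  seq_x <- inputs
  for (layer in params$layers) {
    H <- length(layer$b_z)
    h <- rep(0, H)
    out <- matrix(0, nrow(seq_x), H)
    for (t in seq_len(nrow(seq_x))) {
      h <- oracle_gru_cell(seq_x[t, ], h, layer)
      out[t, ] <- h
    }
    seq_x <- out
  }
  h <- seq_x[nrow(seq_x), ]
  d <- params$disc
  u <- as.numeric(d$W1 %*% h) + d$b1
  uhat <- (u - d$run_mean) / sqrt(d$run_var + params$bn_eps)
  v <- d$gamma * uhat + d$beta
  a <- ifelse(v > 0, v, params$leaky_slope * v)
  sum(d$W2 * a) + d$b2
}

# --- encoders ---------------------------------------------------------------

# Independent double loop over (position, residue-type) pairs.
oracle_pssm400 <- function(mat, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  out <- numeric(400)
  for (a_idx in 1:20) {
    for (pos in seq_along(chars)) {
      if (chars[pos] == AA[a_idx]) {
        for (col in 1:20) {
          out[(a_idx - 1) * 20 + col] <- out[(a_idx - 1) * 20 + col] +
            mat[pos, col]
        }
      }
    }
  }
  out
}

oracle_ctd_groups <- list(
  hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  polarity = c("LIFWCMVY", "PATGS", "HQRKNED"),
  vdw_volume = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondary_structure = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_accessibility = c("ALFCGIVW", "RKQEND", "MSPTHY")
)

# Materializes the class string explicitly and counts with loops.
oracle_ctd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(0)
  for (p in names(oracle_ctd_groups)) {
    cls <- character(L)
    for (i in 1:L) {
      for (g in 1:3) {
        if (grepl(chars[i], oracle_ctd_groups[[p]][g], fixed = TRUE)) {
          cls[i] <- as.character(g)
        }
      }
    }
    comp <- c(sum(cls == "1"), sum(cls == "2"), sum(cls == "3")) / L
    tr <- c(0, 0, 0)
    if (L >= 2) {
      for (i in 1:(L - 1)) {
        pair <- paste0(sort(c(cls[i], cls[i + 1])), collapse = "")
        if (pair == "12") tr[1] <- tr[1] + 1
        if (pair == "13") tr[2] <- tr[2] + 1
        if (pair == "23") tr[3] <- tr[3] + 1
      }
      tr <- tr / (L - 1)
    }
    dist <- numeric(15)
    for (g in 1:3) {
      pos <- which(cls == as.character(g))
      if (length(pos) > 0) {
        for (q in 1:5) {
          frac <- c(0, 0.25, 0.5, 0.75, 1)[q]
          idx <- if (frac == 0) 1 else max(1, floor(frac * length(pos) + 0.5))
          dist[(g - 1) * 5 + q] <- 100 * pos[idx] / L
        }
      }
    }
    out <- c(out, comp, tr, dist)
  }
  out
}

oracle_triad_classes <- c("AGV", "ILFP", "YMTS", "HNQW", "RK", "DE", "C")

# Enumerates every window, keying triads by name.
oracle_conjoint_triad <- function(sequence, normalize = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  cls <- integer(L)
  for (i in 1:L) {
    for (g in 1:7) {
      if (grepl(chars[i], oracle_triad_classes[g], fixed = TRUE)) cls[i] <- g
    }
  }
  counts <- numeric(343)
  for (i in 1:(L - 2)) {
    key <- (cls[i] - 1) * 49 + (cls[i + 1] - 1) * 7 + cls[i + 2]
    counts[key] <- counts[key] + 1
  }
  if (normalize && max(counts) > 0) counts / max(counts) else counts
}

oracle_paac_props <- local({
  h1 <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
          H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  h2 <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
          I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
          R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)
  m <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
         K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
         T = 45, V = 43, W = 130, Y = 107)
  std <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  list(std(h1), std(h2), std(m))
})

# Brute-force double loop over all position pairs at each tier.
oracle_paac <- function(sequence, lam, weight) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  theta <- numeric(lam)
  if (lam > 0) {
    for (k in 1:lam) {
      acc <- 0
      for (i in 1:(L - k)) {
        s <- 0
        for (pr in oracle_paac_props) {
          s <- s + (pr[chars[i]] - pr[chars[i + k]])^2
        }
        acc <- acc + s / 3
      }
      theta[k] <- acc / (L - k)
    }
  }
  freq <- numeric(20)
  for (i in 1:L) freq[which(AA == chars[i])] <- freq[which(AA == chars[i])] + 1
  freq <- freq / L
  denom <- sum(freq) + weight * sum(theta)
  c(freq, weight * theta) / denom
}

# --- sequence identity ------------------------------------------------------

# Greedy longest-first clustering driven by global-alignment percent
# identity (Biostrings pairwiseAlignment), the reference for the k-mer
# approximation on small inputs.
oracle_dedup <- function(records, threshold) {
  ord <- order(-nchar(records$sequence), records$id)
  reps <- integer(0)
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      aln <- Biostrings::pairwiseAlignment(records$sequence[i],
                                           records$sequence[r])
      if (Biostrings::pid(aln) / 100 >= threshold) { joined <- TRUE; break }
    }
    if (!joined) reps <- c(reps, i)
  }
  sort(records$id[reps])
}
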