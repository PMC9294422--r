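test_that("PSSM-400 blocks are residue-grouped row sums", {
  p1 <- gen_pssm("A", seed = 1L)
  f1 <- encode_pssm400(p1, "A")
  expect_equal(f1$width, 400L)
  expect_equal(f1$vector[1:20], as.numeric(p1$matrix[1, ]))
  expect_true(all(f1$vector[21:400] == 0))

  p2 <- gen_pssm("AA", seed = 2L)
  f2 <- encode_pssm400(p2, "AA")
  expect_equal(f2$vector[1:20], as.numeric(p2$matrix[1, ] + p2$matrix[2, ]))

  expect_error(encode_pssm400(p2, "AAA"), "rows")
})

test_that("PSSM-400 matches the double-loop oracle on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_protein(sample(5:80, 1))
    pssm <- gen_pssm(s, seed = i)
    expect_equal(encode_pssm400(pssm, s)$vector,
                 oracle_pssm400(pssm$matrix, s), tolerance = 1e-9)
  }
})

test_that("BLOSUM62 fallback profile reproduces the published matrix", {
  prof <- blosum62_profile("A")
  expect_equal(dim(prof$matrix), c(1L, 20L))
  expect_equal(unname(prof$matrix[1, "A"]), 4)      # BLOSUM62 (A,A)
  expect_equal(unname(prof$matrix[1, "W"]), -3)     # BLOSUM62 (A,W)
  expect_equal(prof$source, "blosum62_fallback")

  two <- blosum62_profile("AA")
  expect_equal(two$matrix[1, ], two$matrix[2, ])

  f <- encode_pssm400(blosum62_profile("AC"), "AC")
  b62 <- blosum62_profile("ACDEFGHIKLMNPQRSTVWY")$matrix
  expect_equal(f$vector[1:20], as.numeric(b62[1, ]))    # block A
  expect_equal(f$vector[21:40], as.numeric(b62[2, ]))   # block C
  expect_error(blosum62_profile("AXC"), "X")
})

test_that("PSSM files round-trip in both dialects", {
  s <- random_protein(12)
  pssm <- gen_pssm(s, seed = 3L)
  plain <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(pssm, plain)
  back <- read_pssm(plain, "p")
  expect_equal(unname(back$matrix), unname(pssm$matrix))

  # PSI-BLAST ASCII layout: header lines, then idx, residue, 20 scores (in
  # PSI-BLAST residue order), 20 percentage columns
  psi <- withr::local_tempfile(fileext = ".pssm")
  pborder <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  perm <- pssm$matrix[, pborder]
  lines <- c("", "Last position-specific scoring matrix computed",
             paste(c("", pborder, pborder), collapse = "   "))
  for (i in seq_len(nrow(perm))) {
    lines <- c(lines, paste(c(i, substr(s, i, i), perm[i, ],
                              rep(0, 20)), collapse = "  "))
  }
  writeLines(lines, psi)
  back2 <- read_pssm(psi, "p")
  expect_equal(unname(back2$matrix), unname(pssm$matrix))
})

test_that("CTD of a homopolymer matches hand enumeration", {
  f <- encode_ctd("AAAAA")
  expect_equal(f$width, 147L)
  v <- f$vector
  for (b in seq(0, 146, by = 21)) {
    comp <- v[b + 1:3]
    expect_equal(sum(comp), 1)                    # one class holds all of A
    g <- which(comp == 1)
    expect_equal(v[b + 4:6], c(0, 0, 0))          # no transitions
    expect_equal(v[b + 6 + (g - 1) * 5 + 1:5], c(20, 20, 60, 80, 100))
    others <- setdiff(1:3, g)
    for (o in others) expect_equal(v[b + 6 + (o - 1) * 5 + 1:5], rep(0, 5))
  }
})

test_that("CTD normalization identities hold on random sequences", {
  set.seed(21)
  for (i in 1:10) {
    s <- random_protein(sample(5:60, 1))
    v <- encode_ctd(s)$vector
    for (b in seq(0, 146, by = 21)) {
      expect_equal(sum(v[b + 1:3]), 1)
    }
  }
  expect_error(encode_ctd(""), "empty")
})

test_that("CTD matches the explicit class-string oracle", {
  set.seed(22)
  for (i in 1:25) {
    s <- random_protein(sample(5:80, 1))
    expect_equal(encode_ctd(s)$vector, oracle_ctd(s), tolerance = 1e-9)
  }
})

test_that("conjoint triad counts windows into 343 class bins", {
  f <- encode_conjoint_triad("AAA")
  expect_equal(f$width, 343L)
  expect_equal(sum(f$vector != 0), 1L)
  expect_equal(f$vector[1], 1)                    # triad (1,1,1), A in class 1
  set.seed(23)
  for (i in 1:10) {
    s <- random_protein(sample(3:60, 1))
    raw <- encode_conjoint_triad(s, normalize = FALSE)$vector
    expect_equal(sum(raw), nchar(s) - 2)
  }
  expect_error(encode_conjoint_triad("AA"), "length")
})

test_that("conjoint triad matches the sliding-window oracle", {
  set.seed(24)
  for (i in 1:25) {
    s <- random_protein(sample(5:80, 1))
    expect_equal(encode_conjoint_triad(s)$vector, oracle_conjoint_triad(s),
                 tolerance = 1e-9)
  }
})

test_that("PAAC collapses to amino-acid composition when order terms vanish", {
  s <- random_protein(20)
  aac <- encode_paac(s, lam = 0L)
  expect_equal(aac$width, 20L)
  expect_equal(sum(aac$vector), 1)
  counts <- table(factor(strsplit(s, "")[[1]], levels = aa_alphabet()))
  expect_equal(aac$vector, as.numeric(counts) / 20)

  # homopolymer: all property differences are zero, so correlations vanish
  g <- encode_paac("GGGGG", lam = 2L, weight = 0.05)
  expect_equal(g$width, 22L)
  expect_equal(g$vector[21:22], c(0, 0))
  expect_equal(g$vector[which(aa_alphabet() == "G")], 1)

  expect_error(encode_paac("MKV", lam = 5L), "lam")
})

test_that("PAAC matches the pairwise-correlation oracle", {
  set.seed(25)
  for (i in 1:25) {
    s <- random_protein(sample(5:80, 1))
    lam <- sample(0:min(3, nchar(s) - 1), 1)
    expect_equal(encode_paac(s, lam = lam, weight = 0.05)$vector,
                 unname(oracle_paac(s, lam, 0.05)), tolerance = 1e-9)
  }
})

test_that("every encoder is permutation-sensitive", {
  a <- "HLTHAQSTLDAK"
  b <- "KHLTHAQSTLDA"   # same composition, rotated order
  expect_false(isTRUE(all.equal(encode_conjoint_triad(a)$vector,
                                encode_conjoint_triad(b)$vector)))
  expect_false(isTRUE(all.equal(encode_ctd(a)$vector, encode_ctd(b)$vector)))
  expect_false(isTRUE(all.equal(encode_paac(a, lam = 2L)$vector,
                                encode_paac(b, lam = 2L)$vector)))
})

test_that("encoder widths are constant across inputs", {
  set.seed(26)
  for (i in 1:5) {
    s <- random_protein(sample(10:50, 1))
    expect_equal(encode_pssm400(blosum62_profile(s), s)$width, 400L)
    expect_equal(encode_ctd(s)$width, 147L)
    expect_equal(encode_conjoint_triad(s)$width, 343L)
    expect_equal(encode_paac(s, lam = 4L)$width, 24L)
  }
})

test_that("feature concatenation follows the published recipes", {
  s <- random_protein(30)
  parts <- list(encode_pssm400(blosum62_profile(s, "p"), s),
                encode_ctd(s, "p"), encode_conjoint_triad(s, "p"))
  full <- concat_features(parts)
  expect_equal(full$width, 400L + 147L + 343L)    # RBPPred-alike: 890
  expect_equal(full$vector,
               c(parts[[1]]$vector, parts[[2]]$vector, parts[[3]]$vector))
  expect_equal(concat_features(parts[2])$vector, parts[[2]]$vector)
  duo <- concat_features(parts[2:3])              # DeepRBPPred-alike: 490
  expect_equal(duo$width, 490L)
  bad <- encode_ctd(s, "other")
  expect_error(concat_features(list(parts[[1]], bad)), "mismatch")
})

test_that("encode_recipe builds feature matrices with documented widths", {
  recs <- gen_sequences(3L, length_range = c(40L, 60L), seed = 31L)
  expect_warning(X <- encode_recipe(recs, "pssm400+ctd+triad"), "BLOSUM62")
  expect_equal(dim(X), c(3L, 890L))
  expect_equal(rownames(X), recs$id)
  X2 <- encode_recipe(recs, "ctd+triad")
  expect_equal(ncol(X2), 490L)
  X3 <- suppressWarnings(encode_recipe(recs, "pssm400+ctd+paac",
                                       paac_lam = 10L))
  expect_equal(ncol(X3), 400L + 147L + 30L)
  expect_error(encode_recipe(recs, "nope"), "known recipes")
})
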