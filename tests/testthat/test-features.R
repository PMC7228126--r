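test_that("k-mer counting covers every overlapping window", {
  expect_equal(count_kmers("ACGT", 2), c(AC = 1L, CG = 1L, GT = 1L))
  expect_equal(count_kmers("AAAA", 1), c(A = 4L))
  for (s in random_seqs(5, 30, seed = 21)) {
    for (k in c(1, 3, 5)) {
      expect_equal(sum(count_kmers(s, k)), nchar(s) - k + 1)
    }
  }
  expect_error(count_kmers("ACG", 5), "exceeds")
})

test_that("PWM weights are per-site log-odds against the uniform background", {
  train <- seq_dataset(c("a", "b"), c("AA", "AA"))
  m <- build_pwm(train, k = 1, pseudocount = 0)
  expect_equal(unname(m$weights["A", ]), rep(log(4), 2))
  expect_equal(pwm_score(seq_dataset("q", "AA"), m), log(4))

  uni <- build_pwm(seq_dataset(letters[1:4], c("AAAA", "CCCC", "GGGG", "TTTT")),
                   k = 1, pseudocount = 0)
  expect_equal(unname(uni$weights), matrix(0, 4, 4), tolerance = 1e-12)
  expect_equal(pwm_score(seq_dataset("q", "ACGT"), uni), 0)

  expect_equal(build_pwm(seq_dataset("a", "ACGTACGT"), k = 3,
                         pseudocount = 0.1)$p0, 1 / 64)
})

test_that("PWM scoring matches a brute-force smoothed re-implementation", {
  # independent oracle: direct loops over sites and k-mers
  oracle_score <- function(train_seqs, query, k, pc) {
    n_sites <- max(nchar(train_seqs)) - k + 1
    kms <- all_kmers(k)
    W <- matrix(NA_real_, length(kms), n_sites, dimnames = list(kms, NULL))
    for (i in seq_len(n_sites)) {
      present <- nchar(train_seqs) >= i + k - 1
      N_i <- sum(present)
      for (x in kms) {
        n_xi <- sum(substr(train_seqs[present], i, i + k - 1) == x)
        p <- (n_xi + pc) / (N_i + 4^k * pc)
        W[x, i] <- log(p / (1 / 4^k))
      }
    }
    n <- min(nchar(query) - k + 1, n_sites)
    mean(vapply(seq_len(n), function(i)
      W[substr(query, i, i + k - 1), i], numeric(1)))
  }
  expect_equal(
    pwm_score(seq_dataset("q", "CC"),
              build_pwm(seq_dataset(c("a", "b"), c("AA", "AA")), 1, 0.25)),
    oracle_score(c("AA", "AA"), "CC", 1, 0.25))

  train <- random_seqs(6, 8, seed = 31)
  queries <- random_seqs(4, 8, seed = 32)
  for (k in c(1, 2)) {
    m <- build_pwm(seq_dataset(paste0("t", seq_along(train)), train), k, 0.25)
    got <- pwm_score(seq_dataset(paste0("q", seq_along(queries)), queries), m)
    want <- vapply(queries, oracle_score, numeric(1),
                   train_seqs = train, k = k, pc = 0.25, USE.NAMES = FALSE)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("variable-length sequences are scored over the sites they have", {
  train <- seq_dataset(c("a", "b"), c("ACGTACGT", "ACGT"))
  m <- build_pwm(train, k = 1, pseudocount = 0.25)
  expect_equal(m$n_sites, 8)
  # longer query than the model: only the model's sites are scored
  long <- seq_dataset("L", strrep("A", 12))
  expect_true(is.finite(pwm_score(long, m)))
  short <- seq_dataset("S", "AC")
  expect_true(is.finite(pwm_score(short, m)))
  expect_error(pwm_score(seq_dataset("x", "A"), build_pwm(train, 2)), "shorter")
})

test_that("base content reproduces the composition identities", {
  d <- seq_dataset(c("a", "b", "c"), c("ATGC", "TTTT", "GGGG"))
  bc <- base_content(d)
  expect_equal(unlist(bc[1, 2:6]),
               c(atContent = 0.5, gcContent = 0.5, atgcRatio = 1,
                 gcSkew = 0, atSkew = 0))
  expect_equal(bc$atContent[2], 1)
  expect_equal(bc$atSkew[2], -1)
  expect_equal(bc$gcSkew[2], 0)       # no G/C: degenerate, not an error
  expect_true(bc$degenerate[2])
  expect_equal(bc$gcContent[3], 1)
  expect_equal(bc$gcSkew[3], 1)
  expect_equal(bc$atgcRatio[3], 0)

  rand <- seq_dataset(paste0("r", 1:6), random_seqs(6, 40, seed = 41))
  rbc <- base_content(rand)
  expect_equal(rbc$atContent + rbc$gcContent, rep(1, 6))
  ok <- rbc$gcContent > 0
  expect_equal(rbc$atgcRatio[ok], (rbc$atContent / rbc$gcContent)[ok])
  expect_true(all(abs(rbc$gcSkew) <= 1 & abs(rbc$atSkew) <= 1))
})

test_that("chemical encoding is the exact ring/hydrogen/functional table", {
  enc <- chemical_encoding("ACGT")
  expect_equal(unname(enc[, 1]), c(0, 1, 0))  # A: purine, weak, amino
  expect_equal(unname(enc[, 2]), c(1, 0, 0))  # C
  expect_equal(unname(enc[, 3]), c(0, 0, 1))  # G
  expect_equal(unname(enc[, 4]), c(1, 1, 1))  # T: pyrimidine, weak, keto
})

test_that("physicochemical encoding places k-mer values at their start positions", {
  pt <- load_property_table()
  enc <- physico_encoding("AAA", pt)
  v_aa <- pt$dinucleotide["Rise", "AA"]
  expect_equal(unname(enc["Rise", ]), c(v_aa, v_aa, 0))
  tri_rows <- rownames(pt$trinucleotide)
  enc2 <- physico_encoding("ACGT", pt)
  expect_true(all(enc2[tri_rows, 3:4] == 0))
  expect_equal(unname(enc2[tri_rows, 1]), unname(pt$trinucleotide[, "ACG"]))
  expect_identical(physico_encoding("ACGT", pt), physico_encoding("ACGT", pt))
})

test_that("per-position property vectors are zero-padded to the fixed width", {
  d <- seq_dataset("s", paste(rep("ACGTT", 10), collapse = ""))  # 50 bp
  X <- nucleotidepro(d, l_max = 82)
  expect_equal(ncol(X) - 1, 47 * 82)
  tail_cols <- grepl("_p(5[0-9]|6[0-9]|7[0-9]|8[01])$", names(X))
  expect_true(all(X[1, tail_cols] == 0))
  dC <- seq_dataset("c", "CATG")
  expect_equal(unname(unlist(nucleotidepro(dC, l_max = 10)[1, 2:4])),
               c(1, 0, 0))
  expect_error(nucleotidepro(d, l_max = 40), "l_max")
})

test_that("property tables load standardized", {
  pt <- load_property_table()
  expect_equal(unname(rowMeans(pt$dinucleotide)), rep(0, 32), tolerance = 1e-6)
  expect_equal(unname(apply(pt$dinucleotide, 1, sd)), rep(1, 32),
               tolerance = 1e-6)
  expect_equal(unname(apply(pt$trinucleotide, 1, sd)), rep(1, 12),
               tolerance = 1e-6)
  expect_equal(dim(pt$trinucleotide), c(12, 64))
})

test_that("PseKNC vectors are probability vectors in every mode", {
  seqs <- seq_dataset(paste0("r", 1:4), random_seqs(4, 30, seed = 51))
  for (mode in c("parallel", "series")) {
    for (k in c(4, 5)) {
      for (w in c(0.1, 0.5)) {
        v <- pseknc(seqs, pseknc_config(k = k, lambda = 3, w = w, mode = mode))
        vals <- as.matrix(v[, -1])
        expect_true(all(vals >= 0))
        expect_equal(unname(rowSums(vals)), rep(1, 4), tolerance = 1e-9)
        expect_equal(ncol(vals),
                     4^k + 3 * if (mode == "series") 6 else 1)
      }
    }
  }
})

test_that("PseKNC collapses on homopolymers and at w = 0", {
  homo <- seq_dataset("h", strrep("A", 12))
  for (mode in c("parallel", "series")) {
    v <- pseknc(homo, pseknc_config(k = 5, lambda = 1, mode = mode))
    vals <- unlist(v[, -1])
    expect_equal(unname(vals[grepl("AAAAA$", names(vals))]), 1)
    expect_true(all(vals[grepl("theta", names(vals))] == 0))
  }
  rand <- seq_dataset("r", random_seqs(1, 20, seed = 61))
  v0 <- pseknc(rand, pseknc_config(k = 4, lambda = 2, w = 0))
  f <- kmer_count_vector(rand$sequence, 4)
  expect_equal(unname(unlist(v0[, 2:(4^4 + 1)])), unname(f / sum(f)))
  expect_true(all(unlist(v0[, -(1:(4^4 + 1))]) == 0))
  expect_error(pseknc(seq_dataset("x", "ACGTA"),
                      pseknc_config(k = 4, lambda = 3)), "too short")
})

test_that("series mode with the product convention is available", {
  rand <- seq_dataset("r", random_seqs(1, 20, seed = 62))
  a <- pseknc(rand, pseknc_config(k = 4, lambda = 2, mode = "series",
                                  series_correlation = "product"))
  b <- pseknc(rand, pseknc_config(k = 4, lambda = 2, mode = "series"))
  expect_equal(sum(a[, -1]), 1, tolerance = 1e-9)
  expect_false(identical(a, b))
})

test_that("feature groups concatenate families with the declared dimensions", {
  d <- tiny_labelled()
  expect_equal(ncol(extract_group(d, "basecontent")) - 1, 5)
  two <- extract_group(d, c("kpwm(1)", "kpwm(6)"))
  expect_equal(ncol(two) - 1, 2)
  expect_equal(unname(attr(two, "family")), c("kpwm", "kpwm"))

  lambda <- 3; l_max <- 20
  g8 <- extract_group(d, c("pseknc1(5)", "pseknc2(5)", "nucleotidepro"),
                      lambda = lambda, l_max = l_max)
  # dimension accounting: (4^5 + lambda) + (4^5 + 6*lambda) + 47 * l_max
  expect_equal(ncol(g8) - 1,
               (4^5 + lambda) + (4^5 + 6 * lambda) + 47 * l_max)
  fam <- attr(g8, "family")
  expect_equal(unname(table(fam)[c("pseknc1", "pseknc2", "nucleotidepro")]),
               c(4^5 + lambda, 4^5 + 6 * lambda, 47 * l_max),
               ignore_attr = TRUE)
  expect_error(extract_group(d, "frobnicate"), "unknown feature family")
})
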