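# minimal matrix/annotation pair for hand-chosen group values
two_group_matrix <- function(male, female) {
  n <- length(male) + length(female)
  annot <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    sex = rep(c("M", "F"), c(length(male), length(female))),
    age_months = 3, replicate = seq_len(n))
  m <- matrix(c(male, female), 1, n,
              dimnames = list("g1", annot$sample_id))
  attr(m, "scale") <- "linear"
  list(matrix = m, annot = annot)
}

test_that("pooled-variance t test matches the closed form and textbook example", {
  d <- two_group_matrix(c(1, 2, 3), c(2, 3, 4))
  rec <- sex_ttest(d$matrix, d$annot)
  expect_equal(rec$t_stat, -1.2247449, tolerance = 1e-6)
  expect_equal(rec$p_value, 0.2878641, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(rec$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(rec$p_value, ref$p.value, tolerance = 1e-10)

  ident <- two_group_matrix(c(1, 2, 3), c(1, 2, 3))
  rec <- sex_ttest(ident$matrix, ident$annot)
  expect_identical(rec$t_stat, 0)
  expect_identical(rec$p_value, 1)

  # zero variance in both sexes with equal means: t = 0, p = 1, no error
  flat <- two_group_matrix(c(5, 5, 5), c(5, 5, 5))
  rec <- sex_ttest(flat$matrix, flat$annot)
  expect_identical(rec$p_value, 1)
})

test_that("the screen agrees with t.test gene-by-gene on random data", {
  annot <- make_annotation()
  m <- random_matrix(annot, n_genes = 40L, seed = 33L)
  rec <- sex_ttest(m, annot)
  m_cols <- annot$sample_id[annot$sex == "M"]
  f_cols <- annot$sample_id[annot$sex == "F"]
  for (g in rownames(m)) {
    ref <- t.test(m[g, m_cols], m[g, f_cols], var.equal = TRUE)
    i <- match(g, rec$gene_id)
    expect_equal(rec$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(rec$p_value[i], ref$p.value, tolerance = 1e-10)
  }
  expect_equal(rec$ratio_MF, rec$mean_M / rec$mean_F, tolerance = 1e-12)
})

test_that("t statistics are antisymmetric in the labels and scale invariant", {
  annot <- make_annotation()
  m <- random_matrix(annot, n_genes = 15L, seed = 44L)
  rec <- sex_ttest(m, annot)
  flipped <- annot
  flipped$sex <- ifelse(annot$sex == "M", "F", "M")
  rec_f <- sex_ttest(m, flipped)
  expect_equal(rec_f$t_stat, -rec$t_stat, tolerance = 1e-12)
  expect_equal(rec_f$p_value, rec$p_value, tolerance = 1e-12)

  m2 <- m * 3.7
  attr(m2, "scale") <- "linear"
  rec_s <- sex_ttest(m2, annot)
  expect_equal(rec_s$t_stat, rec$t_stat, tolerance = 1e-9)
  expect_equal(rec_s$q_value, rec$q_value, tolerance = 1e-9)
  expect_equal(rec_s$ratio_MF, rec$ratio_MF, tolerance = 1e-12)
  expect_equal(rec_s$mean_M, 3.7 * rec$mean_M, tolerance = 1e-12)
})

test_that("a sex with fewer than two samples is rejected", {
  d <- two_group_matrix(c(1), c(2, 3, 4))
  expect_error(sex_ttest(d$matrix, d$annot), "at least 2")
})

test_that("Benjamini-Hochberg step-up matches the hand oracle", {
  expect_identical(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4), tolerance = 1e-12)

  set.seed(9)
  p <- runif(1000)
  # independent step-up oracle: sort, p * m / rank, cumulative min from the top
  ord <- order(p)
  m <- length(p)
  stepped <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q_oracle <- numeric(m)
  q_oracle[ord] <- pmin(stepped, 1)
  expect_equal(benjamini_hochberg(p), q_oracle, tolerance = 1e-14)

  # permutation invariance up to reordering
  perm <- sample(m)
  expect_equal(benjamini_hochberg(p[perm]), q_oracle[perm], tolerance = 1e-14)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("signature extraction keeps signed genes below the q threshold", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    mean_M = c(2, 1, 3), mean_F = c(1, 2, 1),
                    q_value = c(0.05, 0.09, 0.2))
  sig <- extract_signature(rec, 0.1)
  expect_identical(sig$entries, c(a = 1L, b = -1L))
  expect_identical(sig$n_up, 1L)
  expect_identical(sig$n_down, 1L)

  empty <- extract_signature(rec[0, ], 0.1)
  expect_length(empty$entries, 0L)

  all_in <- extract_signature(rec, 1.0)
  expect_length(all_in$entries, 3L)
  expect_error(extract_signature(rec, 0), "0, 1")

  # equal means carry no direction and are excluded
  rec$mean_F[1] <- 2; rec$mean_M[1] <- 2
  expect_identical(names(extract_signature(rec, 1.0)$entries), c("b", "c"))
})

test_that("signatures round-trip through TSV", {
  sig <- extract_signature(
    data.frame(gene_id = c("up1", "dn1"), mean_M = c(3, 1), mean_F = c(1, 3),
               q_value = c(0.01, 0.02)), 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$entries, sig$entries)
})
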