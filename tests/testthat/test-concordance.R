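test_that("cross-tabulation counts label pairs exactly", {
  labels <- c(g1 = 1L, g2 = 2L, g3 = 3L)
  tab <- cross_tabulate(labels, labels, K = 3L)
  expect_identical(sum(diag(tab)), 3L)
  expect_identical(sum(tab) - sum(diag(tab)), 0L)

  male <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L, f = 3L)
  female <- c(a = 1L, b = 2L, c = 2L, d = 2L, e = 1L, f = 3L)
  tab <- cross_tabulate(male, female, K = 3L)
  # brute-force pair counting
  for (j in 1:3) for (k in 1:3) {
    expect_identical(tab[j, k],
                     sum(male == j & female[names(male)] == k))
  }

  disjoint <- cross_tabulate(c(x = 1L), c(y = 2L), K = 2L)
  expect_true(all(disjoint == 0L))
  expect_error(cross_tabulate(c(a = 5L), c(a = 1L), K = 3L), "outside")
})

test_that("cross-tab summaries conserve counts and match direct summation", {
  set.seed(15)
  tab <- matrix(rpois(36, 20), 6, 6)
  s <- summarize_crosstab(tab)
  expect_identical(s$diagonal_total, as.integer(sum(diag(tab))))
  expect_identical(s$offdiagonal_total, as.integer(sum(tab) - sum(diag(tab))))
  expect_identical(s$grand_total, as.integer(sum(tab)))
  expect_identical(s$per_cell(2, 5), as.integer(tab[2, 5]))
  expect_identical(s$diagonal_total + s$offdiagonal_total, s$grand_total)

  z <- summarize_crosstab(matrix(0L, 4, 4))
  expect_identical(z$grand_total, 0L)
})

test_that("a common relabeling permutes the cross-tab but keeps the diagonal totals", {
  set.seed(16)
  male <- setNames(sample.int(4, 200, replace = TRUE), sprintf("g%03d", 1:200))
  female <- setNames(sample.int(4, 200, replace = TRUE), names(male))
  tab <- cross_tabulate(male, female, K = 4L)
  perm <- c(3L, 1L, 4L, 2L)
  tab_p <- cross_tabulate(setNames(perm[male], names(male)),
                          setNames(perm[female], names(female)), K = 4L)
  inv <- order(perm)
  expect_identical(unname(tab_p[perm, perm]), unname(tab))
  expect_identical(sum(diag(tab_p)), sum(diag(tab)))
})

test_that("genes partition into common and discordant sides", {
  male <- c(a = 1L, b = 1L, c = 2L, d = 2L, e = 3L)
  female <- c(a = 1L, b = 2L, c = 2L, d = 3L, e = 3L)
  part <- partition_genes(list(male = male, female = female))
  expect_setequal(part$common_genes, c("a", "c", "e"))
  expect_setequal(part$discordant_genes, c("b", "d"))

  same <- partition_genes(list(male = male, female = male))
  expect_length(same$discordant_genes, 0L)

  # a gene labeled in one sex only is excluded and reported
  part2 <- partition_genes(list(male = c(male, z = 1L), female = female))
  expect_identical(part2$excluded, "z")
  expect_identical(length(part2$common_genes) + length(part2$discordant_genes),
                   nrow(part2$labels))

  # partition sizes always reconcile with the cross-tab grand total
  tab <- cross_tabulate(male, female, K = 3L)
  expect_identical(summarize_crosstab(tab)$grand_total,
                   length(part$common_genes) + length(part$discordant_genes))
})

test_that("gene-set summaries report exact counts and rounded percentages", {
  part <- synthetic_partition(30, 10)
  sets <- list(all_common = sprintf("common_%04d", 1:20),
               empty = c("nothere_1", "nothere_2"),
               mixed = c(sprintf("common_%04d", 1:5), sprintf("disc_%04d", 1:5)))
  s <- gene_set_summary(part, sets)
  expect_identical(s$pct_common[s$set_name == "all_common"], 100L)
  expect_identical(s$total[s$set_name == "empty"], 0L)
  expect_identical(s$n_common[s$set_name == "mixed"], 5L)
  expect_identical(s$pct_common[s$set_name == "mixed"], 50L)
  expect_equal(s$frac_common[s$set_name == "mixed"], 0.5)
})

test_that("overrepresentation p-values match the hypergeometric tail oracle", {
  background <- sprintf("g%03d", 1:100)
  sets <- list(s10 = background[1:10])
  query <- c(background[1:5], background[51:55])
  res <- overrepresentation_test(query, sets, background)
  # brute-force tail sum over overlap >= 5
  oracle <- sum(dhyper(5:10, 10, 90, 10))
  expect_equal(res$p_value, oracle, tolerance = 1e-12)

  # saturation: query = set = background
  res <- overrepresentation_test(background, list(all = background), background)
  expect_equal(res$p_value, 1)

  # no overlap with a tiny set: p close to 1
  res <- overrepresentation_test(background[1:10], list(tiny = background[95:97]),
                                 background)
  expect_gt(res$p_value, 0.7)

  expect_error(overrepresentation_test("x", list(a = "x"), character(0)), "empty")
  expect_error(overrepresentation_test("zz", list(a = "g001"), background),
               "background")
})

test_that("overrepresentation matches the oracle across random small instances", {
  set.seed(18)
  for (i in 1:40) {
    N <- sample(20:200, 1)
    background <- sprintf("b%04d", seq_len(N))
    m <- sample.int(N, 1)
    nq <- sample.int(N, 1)
    gene_set <- sample(background, m)
    query <- sample(background, nq)
    res <- overrepresentation_test(query, list(s = gene_set), background)
    ov <- length(intersect(gene_set, query))
    oracle <- sum(dhyper(ov:min(m, nq), m, N - m, nq))
    expect_equal(res$p_value, oracle, tolerance = 1e-12)
  }
})
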