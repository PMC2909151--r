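test_that("similarity matrix is symmetric with unit diagonal and hand-checked entries", {
  aln <- new_alignment(c(a = "ACGT", b = "ACGA", c = "TTTT"))
  sm <- similarity_matrix(aln)
  expect_equal(diag(sm), c(a = 1, b = 1, c = 1))
  expect_identical(sm, t(sm))
  expect_equal(sm["a", "b"], 0.75)
  expect_equal(sm["a", "c"], 0.25)   # only the final T matches
  expect_equal(sm["b", "c"], 0.0)
  expect_equal(similarity_matrix(new_alignment(c(x = "AC", y = "AC")))["x", "y"], 1.0)
  expect_error(similarity_matrix(new_alignment(c(x = "AC"))), ">= 2")
})

test_that("within/across split enumerates the right pairs", {
  aln <- new_alignment(setNames(rep("ACGT", 4), c("i1.a1", "i1.a2", "i2.a1", "i2.a2")))
  sm <- similarity_matrix(aln)
  pr <- allele_pairs(c("i1", "i2"), c("i1.a1", "i2.a1"), c("i1.a2", "i2.a2"))
  sp <- within_across_split(sm, pr)
  expect_length(sp$within, 2L)
  expect_length(sp$across, 4L)
  # single isolate: no across pair to compare against
  expect_error(within_across_split(sm, pr[1, ]), "across")
  expect_error(allele_pairs("i1", "a", "a"), "identical ids")

  # brute-force enumeration on a 3-isolate fixture with one singleton
  set.seed(901)
  ids <- c("i1.a1", "i1.a2", "i2.a1", "i2.a2", "i3.a1")
  aln3 <- new_alignment(setNames(replicate(5, rand_dna(20)), ids))
  sm3 <- similarity_matrix(aln3)
  pr3 <- allele_pairs(c("i1", "i2"), c("i1.a1", "i2.a1"), c("i1.a2", "i2.a2"))
  sing <- data.frame(allele_id = "i3.a1", isolate_id = "i3", group = "all")
  sp3 <- within_across_split(sm3, pr3, singletons = sing)
  expect_equal(sort(sp3$within), sort(c(sm3["i1.a1", "i1.a2"], sm3["i2.a1", "i2.a2"])))
  iso_of <- setNames(c("i1", "i1", "i2", "i2", "i3"), ids)
  brute <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    if (iso_of[ids[i]] != iso_of[ids[j]]) brute <- c(brute, sm3[ids[i], ids[j]])
  }
  expect_equal(sort(sp3$across), sort(brute))
  # excluding singletons removes exactly the i3 pairs
  sp3b <- within_across_split(sm3, pr3, singletons = sing, include_singletons = FALSE)
  expect_length(sp3b$across, 4L)
})

test_that("Welch test matches the closed formula, base invariances and edge cases", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5)
  wt <- welch_t_test(x, y)
  hand <- welch_hand(x, y)
  expect_equal(wt$t, hand$t, tolerance = 1e-12)
  expect_equal(wt$df, hand$df, tolerance = 1e-12)
  expect_equal(wt$p, hand$p, tolerance = 1e-12)
  # same values: t = 0, two-sided p = 1
  wt0 <- welch_t_test(c(1, 2, 3), c(3, 2, 1))
  expect_equal(wt0$t, 0)
  expect_equal(wt0$p, 1)
  # scale invariance
  wt_s <- welch_t_test(10 * x, 10 * y)
  expect_equal(wt_s$t, wt$t, tolerance = 1e-12)
  # degenerate zero-variance cases
  expect_false(welch_t_test(c(1, 1), c(1, 1))$defined)
  deg <- welch_t_test(c(2, 2), c(1, 1))
  expect_true(is.infinite(deg$t) && deg$t > 0)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2 values")
})

test_that("permutation test is seed-reproducible and detects forced dissimilar pairing", {
  set.seed(902)
  # pool of two divergent haplogroups; forced pairs always span groups
  gA <- rand_dna(60); gB <- mutate_at(gA, sample(60, 25))
  seqs <- c(vapply(1:10, function(i) mutate_at(gA, sample(60, 1)), ""),
            vapply(1:10, function(i) mutate_at(gB, sample(60, 1)), ""))
  names(seqs) <- c(paste0("i", 1:10, ".a1"), paste0("i", 1:10, ".a2"))
  sm <- similarity_matrix(new_alignment(seqs))
  pr <- allele_pairs(paste0("i", 1:10), paste0("i", 1:10, ".a1"),
                     paste0("i", 1:10, ".a2"))
  p1 <- permutation_test(sm, pr, n_perm = 499, seed = 5)$p
  p2 <- permutation_test(sm, pr, n_perm = 499, seed = 5)$p
  expect_identical(p1, p2)
  expect_lt(p1, 0.02)
  expect_error(permutation_test(sm, pr, n_perm = 0), "n_perm")
})

test_that("group tests report direction and significance per population structure", {
  set.seed(903)
  L <- 80
  # founder-like group: two divergent marker lineages, pairs span them
  gA <- rand_dna(L); gB <- mutate_at(gA, sample(L, 30))
  founder <- c(vapply(1:5, function(i) mutate_at(gA, sample(L, 1)), ""),
               vapply(1:5, function(i) mutate_at(gB, sample(L, 1)), ""))
  names(founder) <- c(paste0("f", 1:5, ".a1"), paste0("f", 1:5, ".a2"))
  # variable group: every allele drawn independently from a diffuse cloud
  varia <- vapply(1:10, function(i) mutate_at(gA, sample(L, sample(5:15, 1))), "")
  names(varia) <- c(paste0("v", 1:5, ".a1"), paste0("v", 1:5, ".a2"))
  aln <- new_alignment(c(founder, varia))
  sm <- similarity_matrix(aln)
  pr <- allele_pairs(c(paste0("f", 1:5), paste0("v", 1:5)),
                     c(paste0("f", 1:5, ".a1"), paste0("v", 1:5, ".a1")),
                     c(paste0("f", 1:5, ".a2"), paste0("v", 1:5, ".a2")),
                     group = rep(c("founder", "variable"), each = 5))
  res <- run_group_tests(sm, pr, n_perm = 499, seed = 11)
  expect_equal(nrow(res), 2L)
  f_row <- res[res$group == "founder", ]
  v_row <- res[res$group == "variable", ]
  expect_lt(f_row$p_value, 0.01)
  expect_equal(f_row$direction, "within-more-divergent")
  expect_lt(f_row$t_statistic, 0)   # within less similar => negative t
  expect_gt(v_row$p_value, 0.05)
  # empty group list yields an empty table with the full schema
  empty <- run_group_tests(sm, pr, groups = character(0))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("group", "t_statistic", "p_permutation") %in% names(empty)))
})
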