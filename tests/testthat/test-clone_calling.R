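make_clone_set <- function(mat, iso = "isoT") {
  clone_set(new_alignment(mat, locus = "marker"), isolate_id = iso)
}

test_that("single-linkage clone clustering separates divergent allele blocks", {
  set.seed(501)
  L <- 200
  base <- rand_dna(L)
  # 5 identical clones -> one group
  cs <- make_clone_set(do.call(rbind, rep(list(strsplit(base, "")[[1]]), 5)))
  expect_equal(cluster_clones(cs), list(1:5))

  # two blocks at ~10% divergence, <1% within-block noise, threshold 0.02
  other <- mutate_at(base, sample(L, 20))
  block <- function(hap, m) t(vapply(seq_len(m), function(i) {
    strsplit(mutate_at(hap, sample(L, 1)), "")[[1]]
  }, character(L)))
  cs2 <- make_clone_set(rbind(block(base, 3), block(other, 3)))
  expect_equal(cluster_clones(cs2, 0.02), list(1:3, 4:6))
  # near-1 threshold always chains everything together
  expect_length(cluster_clones(cs2, 0.999), 1L)
  expect_error(cluster_clones(cs2, 0), "threshold")
})

test_that("consensus applies the autapomorphy, two-copy and single-copy rules", {
  # 3 clones, one with a unique substitution at column 7 (0-based)
  hap <- "ACGTACGTACGT"
  m <- do.call(rbind, rep(list(strsplit(hap, "")[[1]]), 3))
  m[2, 8] <- "C"   # column index 7, 0-based
  cc <- consensus_call(new_alignment(m))
  expect_equal(cc$seq, hap)
  expect_equal(cc$discarded_singleton_positions, 7L)
  expect_equal(cc$rule_applied, "majority-consensus")

  # 2 clones: disagreements become two-fold IUPAC codes
  cc2 <- consensus_call(new_alignment(c(c1 = "ACGT", c2 = "ACAT")))
  expect_equal(cc2$seq, "ACRT")
  expect_equal(cc2$ambiguity_positions, 2L)
  expect_equal(cc2$rule_applied, "two-copy-het")

  # 1 clone: verbatim
  cc3 <- consensus_call(new_alignment(c(c1 = "AC-TN")))
  expect_equal(cc3$seq, "AC-TN")
  expect_equal(cc3$rule_applied, "single-copy")

  # 2-2 tie at m = 4 resolves alphabetically and is logged
  m4 <- do.call(rbind, strsplit(c("AAAA", "AAAA", "AAGA", "AAGA"), ""))
  cc4 <- consensus_call(new_alignment(m4))
  expect_equal(substr(cc4$seq, 3, 3), "A")
  expect_equal(cc4$tie_positions, 2L)
})

test_that("call_alleles composes clustering and consensus deterministically", {
  set.seed(502)
  L <- 200
  a <- rand_dna(L); b <- mutate_at(a, sample(L, 20))
  m <- do.call(rbind, strsplit(c(rep(a, 4), rep(b, 2)), ""))
  acs <- call_alleles(make_clone_set(m))
  expect_equal(acs$n_clusters, 2L)
  expect_equal(vapply(acs$calls, `[[`, 0L, "support"), c(4L, 2L))
  expect_equal(acs$calls[[1]]$seq, a)   # higher support first
  expect_equal(acs$calls[[2]]$seq, b)
  expect_equal(vapply(acs$calls, `[[`, "", "id"), c("isoT.a1", "isoT.a2"))

  # all clones identical -> one allele with support = clone count
  acs1 <- call_alleles(make_clone_set(do.call(rbind, strsplit(rep(a, 6), ""))))
  expect_equal(acs1$n_clusters, 1L)
  expect_equal(acs1$calls[[1]]$support, 6L)

  # 4 clones in 3 clusters -> 3 alleles (up to 4 per isolate occur)
  c3 <- mutate_at(a, sample(L, 40))
  m3 <- do.call(rbind, strsplit(c(a, a, b, c3), ""))
  expect_equal(call_alleles(make_clone_set(m3))$n_clusters, 3L)
})

test_that("discarded singletons never overlap variants shared by two clones", {
  set.seed(503)
  for (rep in 1:25) {
    L <- 120
    hap <- rand_dna(L)
    m <- make_clones(hap, sample(3:8, 1), 0.02)
    cc <- consensus_call(new_alignment(m, locus = "marker"))
    cons <- strsplit(cc$seq, "")[[1]]
    # brute force per discarded column: only count-1 variants may be
    # discarded, so the column must hold >= 1 singleton state plus a
    # supported (>= 2 clone) state, and the consensus base is supported
    for (p in cc$discarded_singleton_positions) {
      tab <- table(m[, p + 1L])
      expect_true(any(tab == 1L))
      expect_true(any(tab >= 2L))
      expect_gte(unname(tab[cons[p + 1L]]), 2L)
    }
  }
})

test_that("consensus accuracy improves with clone number at fixed error rate", {
  set.seed(504)
  L <- 400; eps <- 0.05
  err_rate <- function(m, reps = 60) {
    mean(replicate(reps, {
      hap <- rand_dna(L)
      cc <- consensus_call(new_alignment(make_clones(hap, m, eps), locus = "x"))
      cc$seq != hap
    }))
  }
  e3 <- err_rate(3); e9 <- err_rate(9)
  expect_gt(e3, e9)
  expect_lt(e9, 0.1)
})
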