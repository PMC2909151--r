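test_that("segregating-site, mutation and singleton counts match hand enumeration", {
  same <- new_alignment(c(a = "ACGT", b = "ACGT"))
  expect_equal(segregating_sites(same)[c("S", "eta", "eta_s")],
               list(S = 0L, eta = 0L, eta_s = 0L))
  # columns {A,A,G}, {C,C,C}, {A,T,G}: S=2, eta=1+2=3, eta_s: G singleton
  # in col 1, col 3 all-singleton contributes its 2 mutations
  aln <- new_alignment(c(a = "ACA", b = "ACT", c = "GCG"))
  ss <- segregating_sites(aln)
  expect_equal(ss$S, 2L)
  expect_equal(ss$eta, 3L)
  expect_equal(ss$eta_s, 3L)
  # one biallelic singleton column among 10 sequences
  seqs <- setNames(c("AG", rep("AA", 9)), paste0("s", 1:10))
  expect_equal(segregating_sites(new_alignment(seqs))[c("S", "eta", "eta_s")],
               list(S = 1L, eta = 1L, eta_s = 1L))
  expect_error(segregating_sites(new_alignment(c(a = "-", b = "A"))),
               "complete deletion")
})

test_that("k and pi match the brute-force all-pairs averages", {
  # two sequences differing at 5 of 100 sites
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("C", 5), rep("A", 95)), collapse = "")
  aln <- new_alignment(c(a = s1, b = s2))
  expect_equal(mean_pairwise_k(aln), 5)
  expect_equal(nucleotide_diversity(aln), 0.05)
  expect_equal(mean_pairwise_k(new_alignment(c(a = s1, b = s1))), 0)

  set.seed(701)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    seqs <- setNames(replicate(n, {
      v <- sample(c("A", "C", "G", "T", "-"), 30, replace = TRUE,
                  prob = c(rep(0.235, 4), 0.06))
      paste(v, collapse = "")
    }), paste0("s", 1:n))
    if (length(oracle_valid_cols(seqs)) == 0) next
    aln <- new_alignment(seqs)
    expect_equal(mean_pairwise_k(aln), oracle_k(seqs))
    o <- oracle_seg_sites(seqs)
    p <- segregating_sites(aln)
    expect_equal(p$S, o$S); expect_equal(p$eta, o$eta)
    expect_equal(p$eta_s, o$eta_s)
    expect_equal(nucleotide_diversity(aln), oracle_k(seqs) / o$L)
  }
})

test_that("Watterson's theta follows S/a1(n) and its monotonicity", {
  expect_equal(watterson_theta(2, 5)$theta_w, 5)
  expect_error(watterson_theta(1, 5), "n >= 2")
  th <- vapply(1:20, function(S) watterson_theta(10, S)$theta_w, 0)
  expect_true(all(diff(th) > 0))
  th_n <- vapply(c(5, 10, 50, 100), function(n) watterson_theta(n, 30)$theta_w, 0)
  expect_true(all(diff(th_n) < 0))
  expect_equal(watterson_theta(10, 9, L_valid = 100)$theta_w_site,
               watterson_theta(10, 9)$theta_w / 100)
})

test_that("Tajima's D matches the literal formula and is undefined at S=0", {
  expect_false(tajimas_d(new_alignment(c(a = "AAA", b = "AAA")))$defined)
  aln <- new_alignment(c(a = "AAAA", b = "AAAG", c = "AAGG", d = "AGGG"))
  o <- oracle_seg_sites(aln_strings(aln))
  D <- tajimas_d(aln)$D
  expect_equal(D, ref_tajima_d(4, o$S, oracle_k(aln_strings(aln))),
               tolerance = 1e-12)
})

test_that("Fu & Li star statistics match an independent transcription and sign logic", {
  # star-like sample: every mutation a singleton -> D* < 0
  set.seed(702)
  seqs <- setNames(vapply(1:10, function(i) {
    v <- rep("A", 40); v[i] <- "G"; paste(v, collapse = "")
  }, ""), paste0("s", 1:10))
  aln <- new_alignment(seqs)
  expect_lt(fu_li_d_star(aln)$D_star, 0)
  expect_false(fu_li_d_star(new_alignment(c(a = "AA", b = "AA", c = "AA")))$defined)

  for (rep in 1:8) {
    n <- sample(4:25, 1)
    aln <- sim_coalescent(n, 4)
    o <- oracle_seg_sites(aln_strings(aln))
    if (o$S == 0) next
    k <- oracle_k(aln_strings(aln))
    expect_equal(fu_li_d_star(aln)$D_star, ref_fu_li_d_star(n, o$eta, o$eta_s),
                 tolerance = 1e-12)
    expect_equal(fu_li_f_star(aln)$F_star,
                 ref_fu_li_f_star(n, o$eta, o$eta_s, k), tolerance = 1e-12)
  }
})

test_that("statistics are invariant to the phasing chosen for the genotypes", {
  set.seed(703)
  # small pool of similar haplotypes so genotypes stay brute-forceable
  base <- rand_dna(12)
  pool <- c(base, mutate_at(base, 1:2), mutate_at(base, 2:3))
  g <- vapply(1:4, function(i) {
    pick <- sample(3, 2, replace = TRUE)
    combine_haplotypes(pool[pick[1]], pool[pick[2]])
  }, "")
  names(g) <- paste0("g", seq_along(g))
  greedy <- phase_all(g)
  exact <- brute_force_min_haplotypes(g)$witness
  aln1 <- haplotype_alignment(greedy, locus = "x")
  seqs2 <- c(setNames(exact$hap1, paste0(exact$seq_id, ".h1")),
             setNames(exact$hap2, paste0(exact$seq_id, ".h2")))
  aln2 <- new_alignment(seqs2, locus = "x")
  for (f in list(function(a) unlist(segregating_sites(a)[c("S", "eta", "eta_s")]),
                 mean_pairwise_k, nucleotide_diversity,
                 function(a) tajimas_d(a)$D,
                 function(a) fu_li_d_star(a)$D_star,
                 function(a) fu_li_f_star(a)$F_star)) {
    expect_equal(f(aln1), f(aln2))
  }
})

test_that("locus summaries cover nested groups and render undefined cells", {
  set.seed(704)
  seqs <- setNames(replicate(8, rand_dna(30)), paste0("s", 1:8))
  seqs["s7"] <- seqs["s8"]            # an invariant pair for the S=0 group
  meta <- data.frame(seq_id = names(seqs), isolate_id = names(seqs),
                     group = "g", ecology = rep(c("N", "B"), 4))
  aln <- new_alignment(seqs, locus = "mk", meta = meta)
  groups <- list(all = paste0("s", 1:8), founders = paste0("s", 5:8),
                 clonal = c("s7", "s8"), tiny = "s1")
  sm <- locus_summary(list(mk = aln), groups)
  expect_equal(nrow(sm), 4L)
  expect_equal(sm$ecol[1], "N+B")
  # whole-dataset row equals the statistics on the pooled alignment
  expect_equal(sm$k[sm$group == "all"], mean_pairwise_k(aln))
  expect_equal(sm$theta_w[sm$group == "all"],
               watterson_theta(8, segregating_sites(aln)$S)$theta_w)
  # S = 0 group: D and friends undefined, rendered "-"
  clonal <- sm[sm$group == "clonal", ]
  expect_equal(clonal$S, 0L)
  expect_true(is.na(clonal$tajima_d))
  tbl <- format_summary_table(sm)
  expect_equal(tbl$TajimaD[sm$group == "clonal"], "-")
  expect_equal(tbl$TajimaD[sm$group == "tiny"], "-")
  # under-min_n group flagged with NA statistics
  expect_true(is.na(sm$k[sm$group == "tiny"]))
})
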