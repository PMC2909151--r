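# small, fast configurations for the forward-simulator properties
fast_cfg <- function(...) {
  args <- list(N = 80, generations = 60, L_marker = 120, L_neutral = 120,
               n_neutral_loci = 1, K_init = 4, bottleneck = NULL,
               sample_n_dikaryons = 15, clones_min = 3, clones_max = 6,
               missing_allele_prob = 0)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("configuration validation enforces the documented bounds", {
  expect_error(sim_config(N = 1), "N must be")
  expect_error(sim_config(K_init = 1), "K_init")
  expect_error(sim_config(epsilon = 1.5), "rates")
  expect_error(sim_config(clones_min = 0), "clone range")
  expect_error(sim_config(clones_min = 10, clones_max = 5), "clone range")
})

test_that("every sampled dikaryon is heteroallelic at MAT", {
  for (seed in 1:5) {
    sim <- simulate_population(fast_cfg(seed = seed))
    expect_true(all(sim$dikaryons$mat1 != sim$dikaryons$mat2))
  }
})

test_that("complete linkage without mutation keeps marker tracking MAT exactly", {
  sim <- simulate_population(fast_cfg(mu_site = 0, mu_mat = 0, r = 0,
                                      K_init = 2, seed = 42))
  haps <- apply(sim$marker_haps, 1, paste, collapse = "")
  mats <- as.vector(t(sim$dikaryons[, c("mat1", "mat2")]))
  # one-to-one map between MAT allele id and marker haplotype
  expect_true(all(tapply(haps, mats, function(h) length(unique(h))) == 1L))
  expect_true(all(tapply(mats, haps, function(m) length(unique(m))) == 1L))
})

test_that("without novel-MAT mutation the allele count never increases", {
  sim <- simulate_population(fast_cfg(mu_mat = 0, seed = 7))
  traj <- sim$truth$mat_count_trajectory
  expect_true(all(diff(traj) <= 0))
  expect_lte(max(traj), 4L)
})

test_that("clone reads are exact copies at epsilon = 0 and carry errors otherwise", {
  sim <- simulate_population(fast_cfg(epsilon = 0, seed = 3))
  for (d in seq_len(nrow(sim$dikaryons))) {
    reads <- sim$clone_reads[[d]]
    origin <- sim$truth$clone_origin[[d]]
    truth <- matdiv:::.int2char(sim$marker_haps[2 * (d - 1) + origin, , drop = FALSE])
    expect_true(all(reads == truth))
  }
  sim_e <- simulate_population(fast_cfg(epsilon = 0.05, seed = 3))
  n_err <- sum(vapply(seq_len(nrow(sim_e$dikaryons)), function(d) {
    reads <- sim_e$clone_reads[[d]]
    origin <- sim_e$truth$clone_origin[[d]]
    truth <- matdiv:::.int2char(sim_e$marker_haps[2 * (d - 1) + origin, , drop = FALSE])
    sum(reads != truth)
  }, 0))
  expect_gt(n_err, 0)
})

test_that("missing-allele masking yields the expected two-allele fraction", {
  sim <- simulate_population(fast_cfg(sample_n_dikaryons = 400, N = 100,
                                      generations = 30,
                                      missing_allele_prob = 0.47, seed = 12))
  frac_two <- mean(sim$dikaryons$n_exposed == 2L)
  expect_lt(abs(frac_two - 0.53), 0.07)   # ~2.8 sigma of binomial noise at n=400
  sim0 <- simulate_population(fast_cfg(seed = 12))
  expect_true(all(sim0$dikaryons$n_exposed == 2L))
})

test_that("identical seeds give identical simulations and emitted files", {
  cfg <- fast_cfg(seed = 77)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$marker_haps, s2$marker_haps)
  expect_identical(s1$clone_reads, s2$clone_reads)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  emit_inputs(s1, d1); emit_inputs(s2, d2)
  f <- sort(list.files(d1, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("losing MAT diversity halts with a diagnostic", {
  # no compatibility constraint, tiny population, no novel alleles:
  # fixation is certain within a few dozen generations
  expect_error(
    simulate_population(fast_cfg(compatibility = FALSE, N = 6, K_init = 2,
                                 mu_mat = 0, generations = 300, seed = 1)),
    "MAT diversity lost")
})

test_that("emitted genotypes reconstruct exactly from truth haplotypes", {
  sim <- simulate_population(fast_cfg(seed = 21, mu_site = 5e-4))
  g <- sim$genotypes[[1]]
  nm <- sim$neutral_haps[[1]]
  for (d in seq_len(nrow(sim$dikaryons))) {
    h1 <- paste(c("A", "C", "G", "T")[nm[2 * d - 1, ]], collapse = "")
    h2 <- paste(c("A", "C", "G", "T")[nm[2 * d, ]], collapse = "")
    expect_equal(combine_haplotypes(h1, h2), unname(g[d]))
  }
})

test_that("bottlenecks erode neutral richness faster than MAT richness", {
  set.seed(1001)
  retention <- replicate(40, {
    seed <- sample.int(1e6, 1)
    # MAT fixation during a tight bottleneck is possible (and halts the
    # run by design); such reps are dropped and counted
    sim <- tryCatch(simulate_population(
      sim_config(N = 100, generations = 75, L_marker = 200, L_neutral = 200,
                 n_neutral_loci = 2, K_init = 8, mu_mat = 0,
                 init_marker_divergence = 0.05, init_neutral_divergence = 0.02,
                 bottleneck = list(time = 50, size = 12, duration = 15),
                 sample_n_dikaryons = 10, missing_allele_prob = 0,
                 seed = seed)),
      error = function(e) NULL)
    if (is.null(sim)) return(c(NA_real_, NA_real_))
    pre <- sim$truth$snapshots$pre_bottleneck
    post <- sim$truth$snapshots$post_bottleneck
    c(post$mat_richness / pre$mat_richness,
      mean(post$neutral_richness / pre$neutral_richness))
  })
  ok <- colSums(is.na(retention)) == 0
  expect_gte(sum(ok), 35)
  expect_gt(mean(retention[1, ok]), mean(retention[2, ok]))
})

test_that("the no-selection control equalises marker and neutral diversity", {
  set.seed(1002)
  ratios <- replicate(60, {
    seed <- sample.int(1e6, 1)
    sim <- tryCatch(simulate_population(
      sim_config(N = 80, generations = 60, L_marker = 150, L_neutral = 150,
                 n_neutral_loci = 1, K_init = 6, mu_mat = 0.01,
                 init_marker_divergence = 0.01, init_neutral_divergence = 0.01,
                 bottleneck = NULL, sample_n_dikaryons = 15,
                 missing_allele_prob = 0, compatibility = FALSE, seed = seed)),
      error = function(e) NULL)
    if (is.null(sim)) return(NA_real_)
    s <- summarize_truth(sim)
    log(s$pi_ratio)
  })
  ratios <- ratios[is.finite(ratios)]
  expect_gt(length(ratios), 40)
  # mean log-ratio indistinguishable from 0 at the 1% level
  expect_gt(t.test(ratios)$p.value, 0.01)
})

test_that("the coalescent oracle reproduces Watterson's expectation", {
  set.seed(1003)
  S <- replicate(400, segregating_sites(sim_coalescent(12, 4))$S)
  expect_equal(mean(S), 4 * sum(1 / (1:11)), tolerance = 0.08)
  expect_error(sim_coalescent(1, 5), "n >= 2")
})
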