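# Independent oracles used by the tests. Everything here is written as a
# direct, brute-force or literal-formula route, deliberately separate from
# the package's implementation paths.

rand_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# mutate string s at 1-based positions to a different base
mutate_at <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# brute-force pairwise identity: position-by-position scan under pairwise
# deletion
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  n <- 0L; match <- 0L
  for (i in seq_along(av)) {
    if (av[i] %in% c("A", "C", "G", "T") && bv[i] %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (av[i] == bv[i]) match <- match + 1L
    }
  }
  if (n == 0L) list(identity = NA_real_, n = 0L) else list(identity = match / n, n = n)
}

# brute-force complete-deletion column set: union over sequences of
# non-ACGT columns, complemented
oracle_valid_cols <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) keep[j] <- all(m[, j] %in% c("A", "C", "G", "T"))
  which(keep)
}

# brute-force mean pairwise difference count over complete-deletion columns
oracle_k <- function(seqs) {
  vc <- oracle_valid_cols(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))[, vc, drop = FALSE]
  n <- nrow(m)
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(m[i, ] != m[j, ]); np <- np + 1L
  }
  tot / np
}

# brute-force S / eta / eta_s by per-column inspection
oracle_seg_sites <- function(seqs) {
  vc <- oracle_valid_cols(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))[, vc, drop = FALSE]
  S <- 0L; eta <- 0L; eta_s <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1L) {
      S <- S + 1L
      eta <- eta + length(tab) - 1L
      eta_s <- eta_s + min(sum(tab == 1L), length(tab) - 1L)
    }
  }
  list(S = S, eta = eta, eta_s = eta_s, L = ncol(m))
}

# literal transcription of the Tajima (1989) statistic from n, S, k
ref_tajima_d <- function(n, S, k) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# literal transcription of the Simonsen-corrected Fu & Li starred
# statistics (reference implementation for the constants cross-check)
ref_fu_li_constants <- function(n) {
  an <- 0; bn <- 0
  for (i in 1:(n - 1)) { an <- an + 1 / i; bn <- bn + 1 / i^2 }
  an1 <- an + 1 / n
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  uD <- (n / (n - 1)) * (an - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uF <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vF
  c(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF)
}

ref_fu_li_d_star <- function(n, eta, eta_s) {
  ct <- ref_fu_li_constants(n)
  ((n / (n - 1)) * eta - ct[["an"]] * eta_s) /
    sqrt(ct[["uD"]] * eta + ct[["vD"]] * eta^2)
}

ref_fu_li_f_star <- function(n, eta, eta_s, k) {
  ct <- ref_fu_li_constants(n)
  (k - ((n - 1) / n) * eta_s) / sqrt(ct[["uF"]] * eta + ct[["vF"]] * eta^2)
}

# Welch two-sample statistic straight from the closed formula
welch_hand <- function(x, y) {
  sx <- var(x) / length(x); sy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(sx + sy)
  df <- (sx + sy)^2 / (sx^2 / (length(x) - 1) + sy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# literal HKA goodness-of-fit evaluator (for the grid-search oracle)
oracle_hka_x2 <- function(data, thetas, T_div, f) {
  a1 <- function(n) sum(1 / seq_len(n - 1))
  a2 <- function(n) sum(1 / seq_len(n - 1)^2)
  x2 <- 0
  for (i in seq_len(nrow(data))) {
    ESa <- thetas[i] * a1(data$n_a[i])
    x2 <- x2 + (data$S_a[i] - ESa)^2 / (ESa + thetas[i]^2 * a2(data$n_a[i]))
    if (data$n_b[i] >= 2) {
      ESb <- f * thetas[i] * a1(data$n_b[i])
      x2 <- x2 + (data$S_b[i] - ESb)^2 / (ESb + (f * thetas[i])^2 * a2(data$n_b[i]))
    }
    Ed <- thetas[i] * (T_div + (1 + f) / 2)
    x2 <- x2 + (data$d_ab[i] - Ed)^2 / (Ed + (thetas[i] * (1 + f) / 2)^2)
  }
  x2
}

# random genotype string with n_het two-fold ambiguity sites
rand_genotype <- function(L, n_het) {
  v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (n_het > 0) {
    pos <- sample(L, n_het)
    v[pos] <- sample(names(matdiv::IUPAC2), n_het, replace = TRUE)
  }
  paste(v, collapse = "")
}

# genotypes built by pairing haplotypes drawn from a small pool: the
# regime the template-based phasing procedure is designed for
genotypes_from_pool <- function(n_haps, n_genotypes, L) {
  pool <- replicate(n_haps, rand_dna(L))
  vapply(seq_len(n_genotypes), function(i) {
    pick <- sample(n_haps, 2, replace = TRUE)
    combine_haplotypes(pool[pick[1]], pool[pick[2]])
  }, "")
}

# clone matrix: m copies of a haplotype with iid per-base errors
make_clones <- function(hap, m, eps) {
  v <- strsplit(hap, "")[[1]]
  mat <- matrix(rep(v, each = m), nrow = m)
  if (eps > 0) {
    err <- which(matrix(runif(length(mat)) < eps, nrow = m))
    for (e in err) mat[e] <- sample(setdiff(c("A", "C", "G", "T"), mat[e]), 1)
  }
  rownames(mat) <- paste0("c", seq_len(m))
  mat
}
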