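# Multilocus HKA test, two-taxon variant: within-taxon polymorphism
# (segregating sites in taxa A and B) and between-taxon divergence (mean
# pairwise difference count) at L loci are compared with neutral
# expectations under a common ancestry model with locus thetas, a
# divergence time T (units of 2 N_A generations) and a population-size
# ratio f = N_B / N_A. Goodness of fit is the classic sum of
# (obs - E)^2 / Var terms; significance comes from a coalescent-simulated
# null in which every replicate is refitted. Standard assumptions: no
# recombination within loci, free recombination between loci.

.a1 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1L))
.a2 <- function(n) if (n < 2) 0 else sum(1 / seq_len(n - 1L)^2)

#' Validate / build an HKA locus data table
#'
#' @param locus Character vector of locus names.
#' @param n_a,n_b Sample sizes in taxon A and B (n_b = 0 drops the
#'   B-polymorphism term for that locus).
#' @param S_a,S_b Segregating-site counts within each taxon.
#' @param d_ab Mean pairwise difference count between taxa.
#' @param L_valid Analysed sites per locus.
#' @return Data frame of class `hka_data`.
#' @export
hka_data <- function(locus, n_a, n_b, S_a, S_b, d_ab, L_valid = NA_integer_) {
  df <- data.frame(locus = locus, n_a = n_a, n_b = n_b, S_a = S_a, S_b = S_b,
                   d_ab = d_ab, L_valid = L_valid, stringsAsFactors = FALSE)
  if (any(df$n_a < 2)) stop("taxon A needs n_a >= 2 at every locus")
  if (any(df$n_b != 0 & df$n_b < 2)) stop("n_b must be 0 (omitted) or >= 2")
  if (any(df$S_a < 0 | df$S_b < 0 | df$d_ab < 0)) stop("counts must be >= 0")
  class(df) <- c("hka_data", "data.frame")
  df
}

#' Build HKA input from two per-taxon alignments at each locus
#'
#' @param alns_a,alns_b Named lists of `mat_alignment` (same locus names).
#' @return `hka_data` table with S from [segregating_sites()] and d_ab the
#'   mean over all cross-taxon pairs of pairwise difference counts
#'   (complete deletion applied jointly).
#' @export
hka_data_from_alignments <- function(alns_a, alns_b) {
  loci <- names(alns_a)
  if (!identical(sort(loci), sort(names(alns_b)))) stop("locus sets differ between taxa")
  rows <- lapply(loci, function(lc) {
    a <- alns_a[[lc]]; b <- alns_b[[lc]]
    if (ncol(a$mat) != ncol(b$mat)) stop("alignment lengths differ at locus ", lc)
    pooled <- rbind(a$mat, b$mat)
    ok <- matrix(pooled %in% c("A", "C", "G", "T"), nrow(pooled))
    vc <- which(apply(ok, 2L, all))
    if (!length(vc)) stop("no jointly analysable column at locus ", lc)
    am <- a$mat[, vc, drop = FALSE]; bm <- b$mat[, vc, drop = FALSE]
    dd <- mean(vapply(seq_len(nrow(am)), function(i) {
      vapply(seq_len(nrow(bm)), function(j) sum(am[i, ] != bm[j, ]), 0)
    }, numeric(nrow(bm))))
    ssa <- segregating_sites(a)
    ssb <- segregating_sites(b)
    hka_data(lc, nrow(am), nrow(bm), ssa$S, ssb$S, dd, length(vc))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hka_data", "data.frame")
  out
}

#' HKA model expectations and variances for one locus
#'
#' E[S_a] = theta a1(n_a), Var[S_a] = E[S_a] + theta^2 a2(n_a);
#' E[S_b] = f theta a1(n_b), variance analogous with f theta;
#' E[d] = theta (T + (1+f)/2), Var[d] = E[d] + (theta (1+f)/2)^2.
#'
#' @param theta Locus theta (taxon A scale).
#' @param T_div Divergence time in units of 2 N_A generations.
#' @param f Ratio of taxon-B to taxon-A effective size.
#' @param n_a,n_b Sample sizes (n_b = 0 omits the B term).
#' @return List with `E_Sa`, `V_Sa`, `E_Sb`, `V_Sb` (NA when n_b = 0),
#'   `E_d`, `V_d`.
#' @export
hka_expectations <- function(theta, T_div, f, n_a, n_b) {
  E_Sa <- theta * .a1(n_a)
  V_Sa <- E_Sa + theta^2 * .a2(n_a)
  if (n_b >= 2) {
    E_Sb <- f * theta * .a1(n_b)
    V_Sb <- E_Sb + (f * theta)^2 * .a2(n_b)
  } else {
    E_Sb <- NA_real_; V_Sb <- NA_real_
  }
  E_d <- theta * (T_div + (1 + f) / 2)
  V_d <- E_d + (theta * (1 + f) / 2)^2
  list(E_Sa = E_Sa, V_Sa = V_Sa, E_Sb = E_Sb, V_Sb = V_Sb, E_d = E_d, V_d = V_d)
}

# goodness-of-fit statistic for a parameter vector; data columns
# pre-extracted for speed (called hot inside the null simulation)
.hka_x2 <- function(thetas, T_div, f, Sa, Sb, d, a1a, a2a, a1b, a2b, useb) {
  ESa <- thetas * a1a
  VSa <- ESa + thetas^2 * a2a
  x2 <- sum((Sa - ESa)^2 / VSa)
  if (any(useb)) {
    ESb <- f * thetas[useb] * a1b[useb]
    VSb <- ESb + (f * thetas[useb])^2 * a2b[useb]
    x2 <- x2 + sum((Sb[useb] - ESb)^2 / VSb)
  }
  Ed <- thetas * (T_div + (1 + f) / 2)
  Vd <- Ed + (thetas * (1 + f) / 2)^2
  x2 + sum((d - Ed)^2 / Vd)
}

#' Fit the HKA model by minimising the goodness-of-fit statistic
#'
#' Point estimates of the locus thetas, divergence time T and size ratio f
#' by constrained numerical optimisation (log-parameterised `nlminb`),
#' started from method-of-moments values: theta_i from S_a/a1(n_a), f from
#' the ratio of pooled per-a1 polymorphism, T from mean scaled divergence.
#'
#' @param data An `hka_data` table with >= 2 loci.
#' @param mode `"two-taxon"` (default; f estimated when any n_b >= 2) or
#'   `"one-taxon"` (B polymorphism ignored, f fixed at 1).
#' @return List of class `hka_fit`: `theta_per_locus`, `T`, `f`, `x2_obs`,
#'   `mode`, `data`.
#' @export
fit_hka <- function(data, mode = c("two-taxon", "one-taxon")) {
  mode <- match.arg(mode)
  if (nrow(data) < 2L) stop("the HKA test requires >= 2 loci")
  Sa <- data$S_a; Sb <- data$S_b; d <- data$d_ab
  if (all(c(Sa, Sb, d) == 0)) stop("degenerate HKA data: all counts zero")
  a1a <- vapply(data$n_a, .a1, 0); a2a <- vapply(data$n_a, .a2, 0)
  a1b <- vapply(data$n_b, .a1, 0); a2b <- vapply(data$n_b, .a2, 0)
  useb <- mode == "two-taxon" & data$n_b >= 2
  est_f <- any(useb)
  nl <- nrow(data)
  theta0 <- pmax(Sa / a1a, 0.05)
  f0 <- if (est_f) max(sum(Sb[useb]) / sum(a1b[useb]), 0.025) /
    max(sum(Sa) / sum(a1a), 0.025) else 1
  f0 <- min(max(f0, 1e-2), 1e2)
  T0 <- max(mean(d / theta0) - (1 + f0) / 2, 0.05)
  obj <- function(p) {
    thetas <- exp(p[seq_len(nl)])
    T_div <- exp(p[nl + 1L])
    f <- if (est_f) exp(p[nl + 2L]) else 1
    .hka_x2(thetas, T_div, f, Sa, Sb, d, a1a, a2a, a1b, a2b, useb)
  }
  p0 <- c(log(theta0), log(T0), if (est_f) log(f0))
  opt <- stats::nlminb(p0, obj, control = list(iter.max = 300, eval.max = 600))
  thetas <- exp(opt$par[seq_len(nl)])
  structure(list(theta_per_locus = setNames(thetas, data$locus),
                 T = exp(opt$par[nl + 1L]),
                 f = if (est_f) exp(opt$par[nl + 2L]) else 1,
                 x2_obs = opt$objective, mode = mode,
                 convergence = opt$convergence, data = data),
            class = "hka_fit")
}

# total coalescent branch length for n samples, in units of 2N
.coal_branch_length <- function(n) {
  j <- n:2
  sum(j * stats::rexp(length(j), rate = j * (j - 1) / 2))
}

#' Simulate the HKA null distribution of the fit statistic
#'
#' Per replicate and locus, polymorphism counts are drawn by Poisson
#' mutation over simulated coalescent branch lengths (theta_i for taxon A,
#' f theta_i for taxon B) and divergence by Poisson mutation over
#' T plus an exponential two-lineage ancestral coalescence of mean
#' (1+f)/2; the model is refitted on every replicate.
#'
#' @param fit An `hka_fit`.
#' @param n_sims Number of replicates (>= 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of simulated x2 values.
#' @export
hka_null_simulate <- function(fit, n_sims = 1000L, seed = NULL) {
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  thetas <- fit$theta_per_locus; T_div <- fit$T; f <- fit$f
  nl <- nrow(data)
  vapply(seq_len(n_sims), function(rep) {
    sim <- data
    for (i in seq_len(nl)) {
      sim$S_a[i] <- stats::rpois(1L, thetas[i] * .coal_branch_length(data$n_a[i]) / 2)
      sim$S_b[i] <- if (data$n_b[i] >= 2)
        stats::rpois(1L, f * thetas[i] * .coal_branch_length(data$n_b[i]) / 2) else 0L
      t_anc <- stats::rexp(1L, rate = 2 / (1 + f))
      sim$d_ab[i] <- stats::rpois(1L, thetas[i] * (T_div + t_anc))
    }
    if (all(c(sim$S_a, sim$S_b, sim$d_ab) == 0)) return(0)
    fit_hka(sim, mode = fit$mode)$x2_obs
  }, 0)
}

#' Run the full HKA test
#'
#' Fits the model, simulates the null with refitting, and reports
#' p = fraction of simulated x2 >= observed x2.
#'
#' @param data An `hka_data` table.
#' @param n_sims Null replicates (default 1000).
#' @param seed Optional integer seed (stored in the result).
#' @param mode See [fit_hka()].
#' @return `hka_fit` with `p_value`, `n_sims`, `seed` and `x2_null` added.
#' @export
hka_test <- function(data, n_sims = 1000L, seed = NULL, mode = "two-taxon") {
  fit <- fit_hka(data, mode = mode)
  x2_null <- hka_null_simulate(fit, n_sims = n_sims, seed = seed)
  fit$x2_null <- x2_null
  fit$p_value <- mean(x2_null >= fit$x2_obs)
  fit$n_sims <- as.integer(n_sims)
  fit$seed <- seed
  fit
}

#' @export
print.hka_fit <- function(x, ...) {
  cat("HKA fit (", x$mode, "): x2 =", format(x$x2_obs, digits = 5),
      "T =", format(x$T, digits = 4), "f =", format(x$f, digits = 4), "\n")
  cat("thetas:", paste(sprintf("%s=%.3f", names(x$theta_per_locus),
                               x$theta_per_locus), collapse = ", "), "\n")
  if (!is.null(x$p_value)) {
    cat("p =", format(x$p_value, digits = 4), "(", x$n_sims, "simulations )\n")
  }
  invisible(x)
}
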