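# Within-dikaryon allele divergence test. In founder populations with few
# mating-type alleles, the two marker alleles co-occurring in a dikaryon
# are expected to be more divergent (less similar) than random allele
# pairs, because mating requires different MAT alleles and the marker is
# linked to MAT. The test compares mean pairwise similarity within
# individuals to mean similarity across individuals by a two-sample
# unequal-variance (Welch) t test, with a seeded permutation test as a
# distribution-free safeguard against the non-independence of across
# pairs.

#' Pairwise similarity matrix of an allele alignment
#'
#' Symmetric matrix of pairwise identities (pairwise deletion), diagonal 1.
#'
#' @param alleles A `mat_alignment` with >= 2 members.
#' @return Numeric matrix with dimnames = allele ids.
#' @export
similarity_matrix <- function(alleles) {
  m <- alleles$mat
  n <- nrow(m)
  if (n < 2L) stop("similarity matrix requires >= 2 alleles")
  out <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[i, j] <- out[j, i] <- pairwise_identity(m[i, ], m[j, ])$identity
    }
  }
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Build an allele-pair table
#'
#' @param isolate_id,allele1,allele2,group Equal-length vectors; allele ids
#'   must be distinct within a pair.
#' @return Data frame of class `allele_pairs`.
#' @export
allele_pairs <- function(isolate_id, allele1, allele2, group = "all") {
  df <- data.frame(isolate_id = isolate_id, allele1 = allele1,
                   allele2 = allele2, group = group, stringsAsFactors = FALSE)
  if (any(df$allele1 == df$allele2)) stop("allele pair with identical ids")
  class(df) <- c("allele_pairs", "data.frame")
  df
}

# map allele id -> isolate from a pairs table plus optional singleton info
.allele_isolates <- function(pairs, singletons = NULL) {
  m <- c(setNames(pairs$isolate_id, pairs$allele1),
         setNames(pairs$isolate_id, pairs$allele2))
  if (!is.null(singletons)) {
    m <- c(m, setNames(singletons$isolate_id, singletons$allele_id))
  }
  m[!duplicated(names(m))]
}

#' Split similarities into within- and across-individual sets
#'
#' Within = one similarity per isolate with exactly two alleles in the
#' group. Across = similarities of all allele pairs whose members come
#' from different isolates of the group; alleles from single-allele
#' isolates (given via `singletons`) join only the across set when
#' `include_singletons` is TRUE.
#'
#' @param sim_mat Matrix from [similarity_matrix()].
#' @param pairs An `allele_pairs` table.
#' @param group Group to analyse (NULL = all pairs).
#' @param singletons Optional data frame (allele_id, isolate_id, group) of
#'   single-allele isolates.
#' @param include_singletons Include singleton alleles in the across set
#'   (default TRUE).
#' @return List with `within`, `across` (numeric vectors) and the allele
#'   ids used.
#' @export
within_across_split <- function(sim_mat, pairs, group = NULL,
                                singletons = NULL, include_singletons = TRUE) {
  if (!is.null(group)) {
    pairs <- pairs[pairs$group == group, , drop = FALSE]
    if (!is.null(singletons)) {
      singletons <- singletons[singletons$group == group, , drop = FALSE]
    }
  }
  if (nrow(pairs) == 0L) stop("no within-individual allele pair in group ",
                              if (is.null(group)) "(all)" else group)
  ids <- unique(c(pairs$allele1, pairs$allele2))
  if (include_singletons && !is.null(singletons)) {
    ids <- unique(c(ids, singletons$allele_id))
  }
  miss <- setdiff(ids, rownames(sim_mat))
  if (length(miss)) stop("allele id(s) absent from similarity matrix: ",
                         paste(miss, collapse = ", "))
  iso <- .allele_isolates(pairs, if (include_singletons) singletons)
  within <- vapply(seq_len(nrow(pairs)), function(r) {
    sim_mat[pairs$allele1[r], pairs$allele2[r]]
  }, 0)
  across <- numeric(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1L):length(ids)) {
      if (iso[[ids[i]]] != iso[[ids[j]]]) {
        across <- c(across, sim_mat[ids[i], ids[j]])
      }
    }
  }
  if (length(across) == 0L) {
    stop("no across-individual allele pair in group ",
         if (is.null(group)) "(all)" else group,
         " (a single isolate cannot be tested)")
  }
  list(within = within, across = across, allele_ids = ids)
}

#' Two-sample unequal-variance (Welch) t test
#'
#' Thin, flag-aware wrapper over `stats::t.test(var.equal = FALSE)`; the
#' degenerate case of zero variance in both samples is caught and
#' reported as an undefined statistic rather than an error.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param alternative "two.sided" (default), "less" or "greater" (of
#'   mean(x) relative to mean(y)).
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`, `defined`.
#' @export
welch_t_test <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop("Welch test needs >= 2 values per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  mean_x = mean(x), mean_y = mean(y), defined = FALSE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_,
                p = 0, mean_x = mean(x), mean_y = mean(y), defined = TRUE))
  }
  tt <- stats::t.test(x, y, alternative = alternative, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y), defined = TRUE)
}

#' Permutation test of within- vs across-individual similarity
#'
#' The null is built by re-pairing the group's alleles at random into
#' pseudo-isolates, preserving the number of within pairs; the statistic
#' is |mean within - mean across|. The reported p includes the observed
#' arrangement in the null set: p = (1 + #{perm >= obs}) / (1 + n_perm).
#'
#' @inheritParams within_across_split
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return List with `p`, `observed`, `n_perm`.
#' @export
permutation_test <- function(sim_mat, pairs, group = NULL, singletons = NULL,
                             include_singletons = TRUE, n_perm = 999L,
                             seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs_split <- within_across_split(sim_mat, pairs, group, singletons,
                                   include_singletons)
  stat <- function(w, a) abs(mean(w) - mean(a))
  observed <- stat(obs_split$within, obs_split$across)
  ids <- obs_split$allele_ids
  n_pairs <- length(obs_split$within)
  sub <- sim_mat[ids, ids, drop = FALSE]
  nid <- length(ids)
  ut <- upper.tri(sub)
  total_sum <- sum(sub[ut])
  total_n <- sum(ut)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(nid)
    w_idx1 <- perm[seq_len(n_pairs) * 2L - 1L]
    w_idx2 <- perm[seq_len(n_pairs) * 2L]
    w <- sub[cbind(w_idx1, w_idx2)]
    # across = every unordered pair except the pseudo-within ones
    a_mean <- (total_sum - sum(w)) / (total_n - n_pairs)
    if (stat(w, rep(a_mean, 1L)) >= observed) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + n_perm), observed = observed, n_perm = n_perm)
}

#' Run the within-dikaryon divergence test per group
#'
#' @param sim_mat Matrix from [similarity_matrix()].
#' @param pairs An `allele_pairs` table.
#' @param groups Character vector of groups to test (default: all groups
#'   present in `pairs`); empty vector yields an empty table.
#' @param singletons,include_singletons See [within_across_split()].
#' @param n_perm Permutations for the permutation p (0 disables it).
#' @param seed Optional integer seed for the permutation tests.
#' @param alternative Sidedness of the Welch test (default two-sided;
#'   direction is reported separately).
#' @return Data frame with one row per group: group, n_within, n_across,
#'   mean_within_similarity, mean_across_similarity, t_statistic, df,
#'   p_value, p_permutation, direction, method.
#' @export
run_group_tests <- function(sim_mat, pairs, groups = NULL, singletons = NULL,
                            include_singletons = TRUE, n_perm = 999L,
                            seed = NULL, alternative = "two.sided") {
  if (is.null(groups)) groups <- unique(pairs$group)
  cols <- c("group", "n_within", "n_across", "mean_within_similarity",
            "mean_across_similarity", "t_statistic", "df", "p_value",
            "p_permutation", "direction", "method")
  if (length(groups) == 0L) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    sp <- within_across_split(sim_mat, pairs, g, singletons, include_singletons)
    wt <- welch_t_test(sp$within, sp$across, alternative)
    pp <- if (n_perm > 0L) {
      permutation_test(sim_mat, pairs, g, singletons, include_singletons,
                       n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else seed + gi)$p
    } else NA_real_
    data.frame(group = g, n_within = length(sp$within),
               n_across = length(sp$across),
               mean_within_similarity = mean(sp$within),
               mean_across_similarity = mean(sp$across),
               t_statistic = wt$t, df = wt$df, p_value = wt$p,
               p_permutation = pp,
               direction = if (isTRUE(mean(sp$within) < mean(sp$across)))
                 "within-more-divergent" else "within-less-divergent",
               method = "welch_t", stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
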