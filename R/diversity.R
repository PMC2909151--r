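# Per-alignment molecular variation and neutrality statistics in the
# DnaSP convention: complete deletion (columns with any gap, N or
# ambiguity code dropped), per-locus Watterson theta = S / a1(n),
# Tajima's D from S and mean pairwise differences k, and the outgroup-free
# Fu & Li D* / F* with the Simonsen-corrected constants.

#' Neutrality-test constants for sample size n
#'
#' The standard harmonic-number machinery behind Watterson's theta and
#' Tajima's D: a1 = sum 1/i, a2 = sum 1/i^2 (i = 1..n-1),
#' b1 = (n+1)/(3(n-1)), b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2+a2).
#'
#' @param n Number of sequences, n >= 2.
#' @return Named list of constants.
#' @export
neutrality_constants <- function(n) {
  if (n < 2) stop("neutrality constants require n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# integer-coded matrix of the complete-deletion columns (rows = seqs);
# values 1..4 for A,C,G,T
.valid_int_matrix <- function(aln) {
  vc <- valid_columns(aln)
  if (!length(vc)) stop("no columns survive complete deletion")
  m <- aln$mat[, vc, drop = FALSE]
  storage.mode(m) <- "character"
  im <- matrix(match(m, .BASES), nrow(m))
  im
}

# per-column base counts (4 x L matrix) from an integer-coded matrix
.col_counts <- function(im) {
  apply(im, 2L, tabulate, nbins = 4L)
}

#' Segregating sites, total and singleton mutation counts
#'
#' Complete deletion first. S counts polymorphic columns; eta counts
#' mutations as (distinct bases - 1) summed over columns; eta_s counts
#' singleton mutations, i.e. variant bases carried by exactly one
#' sequence (capped per column at the mutation count, so a 2-sequence
#' polymorphic column contributes one singleton, not two).
#'
#' @param aln A `mat_alignment` of phased (unambiguous) sequences, n >= 2.
#' @return List with `S`, `eta`, `eta_s` and `L_valid`.
#' @export
segregating_sites <- function(aln) {
  if (n_seqs(aln) < 2L) stop("segregating sites require >= 2 sequences")
  im <- .valid_int_matrix(aln)
  cc <- .col_counts(im)
  kinds <- colSums(cc > 0L)
  S <- sum(kinds > 1L)
  eta <- sum(pmax(kinds - 1L, 0L))
  singles <- colSums(cc == 1L)
  eta_s <- sum(pmin(singles, pmax(kinds - 1L, 0L)))
  list(S = as.integer(S), eta = as.integer(eta), eta_s = as.integer(eta_s),
       L_valid = ncol(im))
}

# k from per-column counts: mean pairwise differences over all C(n,2)
# pairs, complete-deletion columns
.k_from_counts <- function(cc, n) {
  same <- colSums(cc * (cc - 1L)) / (n * (n - 1L))
  sum(1 - same)
}

#' Mean pairwise difference count k
#'
#' Average over all sequence pairs of the number of differing positions,
#' computed on the complete-deletion columns.
#'
#' @param aln A `mat_alignment`, n >= 2.
#' @return Numeric k.
#' @export
mean_pairwise_k <- function(aln) {
  if (n_seqs(aln) < 2L) stop("k requires >= 2 sequences")
  im <- .valid_int_matrix(aln)
  .k_from_counts(.col_counts(im), nrow(im))
}

#' Nucleotide diversity pi
#'
#' k normalised per analysed (complete-deletion) site.
#'
#' @param aln A `mat_alignment`, n >= 2.
#' @return Numeric pi.
#' @export
nucleotide_diversity <- function(aln) {
  if (n_seqs(aln) < 2L) stop("pi requires >= 2 sequences")
  im <- .valid_int_matrix(aln)
  .k_from_counts(.col_counts(im), nrow(im)) / ncol(im)
}

#' Watterson's theta (per locus)
#'
#' theta_W = S / a1(n). The per-site variant is theta_W / L.
#'
#' @param n Number of sequences (n >= 2).
#' @param S Number of segregating sites.
#' @param L_valid Optional analysed-site count; when given, `theta_w_site`
#'   is also returned.
#' @return List with `theta_w` and (optionally) `theta_w_site`.
#' @export
watterson_theta <- function(n, S, L_valid = NULL) {
  if (n < 2) stop("Watterson's theta requires n >= 2")
  if (S < 0) stop("S must be >= 0")
  th <- S / neutrality_constants(n)$a1
  out <- list(theta_w = th)
  if (!is.null(L_valid)) out$theta_w_site <- th / L_valid
  out
}

#' Tajima's D
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S-1)). Undefined (NA with flag)
#' when S = 0, matching the "-" entries of summary tables.
#'
#' @param aln A `mat_alignment`, n >= 2.
#' @return List with `D` (NA when undefined) and `defined`.
#' @export
tajimas_d <- function(aln) {
  if (n_seqs(aln) < 2L) stop("Tajima's D requires >= 2 sequences")
  im <- .valid_int_matrix(aln)
  cc <- .col_counts(im)
  n <- nrow(im)
  kinds <- colSums(cc > 0L)
  S <- sum(kinds > 1L)
  if (S == 0L) return(list(D = NA_real_, defined = FALSE))
  k <- .k_from_counts(cc, n)
  ct <- neutrality_constants(n)
  D <- (k - S / ct$a1) / sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
  list(D = D, defined = TRUE)
}

# Simonsen-corrected constants for the starred Fu & Li statistics
.fu_li_constants <- function(n) {
  i <- seq_len(n - 1L)
  an <- sum(1 / i)
  bn <- sum(1 / i^2)
  an1 <- an + 1 / n                       # a_{n+1}
  cn <- if (n == 2L) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vd <- ((n / (n - 1))^2 * bn + an^2 * dn -
           2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  ud <- (n / (n - 1)) * (an - n / (n - 1)) - vd
  vf <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * bn - 6 + 8 / n)) / (an^2 + bn)
  uf <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
           (2 * (n + 1) / (n - 1)^2) * (an1 - 2 * n / (n + 1))) / an - vf
  list(an = an, bn = bn, ud = ud, vd = vd, uf = uf, vf = vf)
}

#' Fu & Li's D* (no outgroup)
#'
#' D* contrasts total mutations eta with singleton mutations eta_s:
#' D* = ((n/(n-1)) eta - a_n eta_s) / sqrt(u_D* eta + v_D* eta^2), with
#' the Simonsen-corrected variance constants. Undefined when S = 0.
#'
#' @param aln A `mat_alignment`, n >= 3 (constants degenerate below).
#' @return List with `D_star` and `defined`.
#' @export
fu_li_d_star <- function(aln) {
  n <- n_seqs(aln)
  if (n < 3L) stop("Fu & Li's D* requires >= 3 sequences")
  ss <- segregating_sites(aln)
  if (ss$S == 0L) return(list(D_star = NA_real_, defined = FALSE))
  ct <- .fu_li_constants(n)
  num <- (n / (n - 1)) * ss$eta - ct$an * ss$eta_s
  den <- sqrt(ct$ud * ss$eta + ct$vd * ss$eta^2)
  list(D_star = num / den, defined = TRUE)
}

#' Fu & Li's F* (no outgroup)
#'
#' F* contrasts mean pairwise differences k with singletons:
#' F* = (k - ((n-1)/n) eta_s) / sqrt(u_F* eta + v_F* eta^2), with the
#' Simonsen-corrected constants. Undefined when S = 0.
#'
#' @param aln A `mat_alignment`, n >= 3.
#' @return List with `F_star` and `defined`.
#' @export
fu_li_f_star <- function(aln) {
  n <- n_seqs(aln)
  if (n < 3L) stop("Fu & Li's F* requires >= 3 sequences")
  ss <- segregating_sites(aln)
  if (ss$S == 0L) return(list(F_star = NA_real_, defined = FALSE))
  k <- mean_pairwise_k(aln)
  ct <- .fu_li_constants(n)
  num <- k - ((n - 1) / n) * ss$eta_s
  den <- sqrt(ct$uf * ss$eta + ct$vf * ss$eta^2)
  list(F_star = num / den, defined = TRUE)
}

#' All per-locus statistics for one alignment
#'
#' @param aln A `mat_alignment` of phased sequences.
#' @return One-row data frame: n, S, eta, eta_s, k, pi, theta_w,
#'   theta_w_site, tajima_d, fu_li_d_star, fu_li_f_star, L_valid.
#'   Statistics that are undefined (S = 0, or n below a test's minimum)
#'   are NA.
#' @export
locus_stats <- function(aln) {
  n <- n_seqs(aln)
  ss <- segregating_sites(aln)
  k <- mean_pairwise_k(aln)
  pi <- k / ss$L_valid
  tw <- watterson_theta(n, ss$S, ss$L_valid)
  td <- if (ss$S > 0L) tajimas_d(aln)$D else NA_real_
  ds <- if (ss$S > 0L && n >= 3L) fu_li_d_star(aln)$D_star else NA_real_
  fs <- if (ss$S > 0L && n >= 3L) fu_li_f_star(aln)$F_star else NA_real_
  data.frame(n = n, S = ss$S, eta = ss$eta, eta_s = ss$eta_s, k = k, pi = pi,
             theta_w = tw$theta_w, theta_w_site = tw$theta_w_site,
             tajima_d = td, fu_li_d_star = ds, fu_li_f_star = fs,
             L_valid = ss$L_valid)
}

.ecology_label <- function(eco) {
  eco <- unique(eco[!is.na(eco) & eco != "unknown"])
  if (length(eco) == 0L) "unknown"
  else if (setequal(eco, "N")) "N"
  else if (setequal(eco, "B")) "B"
  else "N+B"
}

#' Per-locus, per-group summary table
#'
#' One row per locus x group, in the style of a molecular-variation
#' summary table. Groups may nest (e.g. a species containing a variety
#' containing a geographic subgroup); each group is just a named id set.
#'
#' @param alignments Named list of `mat_alignment` objects (names = loci),
#'   or a single alignment.
#' @param groups Named list: group name -> character vector of seq ids
#'   (per locus the intersection with that locus's members is used). When
#'   NULL, one "all" group per locus.
#' @param min_n Groups with fewer sequences at a locus are emitted as
#'   flagged rows with NA statistics (default 2).
#' @return Data frame with columns locus, group, ecol, n, S, eta, eta_s,
#'   k, pi, theta_w, tajima_d, fu_li_d_star, fu_li_f_star, L_valid.
#' @export
locus_summary <- function(alignments, groups = NULL, min_n = 2L) {
  if (inherits(alignments, "mat_alignment")) {
    alignments <- setNames(list(alignments), alignments$locus)
  }
  rows <- list()
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    grp <- groups
    if (is.null(grp)) grp <- list(all = rownames(aln$mat))
    for (gname in names(grp)) {
      ids <- intersect(grp[[gname]], rownames(aln$mat))
      if (length(ids) < min_n) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, group = gname, ecol = "unknown", n = length(ids),
          S = NA_integer_, eta = NA_integer_, eta_s = NA_integer_,
          k = NA_real_, pi = NA_real_, theta_w = NA_real_,
          tajima_d = NA_real_, fu_li_d_star = NA_real_,
          fu_li_f_star = NA_real_, L_valid = NA_integer_,
          stringsAsFactors = FALSE)
        next
      }
      sub <- aln_subset(aln, ids)
      st <- locus_stats(sub)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(locus = locus, group = gname,
                   ecol = .ecology_label(sub$meta$ecology),
                   stringsAsFactors = FALSE),
        st[, c("n", "S", "eta", "eta_s", "k", "pi", "theta_w", "tajima_d",
               "fu_li_d_star", "fu_li_f_star", "L_valid")])
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Render a locus summary in summary-table format
#'
#' Tab-separated columns Locus, Group, Ecol, #, S, k, pi, ThetaW, TajimaD,
#' FuLiDstar, FuLiFstar with undefined values rendered "-".
#'
#' @param summary Data frame from [locus_summary()].
#' @param path Optional output path; when given the TSV is written there.
#' @param digits Rounding for the real-valued columns (default 4).
#' @return The formatted data frame, invisibly when `path` is given.
#' @export
format_summary_table <- function(summary, path = NULL, digits = 4L) {
  fmt <- function(x) ifelse(is.na(x), "-", format(round(x, digits),
                                                  trim = TRUE, scientific = FALSE))
  out <- data.frame(Locus = summary$locus, Group = summary$group,
                    Ecol = summary$ecol, "#" = summary$n, S = fmt(summary$S),
                    k = fmt(summary$k), pi = fmt(summary$pi),
                    ThetaW = fmt(summary$theta_w),
                    TajimaD = fmt(summary$tajima_d),
                    FuLiDstar = fmt(summary$fu_li_d_star),
                    FuLiFstar = fmt(summary$fu_li_f_star),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
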