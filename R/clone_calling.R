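# Clone-based allele calling. A dikaryotic isolate yields a set of cloned
# amplicon sequences (3-20 per isolate); the true 1-4 alleles are
# reconstructed by single-linkage clustering of the clones followed by
# per-cluster consensus with PCR-artifact filtering:
#   m >= 3 clones: a variant carried by exactly one clone is autapomorphic
#                  and discarded as an in-vitro PCR mutation;
#   m == 2 clones: sites where the two copies differ become the two-fold
#                  IUPAC ambiguity code (assumed heterozygosity);
#   m == 1 clone : accepted verbatim.

#' Construct a clone set
#'
#' @param clones A `mat_alignment` of cloned sequences from one isolate at
#'   one locus (all clones equal length).
#' @param isolate_id Isolate identifier.
#' @param locus_name Locus name (defaults to the alignment's locus).
#' @return Object of class `clone_set`.
#' @export
clone_set <- function(clones, isolate_id, locus_name = clones$locus) {
  stopifnot(inherits(clones, "mat_alignment"))
  if (n_seqs(clones) < 1L) stop("clone set must contain at least one clone")
  structure(list(isolate_id = isolate_id, clones = clones,
                 locus_name = locus_name),
            class = "clone_set")
}

#' Partition clones into allele groups by single-linkage clustering
#'
#' Distance is 1 - pairwise identity (pairwise deletion). Two clones land
#' in the same group iff they are connected by a chain of pairs each at
#' distance <= `threshold` (connected components of the threshold graph),
#' which is exactly single linkage cut at `threshold`. Groups are labelled
#' deterministically by their lowest clone index.
#'
#' @param cs A `clone_set`.
#' @param threshold Distance threshold in (0,1); default 0.02, well below
#'   the between-allele divergence of the MAT-linked marker and well above
#'   PCR-error-scale within-allele variation.
#' @return List of integer vectors (1-based clone indices), ordered by
#'   smallest member index.
#' @export
cluster_clones <- function(cs, threshold = 0.02) {
  stopifnot(inherits(cs, "clone_set"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  m <- cs$clones$mat
  n <- nrow(m)
  if (n == 1L) return(list(1L))
  # adjacency under chain-distance threshold
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- pairwise_identity(m[i, ], m[j, ])
      d <- if (is.na(pid$identity)) 1 else 1 - pid$identity
      adj[i, j] <- adj[j, i] <- d <= threshold
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      stack <- i
      while (length(stack)) {
        v <- stack[[1L]]; stack <- stack[-1L]
        if (comp[v] == 0L) {
          comp[v] <- cur
          stack <- c(stack, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  groups <- split(seq_len(n), comp)
  groups <- groups[order(vapply(groups, min, 0L))]
  unname(lapply(groups, as.integer))
}

#' Consensus allele from one clone group
#'
#' Applies the m-dependent filtering rules (see module header). With
#' m >= 3, a column where the (post-discard) top count is tied is resolved
#' to the alphabetically first base and the position is logged in
#' `tie_positions` as having ambiguous support.
#'
#' @param group A `mat_alignment` holding the m clones of one allele group.
#' @return An `allele_call`: list with `seq` (character string),
#'   `support` (clone count), `discarded_singleton_positions`,
#'   `ambiguity_positions`, `tie_positions` (all 0-based column indices)
#'   and `rule_applied`.
#' @export
consensus_call <- function(group) {
  stopifnot(inherits(group, "mat_alignment"))
  m <- group$mat
  n <- nrow(m)
  L <- ncol(m)
  if (n == 1L) {
    return(structure(list(seq = paste(m[1L, ], collapse = ""), support = 1L,
                          discarded_singleton_positions = integer(0),
                          ambiguity_positions = integer(0),
                          tie_positions = integer(0),
                          rule_applied = "single-copy"),
                     class = "allele_call"))
  }
  if (n == 2L) {
    out <- m[1L, ]
    amb <- integer(0)
    for (j in seq_len(L)) {
      x <- m[1L, j]; y <- m[2L, j]
      if (x == y) next
      if (x %in% .BASES && y %in% .BASES) {
        out[j] <- .iupac_rev[[paste(sort(c(x, y)), collapse = "")]]
        amb <- c(amb, j - 1L)
      } else {
        # one copy missing/gapped: keep the determinate base if any
        out[j] <- if (x %in% .BASES) x else if (y %in% .BASES) y else "N"
      }
    }
    return(structure(list(seq = paste(out, collapse = ""), support = 2L,
                          discarded_singleton_positions = integer(0),
                          ambiguity_positions = amb,
                          tie_positions = integer(0),
                          rule_applied = "two-copy-het"),
                     class = "allele_call"))
  }
  out <- character(L)
  discarded <- integer(0)
  ties <- integer(0)
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[col != "N"]           # missing never votes
    ct <- sort(table(col), decreasing = TRUE)
    if (length(ct) == 1L) { out[j] <- names(ct); next }
    # autapomorphy rule: single-clone variants are PCR artifacts, provided
    # some state has real (>= 2 clone) support
    if (any(ct >= 2L)) {
      singles <- names(ct)[ct == 1L]
      if (length(singles)) discarded <- c(discarded, j - 1L)
      ct <- ct[ct >= 2L]
    }
    top <- max(ct)
    cand <- sort(names(ct)[ct == top])          # '-' sorts before letters
    cand_bases <- cand[cand %in% .BASES]
    if (length(cand) > 1L) {
      ties <- c(ties, j - 1L)
      out[j] <- if (length(cand_bases)) cand_bases[1L] else cand[1L]
    } else {
      out[j] <- cand[1L]
    }
  }
  structure(list(seq = paste(out, collapse = ""), support = n,
                 discarded_singleton_positions = unique(discarded),
                 ambiguity_positions = integer(0),
                 tie_positions = ties,
                 rule_applied = "majority-consensus"),
            class = "allele_call")
}

#' Call the alleles of one isolate from its clone set
#'
#' Clusters the clones, builds one consensus per group, and orders calls
#' by descending support, ties by lexicographic sequence. Call ids are
#' `<isolate>.a1`, `<isolate>.a2`, ...
#'
#' @param cs A `clone_set`.
#' @param threshold Clustering threshold, see [cluster_clones()].
#' @return An `allele_call_set`: list with `isolate_id`, `locus_name`,
#'   `calls` (list of `allele_call`, each with an `id` field added) and
#'   `n_clusters`.
#' @export
call_alleles <- function(cs, threshold = 0.02) {
  groups <- cluster_clones(cs, threshold)
  calls <- lapply(groups, function(idx) {
    g <- structure(list(locus = cs$locus_name,
                        mat = cs$clones$mat[idx, , drop = FALSE],
                        meta = cs$clones$meta[idx, , drop = FALSE]),
                   class = "mat_alignment")
    cc <- consensus_call(g)
    cc$clone_indices <- idx
    cc
  })
  ord <- order(-vapply(calls, `[[`, 0L, "support"),
               vapply(calls, `[[`, "", "seq"))
  calls <- calls[ord]
  for (i in seq_along(calls)) calls[[i]]$id <- sprintf("%s.a%d", cs$isolate_id, i)
  structure(list(isolate_id = cs$isolate_id, locus_name = cs$locus_name,
                 calls = calls, n_clusters = length(calls)),
            class = "allele_call_set")
}

#' Call alleles for many isolates and collect outputs
#'
#' @param clone_sets List of `clone_set` objects.
#' @param threshold Clustering threshold.
#' @return List with `alleles` (a `mat_alignment` of all called alleles,
#'   isolate ids attached), `audit` (data frame of per-call filtering
#'   records) and `call_sets`.
#' @export
call_alleles_all <- function(clone_sets, threshold = 0.02) {
  call_sets <- lapply(clone_sets, call_alleles, threshold = threshold)
  seqs <- character(0)
  meta <- list()
  audit <- list()
  for (acs in call_sets) {
    for (cc in acs$calls) {
      seqs[[cc$id]] <- cc$seq
      meta[[cc$id]] <- data.frame(seq_id = cc$id, isolate_id = acs$isolate_id,
                                  stringsAsFactors = FALSE)
      audit[[cc$id]] <- data.frame(
        seq_id = cc$id, isolate_id = acs$isolate_id, support = cc$support,
        rule_applied = cc$rule_applied,
        discarded_singleton_positions =
          paste(cc$discarded_singleton_positions, collapse = ","),
        ambiguity_positions = paste(cc$ambiguity_positions, collapse = ","),
        tie_positions = paste(cc$tie_positions, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  locus <- if (length(call_sets)) call_sets[[1L]]$locus_name else "locus"
  list(alleles = new_alignment(seqs, locus = locus,
                               meta = do.call(rbind, meta)),
       audit = do.call(rbind, c(audit, list(make.row.names = FALSE))),
       call_sets = call_sets)
}
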