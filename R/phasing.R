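# Haplotype phase inference for genotype sequences carrying two-fold IUPAC
# heterozygous sites, by the template-then-parsimony procedure that yields
# a (greedily) minimal number of distinct haplotypes: sequences homozygous
# everywhere or heterozygous at a single site are forced and seed the
# template set; multi-heterozygous sequences are assigned to known
# templates whenever possible, otherwise the phasing minimising mutational
# steps (Hamming distance to the nearest templates) is inferred. All
# tie-breaks are fixed (lexicographically smallest haplotype pair) so the
# procedure is deterministic. Known caveat, kept deliberately: the
# procedure may undercount haplotypes when recombinant genotypes occur.

.het_positions <- function(res) which(res %in% names(IUPAC2))

.res_vec <- function(g) {
  if (length(g) == 1L && nchar(g) > 1L) strsplit(toupper(g), "", fixed = TRUE)[[1L]]
  else toupper(g)
}

#' Heterozygous positions of a genotype sequence
#' @param g Genotype sequence (string) possibly containing two-fold IUPAC
#'   ambiguity codes.
#' @return Integer vector of 0-based column indices.
#' @export
het_positions <- function(g) .het_positions(.res_vec(g)) - 1L

# expand one genotype residue vector into the two ordered base choices at
# each het site; returns list(res, het_idx, choices) where choices[k, ] are
# the alphabetically sorted bases at het site k
.genotype_parts <- function(g) {
  res <- .res_vec(g)
  bad <- setdiff(res[!(res %in% c(.BASES, "N", "-"))], names(IUPAC2))
  if (length(bad)) stop("genotype contains non-two-fold code(s): ", paste(bad, collapse = ", "))
  het <- .het_positions(res)
  ch <- if (length(het)) {
    t(vapply(res[het], function(code) strsplit(IUPAC2[[code]], "")[[1L]], character(2)))
  } else matrix(character(0), 0, 2)
  list(res = res, het = het, choices = ch)
}

# all complementary phasings of a genotype: 2^(h-1) unordered pairs.
# Returns a list of c(hap1, hap2) string pairs, each pair sorted.
.enumerate_phasings <- function(g) {
  p <- .genotype_parts(g)
  h <- length(p$het)
  if (h == 0L) {
    s <- paste(p$res, collapse = "")
    return(list(c(s, s)))
  }
  nfree <- h - 1L
  out <- vector("list", 2^nfree)
  for (mask in 0:(2^nfree - 1L)) {
    a <- p$res; b <- p$res
    # first het site fixed: hap a takes the smaller base (kills the
    # hap-order symmetry)
    a[p$het[1L]] <- p$choices[1L, 1L]
    b[p$het[1L]] <- p$choices[1L, 2L]
    if (h > 1L) for (k in 2:h) {
      bit <- bitwAnd(bitwShiftR(mask, k - 2L), 1L)
      a[p$het[k]] <- p$choices[k, 1L + bit]
      b[p$het[k]] <- p$choices[k, 2L - bit]
    }
    pr <- sort(c(paste(a, collapse = ""), paste(b, collapse = "")))
    out[[mask + 1L]] <- pr
  }
  out
}

#' Recombine a haplotype pair into its genotype
#'
#' Site-wise union: equal bases stay; differing unambiguous bases become
#' the two-fold IUPAC code. This is the inverse of phasing and backs the
#' recombination invariant.
#'
#' @param h1,h2 Unambiguous haplotype strings of equal length.
#' @return Genotype string.
#' @export
combine_haplotypes <- function(h1, h2) {
  a <- .res_vec(h1); b <- .res_vec(h2)
  if (length(a) != length(b)) stop("haplotype length mismatch")
  out <- a
  diffc <- which(a != b)
  for (j in diffc) {
    if (a[j] %in% .BASES && b[j] %in% .BASES) {
      out[j] <- .iupac_rev[[paste(sort(c(a[j], b[j])), collapse = "")]]
    } else stop("cannot combine non-base residues at column ", j)
  }
  paste(out, collapse = "")
}

#' Forced haplotypes from 0- and 1-het genotypes
#'
#' Genotypes homozygous at all sites contribute themselves twice; a single
#' heterozygous site forces both resolutions. These "known putative
#' haplotypes" seed the template set for multi-site phasing.
#'
#' @param genotypes Named character vector (or list) of genotype strings.
#' @return List with `haplotypes` (named integer multiplicities),
#'   `assignments` (data frame seq_id, hap1, hap2, provenance) covering the
#'   forced genotypes only, and `unresolved` (ids with >= 2 het sites).
#' @export
known_haplotypes <- function(genotypes) {
  genotypes <- unlist(genotypes)
  if (is.null(names(genotypes)) && length(genotypes))
    names(genotypes) <- paste0("g", seq_along(genotypes))
  haps <- integer(0)
  rows <- list()
  unresolved <- character(0)
  for (id in names(genotypes)) {
    h <- length(het_positions(genotypes[[id]]))
    if (h <= 1L) {
      pr <- .enumerate_phasings(genotypes[[id]])[[1L]]
      for (s in pr) haps[s] <- (if (is.na(haps[s])) 0L else haps[s]) + 1L
      rows[[id]] <- data.frame(seq_id = id, hap1 = pr[1L], hap2 = pr[2L],
                               provenance = "forced", stringsAsFactors = FALSE)
    } else {
      unresolved <- c(unresolved, id)
    }
  }
  list(haplotypes = haps,
       assignments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       unresolved = unresolved)
}

.min_hamming <- function(s, templates) {
  if (!length(templates)) return(NA_real_)
  v <- .res_vec(s)
  min(vapply(templates, function(tp) sum(v != .res_vec(tp)), 0))
}

#' Phase one multi-heterozygous genotype against a template set
#'
#' Among the 2^(h-1) complementary phasings the choice is, in order of
#' preference: (1) both haplotypes already known templates; (2) exactly one
#' a template, partner at minimum Hamming distance from its nearest
#' template; (3) minimum summed Hamming distance of both haplotypes to
#' their nearest templates. Ties at every stage resolve to the
#' lexicographically smallest (sorted) haplotype pair; with an empty
#' template set the lexicographic rule alone decides.
#'
#' @param g Genotype string with >= 2 het sites (fewer is allowed; the
#'   choice is then forced).
#' @param templates Character vector of known haplotype sequences.
#' @param max_het Enumeration guard; genotypes with more het sites error
#'   with instructions to raise the cap explicitly.
#' @return List with `pair` (sorted character pair) and `provenance`
#'   (`"forced"`, `"template-matched"` or `"parsimony-inferred"`).
#' @export
phase_sequence <- function(g, templates = character(0), max_het = 20L) {
  h <- length(het_positions(g))
  if (h > max_het) {
    stop("genotype has ", h, " heterozygous sites, above the enumeration cap (",
         max_het, "); pass a larger max_het to force exhaustive enumeration")
  }
  phs <- .enumerate_phasings(g)
  if (h <= 1L) return(list(pair = phs[[1L]], provenance = "forced"))
  templates <- unique(templates)
  in_t <- lapply(phs, function(pr) pr %in% templates)
  n_in <- vapply(in_t, sum, 0L)
  pick_lex <- function(cand) cand[[order(vapply(cand, paste, "", collapse = "\r"))[1L]]]
  if (any(n_in == 2L)) {
    return(list(pair = pick_lex(phs[n_in == 2L]), provenance = "template-matched"))
  }
  if (any(n_in == 1L)) {
    cand <- phs[n_in == 1L]
    partner_d <- vapply(cand, function(pr) {
      partner <- pr[!(pr %in% templates)][1L]
      .min_hamming(partner, templates)
    }, 0)
    cand <- cand[partner_d == min(partner_d)]
    return(list(pair = pick_lex(cand), provenance = "template-matched"))
  }
  if (length(templates)) {
    total_d <- vapply(phs, function(pr) {
      .min_hamming(pr[1L], templates) + .min_hamming(pr[2L], templates)
    }, 0)
    phs <- phs[total_d == min(total_d)]
  }
  list(pair = pick_lex(phs), provenance = "parsimony-inferred")
}

#' Phase a set of genotype sequences
#'
#' Processes genotypes in ascending het-site count (ties by input order);
#' every resolved haplotype immediately joins the template set. Each
#' genotype contributes two haplotype copies to the multiplicity table, so
#' a sample of n dikaryon-derived genotypes yields 2n haplotypes.
#'
#' @param genotypes Named character vector of genotype strings.
#' @param max_het Per-genotype enumeration cap, see [phase_sequence()].
#' @return Object of class `haplotype_set`: list with `haplotypes` (named
#'   integer multiplicities), `assignments` (data frame seq_id, hap1,
#'   hap2, provenance, in input order) and `n_distinct`.
#' @export
phase_all <- function(genotypes, max_het = 20L) {
  genotypes <- unlist(genotypes)
  if (length(genotypes) == 0L) {
    return(structure(list(haplotypes = integer(0),
                          assignments = data.frame(seq_id = character(0),
                                                   hap1 = character(0),
                                                   hap2 = character(0),
                                                   provenance = character(0)),
                          n_distinct = 0L),
                     class = "haplotype_set"))
  }
  if (is.null(names(genotypes))) names(genotypes) <- paste0("g", seq_along(genotypes))
  if (anyDuplicated(names(genotypes))) stop("duplicate genotype seq_id")
  hcounts <- vapply(genotypes, function(g) length(het_positions(g)), 0L)
  ord <- order(hcounts)                      # stable: ties keep input order
  haps <- integer(0)
  rows <- vector("list", length(genotypes))
  for (i in ord) {
    id <- names(genotypes)[i]
    res <- phase_sequence(genotypes[[i]], templates = names(haps), max_het = max_het)
    for (s in res$pair) haps[s] <- (if (is.na(haps[s])) 0L else haps[s]) + 1L
    rows[[i]] <- data.frame(seq_id = id, hap1 = res$pair[1L], hap2 = res$pair[2L],
                            provenance = res$provenance, stringsAsFactors = FALSE)
  }
  structure(list(haplotypes = haps,
                 assignments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 n_distinct = length(haps)),
            class = "haplotype_set")
}

#' Haplotype alignment from a phased set
#'
#' Expands a `haplotype_set` into a `mat_alignment` of 2n haplotype
#' sequences (ids `<seq_id>.h1` / `.h2`), carrying the genotype's isolate
#' and group labels when a meta table is supplied.
#'
#' @param hs A `haplotype_set`.
#' @param locus Locus name.
#' @param meta Optional meta data frame keyed by genotype `seq_id`.
#' @return A `mat_alignment`.
#' @export
haplotype_alignment <- function(hs, locus = "locus", meta = NULL) {
  asg <- hs$assignments
  seqs <- c(setNames(asg$hap1, paste0(asg$seq_id, ".h1")),
            setNames(asg$hap2, paste0(asg$seq_id, ".h2")))
  seqs <- seqs[order(names(seqs))]
  m2 <- NULL
  if (!is.null(meta)) {
    idx <- match(sub("\\.h[12]$", "", names(seqs)), meta$seq_id)
    m2 <- meta[idx, , drop = FALSE]
    m2$seq_id <- names(seqs)
  }
  new_alignment(seqs, locus = locus, meta = m2)
}

#' Exhaustive minimum-haplotype search (test oracle)
#'
#' Enumerates every joint phasing of all genotypes and returns the global
#' minimum number of distinct haplotypes with one witness assignment. The
#' search space is the product of per-genotype phasing counts and is
#' guarded by `max_combos`.
#'
#' @param genotypes Named character vector of genotype strings.
#' @param max_combos Upper bound on enumerated joint phasings (default
#'   65536).
#' @return List with `min_count` and `witness` (data frame seq_id, hap1,
#'   hap2).
#' @export
brute_force_min_haplotypes <- function(genotypes, max_combos = 65536L) {
  genotypes <- unlist(genotypes)
  if (length(genotypes) == 0L) return(list(min_count = 0L, witness = NULL))
  if (is.null(names(genotypes))) names(genotypes) <- paste0("g", seq_along(genotypes))
  options_per <- lapply(genotypes, .enumerate_phasings)
  sizes <- vapply(options_per, length, 0L)
  if (prod(sizes) > max_combos) {
    stop("joint phasing space (", prod(sizes), ") exceeds max_combos (", max_combos, ")")
  }
  grid <- do.call(expand.grid, c(lapply(sizes, seq_len), list(KEEP.OUT.ATTRS = FALSE)))
  best <- Inf; best_row <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- mapply(function(opts, k) opts[[k]], options_per, unlist(grid[r, ]),
                  SIMPLIFY = FALSE)
    cnt <- length(unique(unlist(sel)))
    if (cnt < best) { best <- cnt; best_row <- sel }
  }
  witness <- data.frame(seq_id = names(genotypes),
                        hap1 = vapply(best_row, `[`, "", 1L),
                        hap2 = vapply(best_row, `[`, "", 2L),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(min_count = as.integer(best), witness = witness)
}
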