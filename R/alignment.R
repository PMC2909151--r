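# Core alignment data model: aligned sequences with isolate/group/ecology
# labels, FASTA + sample-sheet I/O, site classification and pairwise
# distance primitives. Coordinates are 0-based half-open internally;
# report rendering is 1-based inclusive.

#' Two-fold IUPAC ambiguity codes
#'
#' Named character vector mapping each two-fold IUPAC ambiguity code
#' (R, Y, S, W, K, M) to the two bases it denotes, in alphabetical order.
#'
#' @format Named character vector of length 6.
#' @export
IUPAC2 <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

# reverse lookup: "AG" -> "R" etc.
.iupac_rev <- setNames(names(IUPAC2), IUPAC2)

.ALLOWED <- c("A", "C", "G", "T", "N", "-", names(IUPAC2))
.BASES <- c("A", "C", "G", "T")

#' Construct an alignment
#'
#' An alignment is the unit all downstream statistics consume: a set of
#' equal-length, uppercase aligned sequences with optional per-sequence
#' isolate, group and ecology labels. Ecology uses the field convention
#' N = nature, B = building.
#'
#' @param seqs Named character vector of aligned sequences (equal length),
#'   or a character matrix (rows = sequences, rownames = ids).
#' @param locus Locus name.
#' @param meta Optional data frame with columns `seq_id` and any of
#'   `isolate_id`, `group`, `ecology`; matched to sequences by `seq_id`.
#' @return Object of class `mat_alignment`: a list with elements `locus`,
#'   `mat` (character matrix, rows = sequences), and `meta`.
#' @export
new_alignment <- function(seqs, locus = "locus", meta = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  } else {
    if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- names(seqs)[lens != lens[1L]]
      stop("alignment length mismatch: sequence(s) ", paste(bad, collapse = ", "),
           " differ in length from ", names(seqs)[1L])
    }
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) stop("alignment must have >= 1 sequence and >= 1 column")
  if (anyDuplicated(rownames(m))) {
    stop("duplicate seq_id in alignment: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  bad <- setdiff(unique(as.vector(m)), .ALLOWED)
  if (length(bad)) stop("disallowed residue(s) in alignment: ", paste(bad, collapse = ", "))
  ids <- rownames(m)
  full_meta <- data.frame(seq_id = ids, isolate_id = NA_character_,
                          group = NA_character_, ecology = "unknown",
                          stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"seq_id" %in% names(meta)) stop("meta must contain a seq_id column")
    idx <- match(ids, meta$seq_id)
    for (col in intersect(c("isolate_id", "group", "ecology"), names(meta))) {
      hit <- !is.na(idx)
      full_meta[[col]][hit] <- as.character(meta[[col]][idx[hit]])
    }
  }
  structure(list(locus = locus, mat = m, meta = full_meta),
            class = "mat_alignment")
}

#' @export
print.mat_alignment <- function(x, ...) {
  cat(sprintf("<mat_alignment> locus=%s: %d sequences x %d columns\n",
              x$locus, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Number of sequences / columns in an alignment
#' @param aln A `mat_alignment`.
#' @return Integer.
#' @export
n_seqs <- function(aln) nrow(aln$mat)

#' @rdname n_seqs
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Extract aligned sequences as strings
#' @param aln A `mat_alignment`.
#' @return Named character vector.
#' @export
aln_strings <- function(aln) {
  setNames(apply(aln$mat, 1L, paste, collapse = ""), rownames(aln$mat))
}

#' Subset an alignment by sequence ids
#' @param aln A `mat_alignment`.
#' @param ids Character vector of seq ids (must all be present).
#' @return A `mat_alignment` with the selected members, original order of `ids`.
#' @export
aln_subset <- function(aln, ids) {
  miss <- setdiff(ids, rownames(aln$mat))
  if (length(miss)) stop("seq_id not in alignment: ", paste(miss, collapse = ", "))
  m <- aln$mat[ids, , drop = FALSE]
  meta <- aln$meta[match(ids, aln$meta$seq_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(locus = aln$locus, mat = m, meta = meta), class = "mat_alignment")
}

#' Read a sample sheet
#'
#' Headered TSV with columns `seq_id`, `isolate_id`, `locus`, `group`,
#' `ecology`. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("seq_id", "isolate_id", "locus", "group", "ecology")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read an aligned FASTA file
#'
#' Records must share one length (it is an alignment, not a read set). If a
#' sample sheet is supplied every record id must appear in it; isolate,
#' group and ecology labels are attached from it.
#'
#' @param path FASTA file path.
#' @param sample_sheet Optional data frame from [read_sample_sheet()].
#' @param locus Locus name; defaults to the file name without extension.
#' @return A `mat_alignment`.
#' @export
read_fasta <- function(path, sample_sheet = NULL, locus = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("malformed FASTA in ", path, ": no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (is.null(locus)) locus <- sub("\\.[^.]*$", "", basename(path))
  meta <- NULL
  if (!is.null(sample_sheet)) {
    missing_ids <- setdiff(names(seqs), sample_sheet$seq_id)
    if (length(missing_ids)) {
      stop("seq_id(s) absent from sample sheet: ", paste(missing_ids, collapse = ", "))
    }
    meta <- sample_sheet
  }
  new_alignment(seqs, locus = locus, meta = meta)
}

#' Write an alignment to FASTA (60-column wrap)
#' @param aln A `mat_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  set <- Biostrings::BStringSet(aln_strings(aln))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Classify alignment columns
#'
#' One record per column: segregation state, gap/missing/ambiguity flags
#' and per-base allele counts. Under complete deletion, a column containing
#' any gap, `N` or IUPAC ambiguity code in any sequence is flagged
#' `excluded` for the diversity statistics (ambiguity codes are treated as
#' missing before phasing; statistics are meant to run on phased
#' haplotypes).
#'
#' @param aln A `mat_alignment`.
#' @param deletion `"complete"` (default) or `"pairwise-none"` (nothing
#'   excluded; pairwise ops handle gaps per pair).
#' @return Data frame with columns `column_index` (0-based), `state`,
#'   `has_gap`, `has_missing`, `has_ambiguity`, `excluded`, and a
#'   list-column `allele_counts` of named integer vectors over A,C,G,T.
#' @export
classify_sites <- function(aln, deletion = c("complete", "pairwise-none")) {
  deletion <- match.arg(deletion)
  m <- aln$mat
  L <- ncol(m)
  counts <- lapply(seq_len(L), function(j) {
    col <- m[, j]
    tab <- table(factor(col[col %in% .BASES], levels = .BASES))
    as.integer(tab) -> v
    setNames(v, .BASES)
  })
  has_gap <- apply(m == "-", 2L, any)
  has_missing <- apply(m == "N", 2L, any)
  has_amb <- apply(matrix(m %in% names(IUPAC2), nrow(m)), 2L, any)
  n_alleles <- vapply(counts, function(ct) sum(ct > 0L), 0L)
  state <- ifelse(n_alleles <= 1L, "monomorphic",
                  ifelse(n_alleles == 2L, "biallelic", "multiallelic"))
  excluded <- if (deletion == "complete") has_gap | has_missing | has_amb else
    rep(FALSE, L)
  out <- data.frame(column_index = seq_len(L) - 1L, state = state,
                    has_gap = has_gap, has_missing = has_missing,
                    has_ambiguity = has_amb, excluded = excluded,
                    stringsAsFactors = FALSE)
  out$allele_counts <- counts
  out
}

#' Columns retained under complete deletion
#'
#' @param aln A `mat_alignment`.
#' @return Integer vector of 1-based column indices where every sequence
#'   carries an unambiguous base (A/C/G/T).
#' @export
valid_columns <- function(aln) {
  ok <- matrix(aln$mat %in% .BASES, nrow(aln$mat))
  which(apply(ok, 2L, all))
}

.pair_prep <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("pairwise comparison requires equal lengths (", length(a), " vs ", length(b), ")")
  }
  list(a = a, b = b, ok = a %in% .BASES & b %in% .BASES)
}

#' Pairwise identity under pairwise deletion
#'
#' Identity is the fraction of matching positions among positions where
#' both sequences carry an unambiguous non-gap base; gap-vs-gap and any
#' position involving `-`, `N` or an ambiguity code is not compared.
#'
#' @param a,b Sequences: single strings or character vectors of residues.
#' @return List with `identity` (NA if no comparable site) and
#'   `sites_compared`.
#' @export
pairwise_identity <- function(a, b) {
  p <- .pair_prep(a, b)
  n <- sum(p$ok)
  if (n == 0L) return(list(identity = NA_real_, sites_compared = 0L))
  list(identity = sum(p$a[p$ok] == p$b[p$ok]) / n, sites_compared = n)
}

#' Pairwise difference count under pairwise deletion
#' @inheritParams pairwise_identity
#' @return List with `differences` (NA if no comparable site) and
#'   `sites_compared`.
#' @export
pairwise_differences <- function(a, b) {
  p <- .pair_prep(a, b)
  n <- sum(p$ok)
  if (n == 0L) return(list(differences = NA_integer_, sites_compared = 0L))
  list(differences = sum(p$a[p$ok] != p$b[p$ok]), sites_compared = n)
}
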