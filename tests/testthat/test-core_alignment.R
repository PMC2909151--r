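test_that("FASTA round-trip preserves ids and residues, invalid input is rejected", {
  aln <- new_alignment(c(s1 = "ACGTACGTAC", s2 = "ACGTRCGT-C", s3 = "ACNTACGTAC"),
                       locus = "toy")
  tf <- tempfile(fileext = ".fasta")
  write_fasta(aln, tf)
  back <- read_fasta(tf, locus = "toy")
  expect_identical(aln_strings(back), aln_strings(aln))
  expect_equal(n_seqs(back), 3L)

  expect_error(new_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTACG")),
               "length mismatch")
  expect_error(new_alignment(setNames(c("ACGT", "ACGT"), c("a", "a"))),
               "duplicate")
  expect_error(new_alignment(c(a = "ACXT")), "disallowed")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("sample sheet attaches labels and rejects unknown sequences", {
  sheet <- data.frame(seq_id = c("s1", "s2"), isolate_id = c("i1", "i1"),
                      locus = "toy", group = "Europe", ecology = c("B", "N"))
  tf <- tempfile(fileext = ".fasta")
  write_fasta(new_alignment(c(s1 = "ACGT", s2 = "ACGA")), tf)
  aln <- read_fasta(tf, sample_sheet = sheet)
  expect_equal(aln$meta$group, c("Europe", "Europe"))
  expect_equal(aln$meta$ecology, c("B", "N"))

  write_fasta(new_alignment(c(s1 = "ACGT", sX = "ACGA")), tf)
  expect_error(read_fasta(tf, sample_sheet = sheet), "absent from sample sheet")
})

test_that("site classification states, flags and complete-deletion exclusion", {
  aln <- new_alignment(c(a = "AAAGA", b = "AA-GT", c = "GACGN"))
  cs <- classify_sites(aln)
  expect_equal(cs$state, c("biallelic", "monomorphic", "biallelic",
                           "monomorphic", "biallelic"))
  expect_equal(cs$has_gap, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(cs$has_missing, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(cs$excluded, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(cs$allele_counts[[1]], c(A = 2L, C = 0L, G = 1L, T = 0L))
  # counts sum to the number of sequences scored at the column
  expect_true(all(vapply(cs$allele_counts, sum, 0L) ==
                    c(3L, 3L, 2L, 3L, 2L)))
  expect_false(any(classify_sites(aln, "pairwise-none")$excluded))
})

test_that("complete-deletion exclusion equals the brute-force union of bad columns", {
  set.seed(401)
  for (rep in 1:20) {
    n <- sample(3:8, 1); L <- sample(10:40, 1)
    seqs <- replicate(n, {
      v <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      bad <- sample(L, sample(0:3, 1))
      v[bad] <- sample(c("-", "N"), length(bad), replace = TRUE)
      paste(v, collapse = "")
    })
    names(seqs) <- paste0("s", 1:n)
    aln <- new_alignment(seqs)
    expect_identical(valid_columns(aln), oracle_valid_cols(seqs))
  }
})

test_that("pairwise identity and differences agree with direct position scans", {
  expect_equal(pairwise_identity("ACGT", "ACGT")$identity, 1.0)
  pid <- pairwise_identity("ACGT", "ACGA")
  expect_equal(pid$identity, 0.75)
  expect_equal(pid$sites_compared, 4L)
  # gap columns drop out under pairwise deletion
  pid <- pairwise_identity("AC-T", "ACGT")
  expect_equal(pid$identity, 1.0)
  expect_equal(pid$sites_compared, 3L)

  expect_equal(pairwise_differences("ACGT", "ACGT")$differences, 0L)
  expect_equal(pairwise_differences("ACGT", "ACGA")$differences, 1L)
  pd <- pairwise_differences("ACGT", "TGCA")
  expect_equal(pd$differences, pd$sites_compared)

  expect_error(pairwise_identity("ACG", "ACGT"), "equal lengths")
  expect_equal(pairwise_identity("--NN", "ACGT")$sites_compared, 0L)
  expect_true(is.na(pairwise_identity("--NN", "ACGT")$identity))
})

test_that("identity/difference complementarity and symmetry hold on random pairs", {
  set.seed(402)
  for (rep in 1:30) {
    L <- sample(5:60, 1)
    mk <- function() {
      v <- sample(c("A", "C", "G", "T", "-", "N", "R", "Y"), L, replace = TRUE,
                  prob = c(rep(0.22, 4), 0.05, 0.04, 0.02, 0.01))
      paste(v, collapse = "")
    }
    a <- mk(); b <- mk()
    pid <- pairwise_identity(a, b)
    pd <- pairwise_differences(a, b)
    orc <- oracle_identity(a, b)
    expect_equal(pid$identity, orc$identity)
    expect_equal(pid$sites_compared, orc$n)
    expect_equal(pairwise_identity(b, a)$identity, pid$identity)
    if (pid$sites_compared > 0) {
      expect_equal(pid$identity + pd$differences / pd$sites_compared, 1.0)
    }
  }
})
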