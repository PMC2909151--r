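# End-to-end orchestration: simulate (or load) inputs, call alleles from
# clone reads, phase neutral genotypes, tabulate per-locus statistics,
# run the HKA and within-dikaryon tests, and write a report bundle. Every
# output file starts with a header comment carrying the package version,
# the run seed and a config hash, so identical configs reproduce
# identical files.

.pkg_version <- function() as.character(utils::packageVersion("matdiv"))

#' Hash a configuration
#' @param config Any R object.
#' @return MD5 string of its deparsed form.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

.stamp <- function(seed, hash) {
  sprintf("# matdiv %s | seed=%s | config=%s", .pkg_version(),
          if (is.null(seed)) "NA" else seed, hash)
}

.write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param out_dir Output directory for the report bundle.
#' @param sim A `sim_config` (stage `simulate` on) or NULL.
#' @param input_dir Directory of precomputed inputs (stage `simulate`
#'   off): the file set written by [emit_inputs()].
#' @param stages Named logical vector toggling `simulate`, `call_alleles`,
#'   `phase`, `stats`, `hka`, `dikaryon`. The HKA stage needs a second
#'   taxon and therefore runs through [run_hka_stage()] on the outputs of
#'   two pipeline runs; the toggle is recorded in the report either way.
#' @param clone_threshold Clone clustering threshold.
#' @param n_sims HKA null replicates.
#' @param n_perm Permutations for the dikaryon test.
#' @param alpha Significance level recorded in the report.
#' @param seed Integer seed governing the stochastic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, input_dir = NULL,
                       stages = c(simulate = TRUE, call_alleles = TRUE,
                                  phase = TRUE, stats = TRUE, hka = FALSE,
                                  dikaryon = TRUE),
                       clone_threshold = 0.02, n_sims = 1000L, n_perm = 999L,
                       alpha = 0.05, seed = 1L) {
  if (isTRUE(stages[["simulate"]]) && is.null(sim)) {
    stop("config error: stage 'simulate' is on but no sim_config given")
  }
  if (!isTRUE(stages[["simulate"]])) {
    if (is.null(input_dir)) stop("config error: stage 'simulate' is off but no input_dir given")
    if (!dir.exists(input_dir)) stop("config error: input_dir does not exist: ", input_dir)
  }
  structure(list(out_dir = out_dir, sim = sim, input_dir = input_dir,
                 stages = stages, clone_threshold = clone_threshold,
                 n_sims = as.integer(n_sims), n_perm = as.integer(n_perm),
                 alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

.load_inputs <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  marker <- read_fasta(file.path(dir, "marker_alleles.fasta"),
                       sample_sheet = sheet, locus = "marker")
  gfiles <- list.files(dir, pattern = "_genotypes\\.fasta$", full.names = TRUE)
  genotypes <- lapply(gfiles, function(p) {
    aln <- read_fasta(p, locus = sub("_genotypes$", "", sub("\\.fasta$", "", basename(p))))
    aln_strings(aln)
  })
  names(genotypes) <- vapply(gfiles, function(p)
    sub("_genotypes\\.fasta$", "", basename(p)), "")
  cfiles <- list.files(file.path(dir, "clones"), pattern = "\\.fasta$",
                       full.names = TRUE)
  clone_sets <- lapply(cfiles, function(p) {
    iso <- sub("_marker\\.fasta$", "", basename(p))
    clone_set(read_fasta(p, locus = "marker"), isolate_id = iso)
  })
  pairs_df <- utils::read.delim(file.path(dir, "allele_pairs.tsv"),
                                stringsAsFactors = FALSE, comment.char = "#")
  list(sheet = sheet, marker = marker, genotypes = genotypes,
       clone_sets = clone_sets, pairs = pairs_df)
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate -> call-alleles -> phase -> stats -> hka ->
#' dikaryon-test -> report. A failing stage aborts with an error naming
#' the stage. Re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the stage results and written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash excludes the output location so identical analyses written to
  # different directories produce identical files
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  stamp <- .stamp(config$seed, hash)
  on_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(config = config, paths = list())
  st <- config$stages

  if (isTRUE(st[["simulate"]])) {
    sim <- on_stage("simulate", {
      sc <- config$sim
      sc$seed <- config$seed
      simulate_population(sc)
    })
    input_dir <- file.path(config$out_dir, "inputs")
    on_stage("simulate", emit_inputs(sim, input_dir))
    res$sim <- sim
  } else {
    input_dir <- config$input_dir
  }
  inputs <- on_stage("load", .load_inputs(input_dir))
  res$inputs <- inputs

  if (isTRUE(st[["call_alleles"]])) {
    called <- on_stage("call-alleles",
                       call_alleles_all(inputs$clone_sets,
                                        threshold = config$clone_threshold))
    res$called <- called
    p <- file.path(config$out_dir, "called_alleles.fasta")
    write_fasta(called$alleles, p)
    res$paths$called_alleles <- p
    res$paths$call_audit <- .write_stamped_tsv(
      called$audit, file.path(config$out_dir, "call_audit.tsv"), stamp)
  }

  if (isTRUE(st[["phase"]])) {
    phased <- on_stage("phase", lapply(inputs$genotypes, phase_all))
    res$phased <- phased
    audit <- do.call(rbind, lapply(names(phased), function(lc) {
      cbind(locus = lc, phased[[lc]]$assignments)
    }))
    res$paths$phase_audit <- .write_stamped_tsv(
      audit, file.path(config$out_dir, "phase_audit.tsv"), stamp)
  }

  if (isTRUE(st[["stats"]])) {
    alns <- on_stage("stats", {
      out <- list(marker = inputs$marker)
      if (!is.null(res$phased)) {
        for (lc in names(res$phased)) {
          out[[lc]] <- haplotype_alignment(res$phased[[lc]], locus = lc)
        }
      }
      out
    })
    summary <- on_stage("stats", locus_summary(alns))
    res$summary <- summary
    tbl <- format_summary_table(summary)
    res$paths$summary <- .write_stamped_tsv(
      tbl, file.path(config$out_dir, "locus_summary.tsv"), stamp)
  }

  if (isTRUE(st[["dikaryon"]])) {
    dik <- on_stage("dikaryon-test", {
      sim_mat <- similarity_matrix(inputs$marker)
      pr <- allele_pairs(inputs$pairs$isolate_id, inputs$pairs$allele1,
                         inputs$pairs$allele2, inputs$pairs$group)
      paired_iso <- unique(pr$isolate_id)
      mk <- inputs$marker$meta
      singles <- mk[!(mk$isolate_id %in% paired_iso), c("seq_id", "isolate_id", "group")]
      names(singles)[1L] <- "allele_id"
      run_group_tests(sim_mat, pr, singletons = singles,
                      n_perm = config$n_perm, seed = config$seed)
    })
    res$dikaryon <- dik
    res$paths$dikaryon <- .write_stamped_tsv(
      dik, file.path(config$out_dir, "dikaryon_test.tsv"), stamp)
  }

  report <- list(version = .pkg_version(), seed = config$seed,
                 config_hash = hash,
                 stages_run = names(st)[vapply(st, isTRUE, TRUE)])
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  res$paths$report <- file.path(config$out_dir, "run_report.json")
  invisible(res)
}

#' Run an HKA test from pipeline outputs of two taxa
#'
#' Convenience wrapper: builds the per-locus HKA table from two named
#' alignment lists (one per taxon) and runs [hka_test()], writing a
#' stamped TSV + JSON report.
#'
#' @param alns_a,alns_b Named lists of `mat_alignment` per locus.
#' @param out_dir Output directory (NULL = no files).
#' @param n_sims,seed Passed to [hka_test()].
#' @return The `hka_fit`.
#' @export
run_hka_stage <- function(alns_a, alns_b, out_dir = NULL, n_sims = 1000L,
                          seed = 1L) {
  data <- hka_data_from_alignments(alns_a, alns_b)
  fit <- hka_test(data, n_sims = n_sims, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- .stamp(seed, config_hash(list(data = data, n_sims = n_sims)))
    .write_stamped_tsv(cbind(data, theta = fit$theta_per_locus),
                       file.path(out_dir, "hka_input.tsv"), stamp)
    jsonlite::write_json(list(x2_obs = fit$x2_obs, p_value = fit$p_value,
                              T = fit$T, f = fit$f, n_sims = n_sims,
                              seed = seed),
                         file.path(out_dir, "hka_result.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  fit
}
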