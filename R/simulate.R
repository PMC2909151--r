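# Forward simulator of a haploid Wright-Fisher population with a
# mating-type (MAT A) locus under mechanical rare-allele advantage: every
# offspring is produced by two parents that must carry different MAT
# alleles, so rare alleles enjoy a mating advantage without any explicit
# selection coefficient. A marker locus is linked to MAT (recombination
# fraction r per meiosis, default 0), further loci assort freely and
# evolve neutrally. Finite-sites Jukes-Cantor mutation keeps real
# polymorphism and PCR clone errors distinguishable by multiplicity. A
# founder bottleneck emulates the recent range expansion of the study
# system; sampled dikaryons yield IUPAC-coded neutral genotypes and
# PCR-error clone reads of the marker, i.e. every input the analysis
# pipeline consumes, together with a full truth record.
#
# Simplifications, kept deliberate: MAT B is omitted (compatibility at one
# locus only), generations are discrete with mating only at reproduction,
# and the K_init founder MAT lineages carry pre-diverged marker
# haplotypes, standing in for the deep (trans-species) coalescence of
# balanced allele lineages that forward time at these scales cannot
# produce.

.int2char <- function(im) {
  m <- matrix(.BASES[im], nrow(im))
  rownames(m) <- rownames(im)
  m
}

# Jukes-Cantor mutation sprinkled over an integer-coded matrix
.mutate_matrix <- function(im, mu) {
  n_mut <- stats::rpois(1L, length(im) * mu)
  if (n_mut == 0L) return(im)
  pos <- sample.int(length(im), n_mut, replace = TRUE)
  im[pos] <- ((im[pos] - 1L + sample(1:3, n_mut, replace = TRUE)) %% 4L) + 1L
  im
}

# derive a haplotype at the given per-site divergence from an ancestor
.diverge <- function(anc, div) {
  L <- length(anc)
  k <- stats::rbinom(1L, L, div)
  if (k > 0L) {
    pos <- sample.int(L, k)
    anc[pos] <- ((anc[pos] - 1L + sample(1:3, k, replace = TRUE)) %% 4L) + 1L
  }
  anc
}

#' Simulation configuration
#'
#' Defaults describe the emulated study system: a ~860 bp MAT-linked
#' marker completely linked (r = 0) to a MAT locus with 10 founder
#' alleles, three unlinked ~600 bp neutral loci, a founder bottleneck, 40
#' sampled dikaryons with 3-20 marker clone reads each at per-base PCR
#' error 0.002, and a 47% chance that a dikaryon exposes only one marker
#' allele (emulating the insertion-driven amplification failure of the
#' study system, where only 53% of dikaryons yielded two alleles).
#'
#' @param N Haploid population size.
#' @param generations Number of forward generations.
#' @param mu_site Per-site per-generation mutation rate.
#' @param L_marker,L_neutral Marker / neutral locus lengths (bp).
#' @param n_neutral_loci Number of unlinked neutral loci.
#' @param mu_mat Per-birth probability of a novel MAT allele
#'   (infinite-alleles).
#' @param r Recombination fraction between MAT and the marker per meiosis.
#' @param K_init Founder MAT allele count (>= 2).
#' @param init_marker_divergence Per-site divergence among founder marker
#'   haplotypes (deep balanced-lineage divergence).
#' @param init_neutral_divergence Per-site divergence among founder
#'   neutral haplotypes (standing neutral variation).
#' @param n_founder_haps Founder haplotype pool size per neutral locus.
#' @param bottleneck List (time, size, duration) or NULL for none.
#' @param sample_n_dikaryons Dikaryons sampled at the end.
#' @param clones_min,clones_max Clone reads per isolate (uniform draw).
#' @param epsilon Per-base clone (PCR) error rate.
#' @param missing_allele_prob Probability a dikaryon exposes only one
#'   marker allele.
#' @param compatibility If FALSE, reproduction ignores MAT (no-selection
#'   control); dikaryon sampling still requires heteroallelism.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @param init_seed Seed for the founder haplotype construction only
#'   (default: `seed`). Two runs sharing `init_seed` but differing in
#'   `seed` start from the same ancestral MAT lineages and founder pools
#'   and then evolve independently -- a pair of sister populations whose
#'   balanced marker lineages are trans-specifically shared.
#' @param fixed_divergence Per-site probability of a population-specific
#'   fixed substitution applied to every neutral founder haplotype
#'   (default 0). With a shared `init_seed`, this models the neutral
#'   divergence accrued since a taxon split, while the balanced marker
#'   lineages stay shared (trans-species polymorphism): two sister
#'   populations end up about `2 * fixed_divergence` apart at neutral
#'   loci.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(N = 200L, generations = 400L, mu_site = 1e-5,
                       L_marker = 860L, L_neutral = 600L, n_neutral_loci = 3L,
                       mu_mat = 2e-4, r = 0, K_init = 10L,
                       init_marker_divergence = 0.05,
                       init_neutral_divergence = 0.004,
                       n_founder_haps = 8L,
                       bottleneck = list(time = 250L, size = 20L, duration = 30L),
                       sample_n_dikaryons = 40L,
                       clones_min = 3L, clones_max = 20L,
                       epsilon = 0.002, missing_allele_prob = 0.47,
                       compatibility = TRUE, seed = 1L, init_seed = NULL,
                       fixed_divergence = 0) {
  cfg <- list(N = as.integer(N), generations = as.integer(generations),
              mu_site = mu_site, L_marker = as.integer(L_marker),
              L_neutral = as.integer(L_neutral),
              n_neutral_loci = as.integer(n_neutral_loci), mu_mat = mu_mat,
              r = r, K_init = as.integer(K_init),
              init_marker_divergence = init_marker_divergence,
              init_neutral_divergence = init_neutral_divergence,
              n_founder_haps = as.integer(n_founder_haps),
              bottleneck = bottleneck,
              sample_n_dikaryons = as.integer(sample_n_dikaryons),
              clones_min = as.integer(clones_min),
              clones_max = as.integer(clones_max),
              epsilon = epsilon, missing_allele_prob = missing_allele_prob,
              compatibility = isTRUE(compatibility), seed = as.integer(seed),
              init_seed = if (is.null(init_seed)) as.integer(seed) else
                as.integer(init_seed),
              fixed_divergence = fixed_divergence)
  rates <- c(cfg$mu_site, cfg$mu_mat, cfg$r, cfg$epsilon,
             cfg$missing_allele_prob, cfg$init_marker_divergence,
             cfg$init_neutral_divergence, cfg$fixed_divergence)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0,1]")
  if (cfg$N < 2L) stop("N must be >= 2")
  if (cfg$K_init < 2L) stop("K_init must be >= 2")
  if (cfg$clones_min < 1L || cfg$clones_max > 50L ||
      cfg$clones_min > cfg$clones_max) {
    stop("clone range must satisfy 1 <= clones_min <= clones_max <= 50")
  }
  if (!is.null(bottleneck)) {
    stopifnot(all(c("time", "size", "duration") %in% names(bottleneck)))
  }
  class(cfg) <- "sim_config"
  cfg
}

# per-generation population size schedule
.size_schedule <- function(cfg) {
  sizes <- rep(cfg$N, cfg$generations)
  bn <- cfg$bottleneck
  if (!is.null(bn)) {
    lo <- max(1L, bn$time)
    hi <- min(cfg$generations, bn$time + bn$duration - 1L)
    if (lo <= hi) sizes[lo:hi] <- as.integer(bn$size)
  }
  sizes
}

# distinct-row count of an integer matrix
.n_distinct_rows <- function(im) length(unique(apply(im, 1L, paste, collapse = "")))

#' Run the forward simulation
#'
#' @param config A `sim_config`.
#' @return Object of class `sim_output`: list with `config`, `dikaryons`
#'   (data frame: isolate_id, mat1, mat2, n_exposed), `marker_haps` /
#'   `neutral_haps` (truth integer matrices for the sampled haploids),
#'   `genotypes` (IUPAC-coded neutral genotype strings per isolate per
#'   locus), `clone_reads` (per isolate character matrices), `truth`
#'   (MAT trajectory, richness snapshots, exposure and clone-origin
#'   records).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  N <- cfg$N
  # founders: K_init MAT lineages with pre-diverged linked marker; a
  # shared init_seed lets sister populations start from identical
  # lineages and pools
  # per-component seeding so two configs sharing init_seed get identical
  # lineages/pools regardless of how many each of them uses
  set.seed(cfg$init_seed)
  anc_marker <- sample.int(4L, cfg$L_marker, replace = TRUE)
  founder_marker <- t(vapply(seq_len(cfg$K_init), function(k) {
    .diverge(anc_marker, cfg$init_marker_divergence)
  }, integer(cfg$L_marker)))
  founder_pools <- lapply(seq_len(cfg$n_neutral_loci), function(l) {
    set.seed((cfg$init_seed + 7919L * l) %% .Machine$integer.max)
    anc <- sample.int(4L, cfg$L_neutral, replace = TRUE)
    t(vapply(seq_len(cfg$n_founder_haps), function(k) {
      .diverge(anc, cfg$init_neutral_divergence)
    }, integer(cfg$L_neutral)))
  })
  set.seed(cfg$seed)
  # population-specific fixed substitutions at the neutral loci: the
  # divergence accrued since this population split from its sister
  if (cfg$fixed_divergence > 0) {
    founder_pools <- lapply(founder_pools, function(pool) {
      L <- ncol(pool)
      k <- stats::rbinom(1L, L, cfg$fixed_divergence)
      if (k > 0L) {
        pos <- sample.int(L, k)
        subs <- sample(1:3, k, replace = TRUE)
        pool[, pos] <- ((sweep(pool[, pos, drop = FALSE], 2L, subs, "+") - 1L) %% 4L) + 1L
      }
      pool
    })
  }
  mat_id <- sample.int(cfg$K_init, N, replace = TRUE)
  marker <- founder_marker[mat_id, , drop = FALSE]
  neutrals <- lapply(founder_pools, function(pool) {
    pool[sample.int(cfg$n_founder_haps, N, replace = TRUE), , drop = FALSE]
  })
  next_mat <- cfg$K_init + 1L
  sizes <- .size_schedule(cfg)
  mat_count_traj <- integer(cfg$generations)
  bn <- cfg$bottleneck
  snap_pre <- if (!is.null(bn)) min(bn$time - 1L, cfg$generations) else cfg$generations
  snap_post <- if (!is.null(bn)) min(bn$time + bn$duration - 1L, cfg$generations) else NA_integer_
  snapshots <- list()
  for (gen in seq_len(cfg$generations)) {
    n_now <- length(mat_id)
    n_next <- sizes[gen]
    if (cfg$compatibility && length(unique(mat_id)) < 2L) {
      stop("simulation halted at generation ", gen,
           ": MAT diversity lost, mating impossible (single allele ",
           mat_id[1L], " fixed)")
    }
    p1 <- sample.int(n_now, n_next, replace = TRUE)
    p2 <- sample.int(n_now, n_next, replace = TRUE)
    if (cfg$compatibility) {
      bad <- which(mat_id[p2] == mat_id[p1])
      guard <- 0L
      while (length(bad)) {
        p2[bad] <- sample.int(n_now, length(bad), replace = TRUE)
        bad <- bad[mat_id[p2[bad]] == mat_id[p1[bad]]]
        guard <- guard + 1L
        if (guard > 10000L) stop("rejection sampling failed to find compatible mates")
      }
    } else {
      bad <- which(p2 == p1)   # still require two parents
      while (length(bad)) {
        p2[bad] <- sample.int(n_now, length(bad), replace = TRUE)
        bad <- bad[p2[bad] == p1[bad]]
      }
    }
    # meiosis: MAT from p1 or p2 with 1/2; marker follows the MAT-carrying
    # parent unless a recombination event (prob r) swaps it
    from_p2 <- stats::runif(n_next) < 0.5
    mat_parent <- ifelse(from_p2, p2, p1)
    rec <- stats::runif(n_next) < cfg$r
    marker_parent <- ifelse(rec, ifelse(from_p2, p1, p2), mat_parent)
    mat_id <- mat_id[mat_parent]
    marker <- .mutate_matrix(marker[marker_parent, , drop = FALSE], cfg$mu_site)
    neutrals <- lapply(neutrals, function(nm) {
      src <- ifelse(stats::runif(n_next) < 0.5, p1, p2)
      .mutate_matrix(nm[src, , drop = FALSE], cfg$mu_site)
    })
    # novel MAT alleles (infinite-alleles)
    novel <- which(stats::runif(n_next) < cfg$mu_mat)
    if (length(novel)) {
      mat_id[novel] <- seq.int(next_mat, length.out = length(novel))
      next_mat <- next_mat + length(novel)
    }
    mat_count_traj[gen] <- length(unique(mat_id))
    if (gen == snap_pre) {
      snapshots$pre_bottleneck <- list(
        mat_richness = length(unique(mat_id)),
        marker_richness = .n_distinct_rows(marker),
        neutral_richness = vapply(neutrals, .n_distinct_rows, 0L))
    }
    if (!is.na(snap_post) && gen == snap_post) {
      snapshots$post_bottleneck <- list(
        mat_richness = length(unique(mat_id)),
        marker_richness = .n_distinct_rows(marker),
        neutral_richness = vapply(neutrals, .n_distinct_rows, 0L))
    }
  }
  snapshots$final <- list(
    mat_richness = length(unique(mat_id)),
    marker_richness = .n_distinct_rows(marker),
    neutral_richness = vapply(neutrals, .n_distinct_rows, 0L))
  # --- sample dikaryons (heteroallelic at MAT, always) ---
  n_now <- length(mat_id)
  if (length(unique(mat_id)) < 2L) {
    stop("cannot sample dikaryons: MAT diversity lost (single allele fixed)")
  }
  nd <- cfg$sample_n_dikaryons
  i1 <- integer(nd); i2 <- integer(nd)
  for (d in seq_len(nd)) {
    a <- sample.int(n_now, 1L)
    cand <- which(mat_id != mat_id[a])
    b <- if (length(cand) == 1L) cand else sample(cand, 1L)
    i1[d] <- a; i2[d] <- b
  }
  iso_ids <- sprintf("iso%03d", seq_len(nd))
  hap_ids <- as.vector(rbind(paste0(iso_ids, ".h1"), paste0(iso_ids, ".h2")))
  sel <- as.vector(rbind(i1, i2))
  marker_haps <- marker[sel, , drop = FALSE]
  rownames(marker_haps) <- hap_ids
  neutral_haps <- lapply(neutrals, function(nm) {
    m <- nm[sel, , drop = FALSE]; rownames(m) <- hap_ids; m
  })
  names(neutral_haps) <- sprintf("neutral%d", seq_len(cfg$n_neutral_loci))
  # IUPAC genotypes for the neutral loci (what direct sequencing yields)
  genotypes <- lapply(neutral_haps, function(nm) {
    vapply(seq_len(nd), function(d) {
      combine_haplotypes(paste(.BASES[nm[2 * d - 1L, ]], collapse = ""),
                         paste(.BASES[nm[2 * d, ]], collapse = ""))
    }, "")
  })
  for (l in seq_along(genotypes)) names(genotypes[[l]]) <- iso_ids
  # marker allele exposure + clone reads (PCR error applied per clone)
  exposed <- matrix(TRUE, nd, 2L)
  hide <- stats::runif(nd) < cfg$missing_allele_prob
  exposed[cbind(which(hide), sample(c(1L, 2L), sum(hide), replace = TRUE))] <- FALSE
  clone_reads <- vector("list", nd)
  clone_origin <- vector("list", nd)
  for (d in seq_len(nd)) {
    n_cl <- sample(cfg$clones_min:cfg$clones_max, 1L)
    exp_idx <- which(exposed[d, ])
    if (length(exp_idx) == 2L && n_cl >= 2L) {
      n1 <- 1L + stats::rbinom(1L, n_cl - 2L, 0.5)
      origin <- c(rep(exp_idx[1L], n1), rep(exp_idx[2L], n_cl - n1))
    } else {
      origin <- rep(exp_idx[1L], n_cl)
    }
    reads <- marker_haps[2L * (d - 1L) + origin, , drop = FALSE]
    if (cfg$epsilon > 0) reads <- .mutate_matrix(reads, cfg$epsilon)
    rownames(reads) <- sprintf("%s.clone%02d", iso_ids[d], seq_len(n_cl))
    clone_reads[[d]] <- .int2char(reads)
    clone_origin[[d]] <- origin
  }
  names(clone_reads) <- iso_ids
  names(clone_origin) <- iso_ids
  dik <- data.frame(isolate_id = iso_ids, mat1 = mat_id[i1], mat2 = mat_id[i2],
                    n_exposed = rowSums(exposed), stringsAsFactors = FALSE)
  structure(list(config = cfg, dikaryons = dik,
                 marker_haps = marker_haps, neutral_haps = neutral_haps,
                 genotypes = genotypes, clone_reads = clone_reads,
                 truth = list(mat_count_trajectory = mat_count_traj,
                              snapshots = snapshots, exposed = exposed,
                              clone_origin = clone_origin,
                              founder_marker = founder_marker)),
            class = "sim_output")
}

# per-site mean pairwise difference of an integer haplotype matrix
.pi_int <- function(im) {
  n <- nrow(im)
  if (n < 2L) return(NA_real_)
  cc <- apply(im, 2L, tabulate, nbins = 4L)
  same <- colSums(cc * (cc - 1L)) / (n * (n - 1L))
  mean(1 - same)
}

#' Truth-record summaries of a simulation
#'
#' Deterministic summaries used by the property checks: the MAT allele
#' richness trajectory, nucleotide diversity at the marker vs the mean of
#' the neutral loci (over the sampled haplotypes), and the mean per-site
#' divergence of the two marker haplotypes within dikaryons against the
#' mean over cross-dikaryon haplotype pairs.
#'
#' @param sim A `sim_output`.
#' @return List with `mat_count_trajectory`, `final_mat_count`,
#'   `post_bottleneck_mat_count`, `pi_marker`, `pi_neutral`, `pi_ratio`,
#'   `within_dikaryon_divergence`, `cross_dikaryon_divergence`,
#'   `richness_snapshots`.
#' @export
summarize_truth <- function(sim) {
  stopifnot(inherits(sim, "sim_output"))
  mh <- sim$marker_haps
  nd <- nrow(sim$dikaryons)
  pi_marker <- .pi_int(mh)
  pi_neutral <- mean(vapply(sim$neutral_haps, .pi_int, 0))
  L <- ncol(mh)
  within <- vapply(seq_len(nd), function(d) {
    sum(mh[2 * d - 1L, ] != mh[2 * d, ]) / L
  }, 0)
  dik_of <- rep(seq_len(nd), each = 2L)
  cross <- numeric(0)
  n_h <- nrow(mh)
  cross_sum <- 0; cross_n <- 0L
  for (i in seq_len(n_h - 1L)) {
    for (j in (i + 1L):n_h) {
      if (dik_of[i] != dik_of[j]) {
        cross_sum <- cross_sum + sum(mh[i, ] != mh[j, ]) / L
        cross_n <- cross_n + 1L
      }
    }
  }
  snaps <- sim$truth$snapshots
  list(mat_count_trajectory = sim$truth$mat_count_trajectory,
       final_mat_count = snaps$final$mat_richness,
       post_bottleneck_mat_count = if (!is.null(snaps$post_bottleneck))
         snaps$post_bottleneck$mat_richness else snaps$final$mat_richness,
       pi_marker = pi_marker, pi_neutral = pi_neutral,
       pi_ratio = pi_marker / pi_neutral,
       within_dikaryon_divergence = mean(within),
       cross_dikaryon_divergence = cross_sum / cross_n,
       richness_snapshots = sim$truth$snapshots)
}

#' Write all pipeline inputs for a simulated sample
#'
#' Emits, under `outdir`: the exposed marker alleles as one aligned FASTA
#' (`marker_alleles.fasta`, ids `<isolate>.a1`/`.a2`), per-locus neutral
#' genotype FASTAs with IUPAC codes (`<locus>_genotypes.fasta`), per-
#' isolate marker clone FASTAs (`clones/<isolate>_marker.fasta`), a sample
#' sheet TSV, an allele-pairs TSV for the two-allele isolates, and a truth
#' JSON. All randomness was consumed in [simulate_population()], so the
#' file set is byte-identical for identical seeds.
#'
#' @param sim A `sim_output`.
#' @param outdir Output directory (created if needed).
#' @param group Group label written to the sample sheet (default "sim").
#' @return Invisibly, a named list of the written paths.
#' @export
emit_inputs <- function(sim, outdir, group = "sim") {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "clones"), showWarnings = FALSE)
  nd <- nrow(sim$dikaryons)
  iso <- sim$dikaryons$isolate_id
  exposed <- sim$truth$exposed
  # exposed marker alleles, renamed <iso>.a1 / .a2 in exposure order
  seqs <- character(0); sheet <- list(); pair_rows <- list()
  for (d in seq_len(nd)) {
    idx <- which(exposed[d, ])
    ids <- sprintf("%s.a%d", iso[d], seq_along(idx))
    for (k in seq_along(idx)) {
      seqs[[ids[k]]] <- paste(.BASES[sim$marker_haps[2 * (d - 1L) + idx[k], ]],
                              collapse = "")
      sheet[[ids[k]]] <- data.frame(seq_id = ids[k], isolate_id = iso[d],
                                    locus = "marker", group = group,
                                    ecology = "B", stringsAsFactors = FALSE)
    }
    if (length(idx) == 2L) {
      pair_rows[[d]] <- data.frame(isolate_id = iso[d], allele1 = ids[1L],
                                   allele2 = ids[2L], group = group,
                                   stringsAsFactors = FALSE)
    }
  }
  paths <- list()
  marker_aln <- new_alignment(seqs, locus = "marker",
                              meta = do.call(rbind, sheet))
  paths$marker <- file.path(outdir, "marker_alleles.fasta")
  write_fasta(marker_aln, paths$marker)
  for (lc in names(sim$genotypes)) {
    g <- sim$genotypes[[lc]]
    aln <- new_alignment(g, locus = lc)
    p <- file.path(outdir, paste0(lc, "_genotypes.fasta"))
    write_fasta(aln, p)
    paths[[lc]] <- p
    for (id in names(g)) {
      sheet[[paste(lc, id)]] <- data.frame(seq_id = id, isolate_id = id,
                                           locus = lc, group = group,
                                           ecology = "B", stringsAsFactors = FALSE)
    }
  }
  for (d in seq_len(nd)) {
    p <- file.path(outdir, "clones", sprintf("%s_marker.fasta", iso[d]))
    write_fasta(new_alignment(sim$clone_reads[[d]], locus = "marker"), p)
  }
  paths$clones_dir <- file.path(outdir, "clones")
  paths$sample_sheet <- file.path(outdir, "sample_sheet.tsv")
  utils::write.table(do.call(rbind, c(sheet, list(make.row.names = FALSE))),
                     paths$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$pairs <- file.path(outdir, "allele_pairs.tsv")
  pair_df <- do.call(rbind, c(pair_rows[!vapply(pair_rows, is.null, TRUE)],
                              list(make.row.names = FALSE)))
  utils::write.table(pair_df, paths$pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- file.path(outdir, "truth.json")
  truth <- list(
    config = unclass(sim$config),
    dikaryons = sim$dikaryons,
    exposed = sim$truth$exposed,
    mat_count_trajectory = sim$truth$mat_count_trajectory,
    marker_haplotypes = setNames(
      apply(.int2char(sim$marker_haps), 1L, paste, collapse = ""),
      rownames(sim$marker_haps)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Generate clone reads from allele sequences
#'
#' Emulates cloning and sequencing of a PCR product: each allele yields
#' `n_per_allele` clone copies with independent per-base errors at rate
#' `epsilon` (uniform over the three alternative bases).
#'
#' @param haps Character vector of allele sequences (equal length).
#' @param n_per_allele Integer vector (recycled) of clones per allele.
#' @param epsilon Per-base error rate.
#' @return Character matrix of clone sequences (rows = clones, named
#'   `a<i>.c<j>`).
#' @export
make_clone_reads <- function(haps, n_per_allele, epsilon = 0) {
  stopifnot(length(haps) >= 1L)
  n_per_allele <- rep_len(as.integer(n_per_allele), length(haps))
  im <- do.call(rbind, lapply(seq_along(haps), function(i) {
    v <- match(strsplit(toupper(haps[i]), "")[[1L]], .BASES)
    if (anyNA(v)) stop("clone template must be unambiguous A/C/G/T")
    matrix(rep(v, each = n_per_allele[i]), nrow = n_per_allele[i])
  }))
  rownames(im) <- unlist(lapply(seq_along(haps), function(i)
    sprintf("a%d.c%02d", i, seq_len(n_per_allele[i]))))
  if (epsilon > 0) im <- .mutate_matrix(im, epsilon)
  .int2char(im)
}

#' Infinite-sites coalescent sample (independent oracle)
#'
#' Draws one sample of n sequences from the standard neutral coalescent
#' with scaled mutation rate theta (per locus), by Poisson mutation over
#' the simulated genealogy, and returns it as an alignment (ancestral
#' base A, derived G at each mutated site). Used as an independent
#' calibration oracle for the neutrality statistics; it is not part of
#' the forward model.
#'
#' @param n Sample size (>= 2).
#' @param theta Population mutation parameter per locus.
#' @param min_sites Pad with this many invariant columns at least (so the
#'   alignment is valid even with S = 0); default 1.
#' @return A `mat_alignment` of n sequences.
#' @export
sim_coalescent <- function(n, theta, min_sites = 1L) {
  if (n < 2L) stop("coalescent sample needs n >= 2")
  lineages <- as.list(seq_len(n))
  cols <- list()
  while (length(lineages) > 1L) {
    k <- length(lineages)
    t_k <- stats::rexp(1L, rate = k * (k - 1) / 2)
    n_mut <- stats::rpois(1L, theta / 2 * k * t_k)
    if (n_mut > 0L) {
      on <- sample.int(k, n_mut, replace = TRUE)
      for (m in seq_len(n_mut)) cols[[length(cols) + 1L]] <- lineages[[on[m]]]
    }
    pick <- sample.int(k, 2L)
    merged <- c(lineages[[pick[1L]]], lineages[[pick[2L]]])
    lineages <- c(lineages[-pick], list(merged))
  }
  S <- length(cols)
  m <- matrix("A", n, max(S, min_sites))
  for (j in seq_len(S)) m[cols[[j]], j] <- "G"
  rownames(m) <- paste0("seq", seq_len(n))
  new_alignment(m, locus = "coalescent")
}
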