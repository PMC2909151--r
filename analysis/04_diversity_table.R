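#!/usr/bin/env Rscript
# Step 4 -- per-locus, per-group molecular variation table.
#
# For each population and locus: haplotype count, segregating sites, mean
# pairwise differences k, nucleotide diversity pi, per-locus Watterson
# theta, Tajima's D and Fu & Li's D*/F*, computed on phased haplotypes
# under complete deletion. The expectation from the model: comparable
# marker diversity in the founder (building) and source (nature)
# populations, but neutral diversity collapsed in the founder one.

suppressPackageStartupMessages(library(matdiv))
out_root <- "results/analysis"

alns <- list()
groups <- list()
# isolate ids repeat across the two simulated populations; prefix them
prefix_aln <- function(aln, pop) {
  m <- aln$mat
  rownames(m) <- paste(pop, rownames(m), sep = ".")
  meta <- aln$meta
  meta$seq_id <- paste(pop, meta$seq_id, sep = ".")
  new_alignment(m, locus = aln$locus, meta = meta)
}
for (pop in c("founder", "source")) {
  indir <- file.path(out_root, "inputs", pop)
  sheet <- read_sample_sheet(file.path(indir, "sample_sheet.tsv"))
  marker <- read_fasta(file.path(indir, "marker_alleles.fasta"),
                       sample_sheet = sheet, locus = "marker")
  loci <- list(marker = marker)
  for (p in list.files(out_root, pattern = paste0("^", pop, "_neutral\\d+_haplotypes\\.fasta$"),
                       full.names = TRUE)) {
    locus <- sub(paste0("^", pop, "_(neutral\\d+)_haplotypes\\.fasta$"), "\\1", basename(p))
    loci[[locus]] <- read_fasta(p, locus = locus)
  }
  for (lc in names(loci)) {
    if (is.null(alns[[lc]])) alns[[lc]] <- list()
    alns[[lc]][[pop]] <- prefix_aln(loci[[lc]], pop)
    groups[[pop]] <- union(groups[[pop]], rownames(alns[[lc]][[pop]]$mat))
  }
}
# merge the two populations into one alignment per locus
merged <- lapply(alns, function(by_pop) {
  m <- do.call(rbind, lapply(by_pop, function(a) a$mat))
  meta <- do.call(rbind, lapply(names(by_pop), function(pop) {
    mm <- by_pop[[pop]]$meta
    mm$group <- pop
    mm$ecology <- if (pop == "founder") "B" else "N"
    mm
  }))
  new_alignment(m, locus = by_pop[[1]]$locus, meta = meta)
})
groups$all <- unique(unlist(groups))

summary <- locus_summary(merged, groups)
tbl <- format_summary_table(summary, file.path(out_root, "diversity_table.tsv"))
print(format_summary_table(summary), row.names = FALSE)

mk <- summary[summary$locus == "marker", ]
neu <- summary[summary$locus != "marker", ]
cat(sprintf("\nmarker pi founder/source: %.4f / %.4f | mean neutral pi founder/source: %.4f / %.4f\n",
            mk$pi[mk$group == "founder"], mk$pi[mk$group == "source"],
            mean(neu$pi[neu$group == "founder"], na.rm = TRUE),
            mean(neu$pi[neu$group == "source"], na.rm = TRUE)))
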