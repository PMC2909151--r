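#!/usr/bin/env Rscript
# Step 3 -- phase the neutral-locus genotypes.
#
# Direct sequencing of a dikaryon yields one sequence per locus with
# two-fold IUPAC codes at heterozygous sites. Haplotypes are inferred by
# the template-then-parsimony procedure (forced 0/1-het resolutions seed
# the templates; multi-het genotypes are matched to templates or, failing
# that, to minimum-mutation partners), yielding a minimal allele count.

suppressPackageStartupMessages(library(matdiv))
out_root <- "results/analysis"

for (pop in c("founder", "source")) {
  indir <- file.path(out_root, "inputs", pop)
  gfiles <- list.files(indir, pattern = "_genotypes\\.fasta$", full.names = TRUE)
  audit <- list()
  for (p in gfiles) {
    locus <- sub("_genotypes\\.fasta$", "", basename(p))
    g <- aln_strings(read_fasta(p, locus = locus))
    hs <- phase_all(g)
    audit[[locus]] <- cbind(locus = locus, hs$assignments)
    write_fasta(haplotype_alignment(hs, locus = locus),
                file.path(out_root, sprintf("%s_%s_haplotypes.fasta", pop, locus)))
    prov <- table(hs$assignments$provenance)
    cat(sprintf("[%s %s] %d genotypes -> %d distinct haplotypes (%s)\n",
                pop, locus, length(g), hs$n_distinct,
                paste(sprintf("%s %d", names(prov), prov), collapse = ", ")))
  }
  utils::write.table(do.call(rbind, audit),
                     file.path(out_root, paste0(pop, "_phase_audit.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
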