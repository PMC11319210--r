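#!/usr/bin/env Rscript
# Step 4 — structural-variant landscape:
#   merge the per-accession call sets into a nonredundant set, summarize the
#   five SV categories, annotate genomic context (CDS / genic / 2 kb flank /
#   intergenic, repeat membership, coding effect), test repeat-region
#   enrichment with a two-sided Fisher's exact test, scan for inversion
#   hotspots, and partition the target group's core SVs by inheritance from
#   the two candidate ancestors.

suppressPackageStartupMessages(library(panmelon))

indir <- "results/simulated"
outdir <- "results/svs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

records <- read_sv_table(file.path(indir, "svs.tsv"), "tsv")
genes <- read_gff3(file.path(indir, "genes.gff3"))
repeats <- read_repeat_bed(file.path(indir, "repeats.bed"))
assembly <- read_fasta(file.path(indir, "genome.fa"))
chrom_lengths <- vapply(assembly, nchar, numeric(1))

nr <- merge_svs(records)
cat(sprintf("Merged %d records into %d nonredundant SVs.\n",
            nrow(records), nrow(nr$table)))
write.table(nr$table, file.path(outdir, "nonredundant_svs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(id = rownames(nr$presence), nr$presence * 1L),
            file.path(outdir, "sv_presence.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

sm <- summarize_types(nr)
write.table(sm, file.path(outdir, "type_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Type summary (count, percent):\n")
print(sm, row.names = FALSE)

ann <- annotate_svs(nr, genes, repeats)
write.table(ann$annotations, file.path(outdir, "annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Genomic-context fractions:\n")
print(round(ann$summary, 4))

en <- repeat_enrichment(nr, repeats, chrom_lengths)
jsonlite::write_json(list(table = as.data.frame(en$table),
                          density_repeat = en$density_repeat,
                          density_nonrepeat = en$density_nonrepeat,
                          odds_ratio = en$odds_ratio, p_value = en$p_value),
                     file.path(outdir, "enrichment.json"), auto_unbox = TRUE,
                     pretty = TRUE)
cat(sprintf(paste0("Repeat enrichment: %.1f vs %.1f SVs per 500 kb ",
                   "(repeat vs nonrepeat), OR = %.2f, p = %.3g\n"),
            en$density_repeat, en$density_nonrepeat, en$odds_ratio,
            en$p_value))

hs <- inversion_hotspots(nr)
write.table(hs, file.path(outdir, "inversion_hotspots.bed"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("Inversion hotspots (>= 3 inversions per 1 Mb window): %d\n",
            nrow(hs)))

ap <- ancestry_partition(nr, paste0("lanatus_", 1:4),
                         "mucosospermus", "cordophanus")
jsonlite::write_json(c(as.list(ap$counts), list(total = ap$total)),
                     file.path(outdir, "ancestry.json"), auto_unbox = TRUE,
                     pretty = TRUE)
cat(sprintf(paste0("Core SVs of the target group: %d; inherited from ",
                   "ancestor A only: %d,\nfrom ancestor B only: %d, from ",
                   "both: %d, from neither: %d.\n"),
            ap$total, ap$counts["onlyA"], ap$counts["onlyB"],
            ap$counts["both"], ap$counts["neither"]))

thr <- bonferroni_threshold(0.05, 9618384)
cat(sprintf("Bonferroni threshold for a 9,618,384-marker scan: %.3g\n", thr))
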