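#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs with known ground truth:
#   * a 28-accession, 7-species PAV matrix (20,000 gene families),
#   * a 3-chromosome genome with centromeric arrays, Gypsy repeats, genes
#     and telomeric caps,
#   * per-accession SV call sets with a two-ancestor inheritance design.
# Everything downstream (02-04) consumes the files written here.

suppressPackageStartupMessages(library(panmelon))

seed <- 2024L
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("Simulating the PAV panel ...")
pav_sim <- simulate_pav(seed = seed)
write_pav_matrix(pav_sim$pav, file.path(outdir, "pav.tsv"),
                 file.path(outdir, "species.tsv"))

message("Simulating a 3-chromosome genome ...")
genome <- simulate_genome(n_chromosomes = 3, seed = seed)
write_fasta(genome$bundle$assembly, file.path(outdir, "genome.fa"))
write_gff3(genome$bundle$genes, file.path(outdir, "genes.gff3"))
write_repeat_bed(genome$bundle$repeats, file.path(outdir, "repeats.bed"))

message("Simulating the SV landscape ...")
accessions <- c(paste0("lanatus_", 1:4), "mucosospermus", "cordophanus")
design <- list(target = paste0("lanatus_", 1:4),
               ancestor_a = "mucosospermus", ancestor_b = "cordophanus")
svs <- simulate_sv_landscape(accessions, design, n_svs = 2000,
                             repeat_enrichment_factor = 3,
                             annotation_bundle = genome$bundle,
                             seed = seed + 1L)
write_sv_table(svs$records, file.path(outdir, "svs.tsv"))

manifest <- list(
  seed = seed,
  pav = pav_sim$manifest["generator_params"],
  genome = lapply(genome$manifests, function(m)
    list(true_centromere = m$true_centromere,
         true_telomere_ends = m$true_telomere_ends)),
  svs = list(origin_table = as.list(table(svs$manifest$true_sv_origin)),
             generator_params = svs$manifest$generator_params))
jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf(paste0(
  "Simulated: %d families x %d accessions; %d chromosomes (%.1f Mb);\n",
  "%d SV records over %d accessions (true nonredundant SVs: %d).\n"),
  nrow(pav_sim$pav$presence), ncol(pav_sim$pav$presence),
  length(genome$bundle$assembly),
  sum(nchar(genome$bundle$assembly)) / 1e6,
  nrow(svs$records), length(accessions),
  nrow(svs$manifest$true_positions)))
cat("Inputs written to", outdir, "\n")
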