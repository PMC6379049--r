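#!/usr/bin/env Rscript
# Stage 2: quantitative expression analytics on the simulated atlas.
#
# Normalization, tissue-specificity classification, per-tissue RMA slopes
# of protein on mRNA, correlation structure, rank-abundance shares, top-100
# overlap, co-inertia RV and proteomic-ruler copy numbers. Reads the TSVs
# written by 01_simulate.R; results land in results/atlas/.

suppressMessages(library(atlasomics))

in_dir <- "results/sim"
out_dir <- "results/atlas"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

mrna <- read_expression_tsv(file.path(in_dir, "mrna_fpkm.tsv"), "fpkm")
protein <- read_expression_tsv(file.path(in_dir, "protein_intensity.tsv"),
                               "intensity")
truth <- read.delim(file.path(in_dir, "truth.tsv"))
coding <- rownames(protein$values)
mrna_coding <- expression_matrix(mrna$values[coding, , drop = FALSE],
                                 "fpkm", 1)

## tissue specificity (fivefold scheme) on both layers
spec_m <- classify_specificity(mrna_coding)
spec_p <- classify_specificity(protein)
tab <- rbind(mrna = table(spec_m$category),
             protein = table(spec_p$category))
write.table(cbind(layer = rownames(tab), as.data.frame.matrix(tab)),
            file.path(out_dir, "specificity_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
planted <- truth$gene_id[truth$enriched]
called <- spec_m$gene_id[spec_m$category == "tissue_enriched"]
cat(sprintf("specificity: %d/%d planted tissue-enriched genes recalled at the mRNA layer (noise SD %s)\n",
            length(intersect(called, planted)), length(planted), "0.3"))
print(tab)

## per-tissue protein ~ mRNA slopes (ranged major axis)
slopes <- atlas_slopes(mrna_coding, protein)
write.table(slopes, file.path(out_dir, "slopes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("RMA slopes across %d tissues: median %.2f (range %.2f-%.2f; planted 2.6)\n",
            nrow(slopes), median(slopes$slope), min(slopes$slope),
            max(slopes$slope)))

## correlation structure
cs <- correlation_suite(mrna_coding, protein, min_tissues = 10L)
write.table(cs$per_tissue, file.path(out_dir, "per_tissue_spearman.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cs$per_gene, file.path(out_dir, "per_gene_spearman.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
off <- function(m) m[upper.tri(m)]
cat(sprintf("tissue-tissue correlation medians: protein %.2f vs mRNA %.2f\n",
            median(off(cs$tissue_cor_protein), na.rm = TRUE),
            median(off(cs$tissue_cor_mrna), na.rm = TRUE)))

## rank-abundance and top-100 overlap
ra <- rank_abundance_profile(mrna_coding, 1L)
cat(sprintf("tissue01 mRNA rank-abundance: top-10 transcripts carry %.1f%% of the FPKM\n",
            100 * ra$top_shares[["top10"]]))
ov <- top_n_overlap(mrna_coding, protein,
                    min(100L, min(colSums(mrna_coding$values > 0 &
                                            protein$values > 0))))
write.table(ov, file.path(out_dir, "top100_overlap.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top-100 mRNA/protein overlap: mean %.2f across tissues\n",
            mean(ov$overlap)))

## co-inertia (genes as observations, tissue profiles as variables)
ci <- coinertia_rv(log10(impute_floor(mrna_coding$values)),
                   log10(impute_floor(protein$values)))
cat(sprintf("co-inertia RV between the two layers: %.3f\n", ci$rv))
write.table(data.frame(tissue = rownames(ci$sample_scores_X),
                       ci$sample_scores_X, ci$sample_scores_Y),
            file.path(out_dir, "coinertia_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## proteomic-ruler copy numbers in tissue01, using the five most abundant
## proteins as stand-in histones and simulated molar masses
ints <- protein$values[, 1]
ints <- ints[ints > 0]
set.seed(1)
mm <- setNames(runif(length(ints), 1.5e4, 1.5e5), names(ints))
hist_ids <- names(sort(ints, decreasing = TRUE))[1:5]
cp <- protein_copy_numbers(ints, mm, hist_ids)
ribo_ids <- names(sort(ints, decreasing = TRUE))[6:20]
mc <- mrna_copy_numbers(
  mrna_coding$values[names(ints), 1],
  setNames(rep(1500, length(ints)), names(ints)),
  cp$copies_per_cell[match(ribo_ids, cp$entity_id)])
write.table(cp, file.path(out_dir, "protein_copies_tissue01.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mc, file.path(out_dir, "mrna_copies_tissue01.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("copy numbers (tissue01): protein median %.2e, mRNA median %.2e per cell\n",
            median(cp$copies_per_cell, na.rm = TRUE),
            median(mc$copies_per_cell, na.rm = TRUE)))
cat("outputs in", out_dir, "\n")
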