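#!/usr/bin/env Rscript

# Stage 3 — cross-reactive CDR3s and their distance separation.
#
# Filters the simulated TCR-epitope table (human, MHC-I, nonamer, A*02),
# identifies cross-reactive CDR3 sets, profiles their sequence identity,
# and asks whether the epitopes of the most promiscuous CDR3 lie closer
# together in structured-feature space than a background pool.

suppressPackageStartupMessages(library(phlacross))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
ind <- "results/simulated"
out <- "results"
cfg <- synthetic_config(seed = seed, image_size = c(160L, 120L))

rec <- load_tcr_table(file.path(ind, "tcr_assays.tsv"))
drops <- attr(rec, "drop_counts")
cat("filters dropped:", paste(names(drops), drops, collapse = " | "), "\n")

sets <- find_crossreactive(rec)
cat("cross-reactive CDR3s:", length(sets), "| top set sizes:",
    paste(head(vapply(sets, function(s) length(s$epitopes), integer(1)), 4),
          collapse = ", "), "\n")

top <- sets[[1]]
ident <- crossreactive_identity_profile(top)
cat(sprintf("top set identity: median %.1f%%, %.0f%% of pairs <= 33%%\n",
            median(ident), 100 * mean(ident <= 100 / 3 + 1e-9)))
pfm <- position_frequency_matrix(top$epitopes)
conserved <- which(apply(pfm, 2, max) == 1)
cat("fully conserved positions in the top set:",
    paste(colnames(pfm)[conserved], collapse = ", "), "\n")

# distance separation: epitopes of the top CDR3 vs unrelated epitopes
background <- setdiff(unique(rec$epitope), top$epitopes)
all_eps <- c(top$epitopes, background)
vecs <- lapply(all_eps, function(s) {
  build_feature_vector(
    aggregate_residues(generate_phla_structure(s, cfg)),
    scope = "EPITOPE", components = c("c", "XYZ"), epitope_id = s
  )
})
pt <- pairwise_distance_table(vecs)
in_top <- pt$id_a %in% top$epitopes & pt$id_b %in% top$epitopes
cmp <- compare_to_pool(pt$distance[in_top], pt$distance[!in_top])
cat(sprintf(
  "within-set median %.3f vs background %.3f (rank-sum p = %.3g, d = %.2f)\n",
  cmp$median_target, cmp$median_pool, cmp$p_value, cmp$effect_size))

stats <- data.frame(
  cdr3_key = vapply(sets, `[[`, character(1), "cdr3_key"),
  n_epitopes = vapply(sets, function(s) length(s$epitopes), integer(1))
)
write.table(stats, file.path(out, "crossreactive_sets.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(stats), "cross-reactive sets\n")
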