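#!/usr/bin/env Rscript

# Stage 4 — activation readouts vs pHLA dissimilarity.
#
# Builds image-space (Canberra, masked composite) and feature-space
# (Euclidean) distances from each variant to the reference epitope,
# generates an activation assay with the planted negative dependence,
# and measures: the distance-readout Spearman correlations, the embedding
# + regression association, the per-position variant difference map, and
# the feature-combination scan.

suppressPackageStartupMessages(library(phlacross))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
ind <- "results/simulated"
out <- "results"
cfg <- synthetic_config(seed = seed, image_size = c(160L, 120L))

pngs <- list.files(file.path(ind, "png"), pattern = "_TOP\\.png$",
                   full.names = TRUE)
ids <- sub("_TOP\\.png$", "", basename(pngs))
reference <- "ALWGPDPAA"
stopifnot(reference %in% ids)

cat("decomposing", length(pngs), "top-view surface renders\n")
comps <- setNames(lapply(pngs, function(f) decompose_image(f)$composite),
                  ids)
mask <- variability_mask(comps, central_fraction = 0.5)
cat(sprintf("informative-pixel mask: %d pixels (%.1f%% of the raster)\n",
            sum(mask$keep), 100 * mean(mask$keep)))

variants <- setdiff(ids, reference)
d_img <- vapply(variants, function(v) {
  image_distance(comps[[v]], comps[[reference]], mask)
}, numeric(1))

tabs <- lapply(ids, function(id) {
  aggregate_residues(generate_phla_structure(id, cfg))
})
names(tabs) <- ids
vecs <- lapply(ids, function(id) {
  build_feature_vector(tabs[[id]], scope = "EPITOPE",
                       components = c("c", "XYZ"), epitope_id = id)
})
pt <- pairwise_distance_table(vecs)
d_feat <- distance_to_reference(variants, pt, reference)

assay <- generate_activation_assay(
  d_feat, synthetic_config(seed = seed, planted_slope = -1,
                           noise_sd = sqrt(3) * sd(d_feat))
)

for (nm in c("image", "feature")) {
  d <- if (nm == "image") d_img else d_feat
  ca <- correlate_activation(d, assay, method = "spearman")
  cat(sprintf("%s-space distance vs readout: rho = %.2f, p = %.3g, n = %d\n",
              nm, ca$coefficient, ca$p_value, ca$n))
}

er <- embed_and_regress(comps[variants], assay, method = "pca", mask = mask)
cat(sprintf("embedding regression: overall p = %.3g; dim correlations %s\n",
            er$regression_p,
            paste(sprintf("r%d=%.2f", er$per_dim_correlations$dim,
                          er$per_dim_correlations$r), collapse = ", ")))

regions <- attr(render_surface(generate_phla_structure(reference, cfg),
                               "TOP", cfg), "position_regions")
vdm <- variant_difference_map(comps[variants], comps[[reference]], regions)
write.table(data.frame(variant = rownames(vdm), vdm, check.names = FALSE),
            file.path(out, "variant_difference_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

scan <- combination_scan(tabs, assay, reference)
write.table(scan, file.path(out, "combination_scan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
best <- scan[which.min(scan$p_value), ]
cat(sprintf("combination scan: strongest %s (rho = %.2f, p = %.3g); %d/%d significant\n",
            best$label, best$rho, best$p_value,
            sum(scan$significant, na.rm = TRUE), nrow(scan)))
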