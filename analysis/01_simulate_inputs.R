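#!/usr/bin/env Rscript

# Stage 1 — simulate the study inputs.
#
# Generates everything downstream stages consume: docked pHLA structures
# (PQR) and surface renders (PNG, five perspectives) for a reference
# epitope and its variants, a TCR-epitope assay table with planted
# cross-reactive CDR3s, and self/viral/tumor epitope pools with planted
# overlap and mimicry. All outputs land under results/simulated/.

suppressPackageStartupMessages(library(phlacross))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/simulated"
dir.create(file.path(out, "pqr"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "png"), recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed, image_size = c(160L, 120L))

# reference epitope (a preproinsulin-like nonamer) and single-residue
# variants at the TCR-facing positions
reference <- "ALWGPDPAA"
positions <- c(1L, 3L, 4L, 5L, 6L, 7L, 8L)
subs <- c("D", "E", "K", "R", "G", "S", "V", "F")
variants <- unique(unlist(lapply(positions, function(p) {
  vapply(subs, function(a) {
    s <- strsplit(reference, "")[[1]]
    if (s[p] == a) return(NA_character_)
    s[p] <- a
    paste(s, collapse = "")
  }, character(1))
})))
variants <- c(reference, variants[!is.na(variants)])
cat("simulating", length(variants), "pHLA structures (reference",
    reference, ")\n")

for (v in variants) {
  st <- generate_phla_structure(v, cfg)
  write_pqr(st, file.path(out, "pqr", paste0(v, ".pqr")))
  for (p in cfg$perspectives) {
    img <- render_surface(st, p, cfg)
    write_surface_png(img, file.path(out, "png",
                                     paste0(v, "_", p, ".png")))
  }
}

tcr <- generate_tcr_table(cfg)
write.table(tcr, file.path(out, "tcr_assays.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("TCR table:", nrow(tcr), "rows,",
    length(attr(tcr, "planted_sets")), "planted promiscuous CDR3s\n")

pools <- generate_epitope_pools(
  synthetic_config(seed = seed, n_self = 989L, n_viral = 987L,
                   n_tumor = 133L, shared_fraction = 0.01,
                   mimic_self_fraction = 0.6)
)
for (nm in names(pools)) {
  write.table(pools[[nm]], file.path(out, paste0("pool_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("pools: self", nrow(pools$self), "| viral", nrow(pools$viral),
    "| tumor", nrow(pools$tumor), "\n")
cat("done; outputs in", out, "\n")
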