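#!/usr/bin/env Rscript

# Stage 5 — self / viral / tumor pool comparisons.
#
# On the simulated pools: shared-sequence census (with and without anchor
# trimming), redundancy profiles, origin-class distance statistics with
# Kruskal-Wallis, extreme-pair ranking, closest-match mimicry
# classification, the resampling shift, and position-wise Atchley and
# amino-acid-class statistics on the mimicry groups.

suppressPackageStartupMessages(library(phlacross))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
ind <- "results/simulated"
out <- "results"
cfg <- synthetic_config(seed = seed, image_size = c(160L, 120L))

pools <- lapply(c(self = "self", viral = "viral", tumor = "tumor"),
                function(nm) {
  read.delim(file.path(ind, paste0("pool_", nm, ".tsv")),
             stringsAsFactors = FALSE)
})

cen <- shared_sequence_census(pools$self$sequence, pools$viral$sequence)
cen_tr <- shared_sequence_census(pools$self$sequence, pools$viral$sequence,
                                 trimmed = TRUE)
cat(sprintf("census: %d/%d shared (%.3g%%); trimmed %d/%d (%.3g%%)\n",
            cen$shared_count, cen$restricted_count, cen$shared_percent,
            cen_tr$shared_count, cen_tr$restricted_count,
            cen_tr$shared_percent))

for (nm in c("self", "viral")) {
  rp <- redundancy_profile(pools[[nm]]$multiplicity)
  cat(sprintf("%s pool: %.0f%% of binders redundant (multiplicity >= 2)\n",
              nm, 100 * rp$fraction_redundant))
}

# distance layer over a subsample of the pools (plus all tumor epitopes).
# The subsample keeps every tumor parent so the tumor rows face the same
# complete background they would in a full-cohort run.
set.seed(seed)
pick <- function(pool, other) {
  eligible <- setdiff(pool, other)
  keep <- intersect(pools$tumor$parent, eligible)
  unique(c(keep, sample(eligible, 250)))[1:250]
}
sub_self <- pick(pools$self$sequence, pools$viral$sequence)
sub_viral <- pick(pools$viral$sequence, pools$self$sequence)
seqs <- c(sub_self, sub_viral, pools$tumor$sequence)
origins <- setNames(rep(c("SELF", "VIRAL", "TUMOR"),
                        c(250, 250, nrow(pools$tumor))), seqs)
cat("building feature vectors for", length(seqs), "epitopes\n")
vecs <- lapply(seqs, function(s) {
  build_feature_vector(aggregate_residues(generate_phla_structure(s, cfg)),
                       scope = "EPITOPE", components = c("c", "XYZ"),
                       epitope_id = s)
})
pt <- pairwise_distance_table(vecs, origins)

hv <- pt[pt$pair_class %in% c("HH", "HV", "VV"), ]
cls_stats <- classify_pair_distances(hv)
cat(sprintf("pair-class medians: %s | Kruskal-Wallis p = %.3g\n",
            paste(names(cls_stats$medians),
                  sprintf("%.2f", cls_stats$medians), collapse = " "),
            cls_stats$kruskal_p))

ex <- extreme_pairs(hv, n_each = 300L)
cat("extreme pairs: smallest tail classes:",
    paste(capture.output(print(table(ex$pair_class[ex$tail == "smallest"]))),
          collapse = " "), "\n")
write.table(ex, file.path(out, "extreme_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cls <- closest_match_classification(pools$tumor$sequence, pt)
tab <- table(cls$label)
cat("closest-match classification:",
    paste(names(tab), tab, collapse = " | "), "\n")
agree <- mean(ifelse(cls$label == "CloserToHuman", "SELF",
                     ifelse(cls$label == "CloserToViral", "VIRAL", NA)) ==
                pools$tumor$planted_origin, na.rm = TRUE)
cat(sprintf("agreement with planted mimicry origin: %.0f%%\n", 100 * agree))
write.table(cls, file.path(out, "closest_match.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

th <- pt$distance[pt$pair_class == "TH"]
tv <- pt$distance[pt$pair_class == "TV"]
shift <- resampling_shift(th, tv, sizes = seq(100L, 500L, 100L),
                          reps = 1000L, seed = seed)
cat("resampling shift (tumor-self vs tumor-viral distances):\n")
print(shift, row.names = FALSE)

human_grp <- cls$tumor_id[cls$label == "CloserToHuman"]
viral_grp <- cls$tumor_id[cls$label == "CloserToViral"]
if (length(human_grp) >= 3 && length(viral_grp) >= 3) {
  at <- atchley_position_compare(human_grp, viral_grp)
  sig <- at[at$p_value < 0.05, ]
  cat("Atchley cells with p < 0.05:", nrow(sig), "of", nrow(at), "\n")
  write.table(at, file.path(out, "atchley_position_compare.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- aa_class_contingency(human_grp, viral_grp, position = 6)
  cat("position-6 class percentages:\n")
  print(ct$percent)
}
cat("done\n")
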