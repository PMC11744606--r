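# Self / viral / tumor epitope pool comparisons: anchor-trimmed sequence
# census, origin-class distance statistics, extreme-pair ranking,
# closest-match mimicry classification, resampling shift, and position-wise
# Atchley-factor and amino-acid-class statistics.

#' Atchley factor table
#'
#' The five physicochemical factor scores per amino acid (F1 polarity /
#' accessibility, F2 secondary-structure propensity, F3 molecular size,
#' F4 codon composition, F5 electrostatic charge), stored to 3 decimals.
#'
#' @return 20 x 5 numeric matrix, rows named by residue, columns F1..F5.
#' @export
atchley_factors <- function() {
  vals <- c(
    A = c(-0.591, -1.302, -0.733,  1.570, -0.146),
    C = c(-1.343,  0.465, -0.862, -1.020, -0.255),
    D = c( 1.050,  0.302, -3.656, -0.259, -3.242),
    E = c( 1.357, -1.453,  1.477,  0.113, -0.837),
    F = c(-1.006, -0.590,  1.891, -0.397,  0.412),
    G = c(-0.384,  1.652,  1.330,  1.045,  2.064),
    H = c( 0.336, -0.417, -1.673, -1.474, -0.078),
    I = c(-1.239, -0.547,  2.131,  0.393,  0.816),
    K = c( 1.831, -0.561,  0.533, -0.277,  1.648),
    L = c(-1.019, -0.987, -1.505,  1.266, -0.912),
    M = c(-0.663, -1.524,  2.219, -1.005,  1.212),
    N = c( 0.945,  0.828,  1.299, -0.169,  0.933),
    P = c( 0.189,  2.081, -1.628,  0.421, -1.392),
    Q = c( 0.931, -0.179, -3.005, -0.503, -1.853),
    R = c( 1.538, -0.055,  1.502,  0.440,  2.897),
    S = c(-0.228,  1.399, -4.760,  0.670, -2.647),
    T = c(-0.032,  0.326,  2.213,  0.908,  1.313),
    V = c(-1.337, -0.279, -0.544,  1.242, -1.262),
    W = c(-0.595,  0.009,  0.672, -2.128, -0.184),
    Y = c( 0.260,  0.830,  3.097, -0.838,  1.512)
  )
  matrix(vals, nrow = 20L, byrow = TRUE,
         dimnames = list(AMINO_ACIDS, paste0("F", 1:5)))
}

#' Default amino-acid property class map
#'
#' Partition of the 20 residues into Acid, Basic, Hydrophobic, Neutral and
#' Polar classes. An approximation of the five-class scheme used for
#' position-wise contingency tables; override by passing a different named
#' vector where accepted.
#'
#' @return Named character vector, residue -> class.
#' @export
aa_class_map <- function() {
  c(D = "Acid", E = "Acid",
    K = "Basic", R = "Basic", H = "Basic",
    A = "Hydrophobic", V = "Hydrophobic", L = "Hydrophobic",
    I = "Hydrophobic", M = "Hydrophobic", F = "Hydrophobic",
    W = "Hydrophobic", C = "Hydrophobic",
    G = "Neutral", P = "Neutral",
    S = "Polar", T = "Polar", N = "Polar", Q = "Polar", Y = "Polar")
}

#' Remove HLA anchor positions from a peptide
#'
#' Drops position 2 and the C-terminal anchor (position 9 of a nonamer,
#' position 10 of a decamer) — the residues buried in the HLA groove and
#' largely hidden from the TCR. Only 9- and 10-mers are trimmed; other
#' lengths are returned unchanged.
#'
#' @param seq Peptide string (vectorized).
#' @param lengths Peptide lengths subject to trimming.
#' @return Trimmed peptide string(s).
#' @export
trim_anchor_positions <- function(seq, lengths = c(9L, 10L)) {
  if (any(nchar(seq) < 3L)) stop("peptide too short to trim", call. = FALSE)
  vapply(seq, function(s) {
    n <- nchar(s)
    if (!n %in% lengths) return(s)
    chars <- strsplit(s, "")[[1]]
    paste(chars[-c(2L, n)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Census of sequences shared between the self and viral pools
#'
#' Deduplicates each pool (optionally after anchor trimming), intersects
#' them, and reports the shared percentage at 2 significant figures —
#' the printed-table style.
#'
#' @param self_pool,viral_pool Character vectors of peptides, all the same
#'   length within a call.
#' @param trimmed Apply [trim_anchor_positions()] first?
#' @return List with `restricted_count` (unique self sequences),
#'   `shared_count`, `shared_percent`.
#' @export
shared_sequence_census <- function(self_pool, viral_pool, trimmed = FALSE) {
  lens <- unique(nchar(c(self_pool, viral_pool)))
  if (length(lens) != 1L) {
    stop("mixed peptide lengths in one census call: ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  if (trimmed) {
    self_pool <- trim_anchor_positions(self_pool)
    viral_pool <- trim_anchor_positions(viral_pool)
  }
  self_u <- unique(self_pool)
  shared <- intersect(self_u, unique(viral_pool))
  list(
    restricted_count = length(self_u),
    shared_count = length(shared),
    shared_percent = shared_percent(length(shared), length(self_u))
  )
}

#' Shared percentage at printed precision
#'
#' `100 * shared / restricted`, rounded to 2 significant figures (the style
#' of census tables such as "168 (0.037%)").
#'
#' @param shared,restricted Counts.
#' @export
shared_percent <- function(shared, restricted) {
  if (restricted <= 0) stop("restricted count must be positive",
                            call. = FALSE)
  signif(100 * shared / restricted, 2)
}

#' Multiplicity histogram of a pool
#'
#' @param multiplicities Positive integer vector (occurrences of each unique
#'   sequence among predicted binders).
#' @return List with `histogram` (named counts) and `fraction_redundant`
#'   (share with multiplicity >= 2).
#' @export
redundancy_profile <- function(multiplicities) {
  stopifnot(all(multiplicities >= 1L))
  h <- table(multiplicities)
  list(histogram = h,
       fraction_redundant = mean(multiplicities >= 2L))
}

#' Per-class distance medians and Kruskal-Wallis test
#'
#' @param pairs Pair table with `distance` and `pair_class` columns.
#' @return List with `medians` (named by class) and `kruskal_p` (`NA` with a
#'   warning if only one class is present).
#' @export
classify_pair_distances <- function(pairs) {
  stopifnot(all(c("distance", "pair_class") %in% names(pairs)))
  med <- c(tapply(pairs$distance, pairs$pair_class, stats::median))
  if (length(unique(pairs$pair_class)) < 2L) {
    warning("single pair class; Kruskal-Wallis not defined")
    return(list(medians = med, kruskal_p = NA_real_))
  }
  kw <- stats::kruskal.test(pairs$distance, factor(pairs$pair_class))
  list(medians = med, kruskal_p = kw$p.value)
}

#' Extreme pairs: the n smallest and n largest distances
#'
#' @param pairs Pair table with `id_a`, `id_b`, `distance`.
#' @param n_each Pairs to take from each tail (default 300).
#' @return The 2 * n_each selected rows, each tail sorted ascending by
#'   distance (ties broken by canonical pair id), with a `tail` column
#'   (`"smallest"`/`"largest"`).
#' @export
extreme_pairs <- function(pairs, n_each = 300L) {
  if (nrow(pairs) < 2L * n_each) {
    stop("need at least ", 2L * n_each, " pairs, got ", nrow(pairs),
         call. = FALSE)
  }
  ord <- order(pairs$distance, pairs$id_a, pairs$id_b)
  low <- pairs[ord[seq_len(n_each)], ]
  high <- pairs[ord[seq.int(nrow(pairs) - n_each + 1L, nrow(pairs))], ]
  low$tail <- "smallest"
  high$tail <- "largest"
  out <- rbind(low, high)
  rownames(out) <- NULL
  out
}

#' Classify tumor epitopes by their closest self or viral match
#'
#' For each tumor epitope, finds the shortest distance to any self and any
#' viral epitope and labels it `CloserToHuman`, `CloserToViral`, or `Tie`
#' (exact equality, reported separately rather than silently assigned).
#'
#' @param tumor_ids Tumor epitope identifiers.
#' @param pair_distances Pair table with `id_a`, `id_b`, `distance`,
#'   `pair_class` containing `TH` and `TV` rows.
#' @return Data.frame with `tumor_id`, `nearest_self_distance`,
#'   `nearest_viral_distance`, `label`.
#' @export
closest_match_classification <- function(tumor_ids, pair_distances) {
  th <- pair_distances[pair_distances$pair_class == "TH", ]
  tv <- pair_distances[pair_distances$pair_class == "TV", ]
  nearest <- function(tab, id) {
    hit <- tab$id_a == id | tab$id_b == id
    if (!any(hit)) return(NA_real_)
    min(tab$distance[hit])
  }
  ns <- vapply(tumor_ids, nearest, numeric(1), tab = th)
  nv <- vapply(tumor_ids, nearest, numeric(1), tab = tv)
  bad <- tumor_ids[is.na(ns) | is.na(nv)]
  if (length(bad)) {
    stop("tumor id(s) missing a self or viral distance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  label <- ifelse(ns < nv, "CloserToHuman",
                  ifelse(ns > nv, "CloserToViral", "Tie"))
  data.frame(tumor_id = tumor_ids, nearest_self_distance = unname(ns),
             nearest_viral_distance = unname(nv), label = unname(label),
             stringsAsFactors = FALSE)
}

#' Distance shift between pools under repeated subsampling
#'
#' For each subsample size, repeatedly draws that many distances from the
#' self and viral pools and computes Cohen's d between the subsamples.
#'
#' @param self_distances,viral_distances Numeric pools.
#' @param sizes Subsample sizes (default 100 to 500 by 100).
#' @param reps Resampling repetitions per size (default 1000).
#' @param seed RNG seed; the result is reproducible given the seed.
#' @return Data.frame with `size`, `mean_d`, `sd_d`.
#' @export
resampling_shift <- function(self_distances, viral_distances,
                             sizes = seq(100L, 500L, by = 100L),
                             reps = 1000L, seed = 1L) {
  if (max(sizes) > length(self_distances) ||
      max(sizes) > length(viral_distances)) {
    stop("subsample size exceeds pool size", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(sizes, function(sz) {
      d <- replicate(reps, {
        cohens_d(sample(self_distances, sz), sample(viral_distances, sz))
      })
      data.frame(size = sz, mean_d = mean(d), sd_d = stats::sd(d))
    })
    do.call(rbind, rows)
  })
}

#' Position-wise Atchley factor comparison of two nonamer groups
#'
#' Assigns each residue its five factor scores and compares the two groups
#' at every (position, factor) cell with a two-sided Wilcoxon rank-sum test
#' (unadjusted p-values).
#'
#' @param group_a_seqs,group_b_seqs Character vectors of nonamers (n >= 3
#'   each).
#' @param table Factor table, default [atchley_factors()].
#' @return Data.frame with `position`, `factor`, `median_a`, `median_b`,
#'   `p_value` (45 rows).
#' @export
atchley_position_compare <- function(group_a_seqs, group_b_seqs,
                                     table = atchley_factors()) {
  if (any(nchar(c(group_a_seqs, group_b_seqs)) != 9L)) {
    stop("all sequences must be nonamers", call. = FALSE)
  }
  stopifnot(length(group_a_seqs) >= 3L, length(group_b_seqs) >= 3L)
  ca <- do.call(rbind, strsplit(group_a_seqs, ""))
  cb <- do.call(rbind, strsplit(group_b_seqs, ""))
  rows <- list()
  for (pos in 1:9) {
    for (f in colnames(table)) {
      va <- table[ca[, pos], f]
      vb <- table[cb[, pos], f]
      p <- if (stats::sd(c(va, vb)) == 0) 1 else
        suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE,
                                            correct = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, factor = f,
        median_a = stats::median(va), median_b = stats::median(vb),
        p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Amino-acid-class contingency table at one peptide position
#'
#' Counts the residues of each property class at the given position in two
#' groups, with column percentages at 1 decimal.
#'
#' @param group_a_seqs,group_b_seqs Character vectors of peptides.
#' @param position 1-based peptide position.
#' @param class_map Residue -> class map, default [aa_class_map()].
#' @param group_names Column labels.
#' @return List with `counts` (5 x 2 integer matrix), `percent` (5 x 2, one
#'   decimal), `totals` (length-2 group sizes).
#' @export
aa_class_contingency <- function(group_a_seqs, group_b_seqs, position,
                                 class_map = aa_class_map(),
                                 group_names = c("CloserToHuman",
                                                 "CloserToViral")) {
  if (position < 1L || any(nchar(c(group_a_seqs, group_b_seqs)) < position)) {
    stop("invalid position ", position, call. = FALSE)
  }
  classes <- sort(unique(class_map))
  count1 <- function(seqs) {
    res <- substr(seqs, position, position)
    table(factor(class_map[res], levels = classes))
  }
  counts <- cbind(count1(group_a_seqs), count1(group_b_seqs))
  colnames(counts) <- group_names
  totals <- colSums(counts)
  percent <- round(100 * sweep(counts, 2, totals, "/"), 1)
  list(counts = counts, percent = percent, totals = totals)
}
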