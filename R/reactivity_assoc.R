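# Association of pHLA dissimilarity with T-cell activation readouts:
# distance-to-reference correlations, low-dimensional embedding + regression
# of the composite images, variant difference maps, and the scan over
# feature-component combinations.

#' Distances of each epitope to a reference epitope
#'
#' @param ids Epitope identifiers to resolve.
#' @param distance_source A pair table (data.frame with `id_a`, `id_b`,
#'   `distance`, e.g. from [pairwise_distance_table()]) or a function
#'   `f(id, reference_id) -> number`.
#' @param reference_id The reference epitope; it maps to distance 0.
#' @return Named numeric vector, one entry per id.
#' @export
distance_to_reference <- function(ids, distance_source, reference_id) {
  if (is.function(distance_source)) {
    d <- vapply(ids, function(id) {
      if (id == reference_id) 0 else distance_source(id, reference_id)
    }, numeric(1))
    return(setNames(d, ids))
  }
  tab <- distance_source
  known <- unique(c(tab$id_a, tab$id_b))
  if (!reference_id %in% c(known, ids)) {
    stop("reference '", reference_id, "' not present in the distance source",
         call. = FALSE)
  }
  hit <- tab$id_a == reference_id | tab$id_b == reference_id
  other <- ifelse(tab$id_a[hit] == reference_id, tab$id_b[hit],
                  tab$id_a[hit])
  lut <- setNames(tab$distance[hit], other)
  lut[reference_id] <- 0
  missing_ids <- setdiff(ids, names(lut))
  if (length(missing_ids)) {
    stop("no distance to reference for: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  setNames(unname(lut[ids]), ids)
}

#' Correlate epitope distances with an activation readout
#'
#' Joins distances and assay rows on the variant identifier and computes a
#' Spearman (default) or Pearson correlation with a two-sided p-value.
#'
#' @param distances Named numeric vector (names are variant ids).
#' @param assay Data.frame with columns `variant_id` and `readout`.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `coefficient`, `p_value`, `n`.
#' @export
correlate_activation <- function(distances, assay,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  common <- intersect(names(distances), assay$variant_id)
  if (length(common) < 3L) {
    stop("need at least 3 paired observations, got ", length(common),
         call. = FALSE)
  }
  d <- distances[common]
  r <- assay$readout[match(common, assay$variant_id)]
  if (stats::sd(d) == 0 || stats::sd(r) == 0) {
    stop("correlation undefined: constant ",
         if (stats::sd(d) == 0) "distances" else "readout", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(d, r, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       n = length(common))
}

#' Embed composite images and regress a readout on the embedding
#'
#' Flattens the (masked) composite matrices to one vector per image, embeds
#' them in `n_dims` dimensions (deterministic PCA by default; UMAP with a
#' fixed seed as the alternative), then fits an ordinary least-squares
#' regression of the readout on the embedding dimensions.
#'
#' @param composites Named list of composite matrices (names = variant ids).
#' @param assay Data.frame with `variant_id` and `readout`.
#' @param n_dims Number of embedding dimensions (default 2).
#' @param method `"pca"` (deterministic) or `"umap"` (requires the uwot
#'   package; `n_neighbors = 30`, `min_dist = 0.3`, fixed seed).
#' @param mask Optional `PixelMask` applied before flattening.
#' @param seed Seed for the stochastic embedding.
#' @return List with `embedding` (n x n_dims matrix), `regression_p`
#'   (overall F-test p-value), and `per_dim_correlations` (Pearson r and p
#'   per dimension).
#' @export
embed_and_regress <- function(composites, assay, n_dims = 2L,
                              method = c("pca", "umap"), mask = NULL,
                              seed = 1L) {
  method <- match.arg(method)
  if (length(composites) < n_dims + 2L) {
    stop("need at least n_dims + 2 images", call. = FALSE)
  }
  flatten <- function(m) {
    if (!is.null(mask)) {
      keep <- if (inherits(mask, "PixelMask")) mask$keep else mask
      m[keep]
    } else as.numeric(m)
  }
  X <- do.call(rbind, lapply(composites, flatten))
  rownames(X) <- names(composites)

  emb <- if (method == "pca") {
    keep <- apply(X, 2, stats::sd) > 0
    p <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    p$x[, seq_len(n_dims), drop = FALSE]
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("method = 'umap' requires the uwot package", call. = FALSE)
    }
    nn <- min(30L, nrow(X) - 1L)
    with_seed(seed, uwot::umap(X, n_components = n_dims, n_neighbors = nn,
                               min_dist = 0.3))
  }
  colnames(emb) <- paste0("dim", seq_len(n_dims))

  common <- intersect(rownames(emb), assay$variant_id)
  if (length(common) < n_dims + 2L) {
    stop("too few images matched to assay rows", call. = FALSE)
  }
  y <- assay$readout[match(common, assay$variant_id)]
  E <- emb[common, , drop = FALSE]
  if (stats::sd(y) == 0) {
    return(list(embedding = emb, regression_p = NA_real_,
                per_dim_correlations = data.frame(dim = seq_len(n_dims),
                                                  r = NA_real_,
                                                  p_value = NA_real_)))
  }
  fit <- stats::lm(y ~ E)
  fs <- suppressWarnings(summary(fit))$fstatistic
  reg_p <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  per_dim <- do.call(rbind, lapply(seq_len(n_dims), function(j) {
    ct <- stats::cor.test(E[, j], y, method = "pearson")
    data.frame(dim = j, r = unname(ct$estimate), p_value = ct$p.value)
  }))
  list(embedding = emb, regression_p = reg_p,
       per_dim_correlations = per_dim)
}

#' Per-position composite differences of variants against a reference
#'
#' For every variant, averages (variant composite - reference composite)
#' over the pixel region of each peptide position. Under the composite
#' convention (red - blue + transparency) a positive entry is a gain of
#' negative surface charge relative to the reference.
#'
#' @param variant_composites Named list of composite matrices.
#' @param reference_composite The reference composite matrix.
#' @param position_regions List (length 9, named P1..P9) of pixel index
#'   vectors into the composite matrices; the synthetic renderer supplies
#'   these, external images need them configured.
#' @param by `"variant"` (default) returns a variant x position matrix;
#'   `"residue"` aggregates rows by the residue identity each variant has at
#'   each position, with `NA` where no variant carries that residue there.
#' @param variant_sequences Required for `by = "residue"`: named character
#'   vector of the variants' peptide sequences.
#' @return Numeric matrix of signed mean differences.
#' @export
variant_difference_map <- function(variant_composites, reference_composite,
                                   position_regions,
                                   by = c("variant", "residue"),
                                   variant_sequences = NULL) {
  by <- match.arg(by)
  if (any(lengths(position_regions) == 0L)) {
    stop("empty position region(s): ",
         paste(names(position_regions)[lengths(position_regions) == 0L],
               collapse = ", "), call. = FALSE)
  }
  pos_names <- names(position_regions) %||% paste0("P",
                                          seq_along(position_regions))
  vm <- do.call(rbind, lapply(variant_composites, function(comp) {
    delta <- comp - reference_composite
    vapply(position_regions, function(px) mean(delta[px]), numeric(1))
  }))
  dimnames(vm) <- list(names(variant_composites), pos_names)
  if (by == "variant") return(vm)

  if (is.null(variant_sequences)) {
    stop("by = 'residue' requires variant_sequences", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(variant_sequences[rownames(vm)], ""))
  out <- matrix(NA_real_, nrow = 20L, ncol = ncol(vm),
                dimnames = list(AMINO_ACIDS, pos_names))
  for (j in seq_len(ncol(vm))) {
    means <- tapply(vm[, j], factor(chars[, j], levels = AMINO_ACIDS), mean)
    out[, j] <- as.numeric(means)
  }
  out
}

#' Scan feature-component combinations for activation correlations
#'
#' For each configuration (component set x anchor trimming), builds feature
#' vectors from the per-variant residue tables, computes distances to the
#' reference and the Spearman correlation with the readout, and flags
#' significance at 0.05 (unadjusted).
#'
#' @param residue_tables Named list of residue feature data.frames, one per
#'   variant (names = variant ids), reference included.
#' @param assay Data.frame with `variant_id` and `readout`.
#' @param reference_id The reference variant id.
#' @param configs List of configurations, each a list with `components`
#'   (character subset of c, XYZ, r) and `trimmed` (logical); defaults to
#'   the full combination grid.
#' @param scope Structural scope for the feature vectors.
#' @return A `CombinationScan` data.frame: `label`, `components`, `trimmed`,
#'   `rho`, `p_value`, `significant`, `error`.
#' @export
combination_scan <- function(residue_tables, assay, reference_id,
                             configs = NULL, scope = "EPITOPE") {
  if (is.null(configs)) {
    sets <- list("c", "XYZ", "r", c("c", "XYZ"), c("c", "r"),
                 c("XYZ", "r"), c("c", "XYZ", "r"))
    configs <- do.call(c, lapply(sets, function(s) {
      list(list(components = s, trimmed = FALSE),
           list(components = s, trimmed = TRUE))
    }))
  }
  rows <- lapply(configs, function(cfg) {
    label <- paste0(if (cfg$trimmed) "tr_" else "",
                    paste(cfg$components, collapse = "+"))
    res <- tryCatch({
      vecs <- lapply(names(residue_tables), function(id) {
        build_feature_vector(residue_tables[[id]], scope = scope,
                             components = cfg$components,
                             trimmed = cfg$trimmed, epitope_id = id)
      })
      pt <- pairwise_distance_table(vecs)
      d <- distance_to_reference(setdiff(names(residue_tables),
                                         reference_id), pt, reference_id)
      ca <- correlate_activation(d, assay, method = "spearman")
      data.frame(label = label,
                 components = paste(cfg$components, collapse = "+"),
                 trimmed = cfg$trimmed, rho = ca$coefficient,
                 p_value = ca$p_value,
                 significant = ca$p_value < 0.05, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(label = label,
                 components = paste(cfg$components, collapse = "+"),
                 trimmed = cfg$trimmed, rho = NA_real_, p_value = NA_real_,
                 significant = NA, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("CombinationScan", class(out))
  out
}
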