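test_that("distance to reference resolves pair tables and maps ref to 0", {
  pt <- data.frame(
    id_a = c("A", "A", "B"), id_b = c("B", "C", "C"),
    distance = c(1, 2, 3), stringsAsFactors = FALSE
  )
  d <- distance_to_reference(c("A", "B", "C"), pt, reference_id = "A")
  expect_equal(unname(d), c(0, 1, 2))
  expect_named(d, c("A", "B", "C"))
  expect_error(distance_to_reference("B", pt, "Z"), "not present")

  # cross-module consistency: lookups match pairwise_distance_table entries
  mk <- function(id, vals) {
    structure(list(epitope_id = id, scope = "EPITOPE", components = "c",
                   trimmed = FALSE, values = vals), class = "FeatureVector")
  }
  set.seed(2)
  vecs <- lapply(c("r", "v1", "v2", "v3"), function(id) mk(id, rnorm(5)))
  tab <- pairwise_distance_table(vecs)
  d2 <- distance_to_reference(c("v1", "v2", "v3"), tab, "r")
  for (v in names(d2)) {
    expect_equal(d2[[v]],
                 euclidean_distance(vecs[[1]],
                                    vecs[[which(c("r", "v1", "v2", "v3") ==
                                                  v)]]))
  }
})

test_that("activation correlation recovers monotone and planted signals", {
  d <- setNames(seq(0.1, 3, length.out = 20), paste0("v", 1:20))
  assay <- data.frame(variant_id = names(d), readout = 100 - 10 * unname(d))
  perfect <- correlate_activation(d, assay)
  expect_equal(perfect$coefficient, -1)
  expect_equal(perfect$n, 20L)

  # Spearman is invariant under monotone transforms of either variable
  assay_exp <- transform(assay, readout = exp(readout / 50))
  expect_equal(correlate_activation(d, assay_exp)$coefficient, -1)
  expect_equal(correlate_activation(d^3, assay)$coefficient, -1)

  # planted negative dependence at 25% explained variance, n = 150
  set.seed(31)
  d150 <- setNames(runif(150, 0, 5), paste0("w", 1:150))
  cfg <- synthetic_config(seed = 44, planted_slope = -1,
                          noise_sd = sqrt(3) * stats::sd(d150))
  planted <- generate_activation_assay(d150, cfg)
  got <- correlate_activation(d150, planted)
  expect_lt(got$coefficient, -0.3)
  expect_lt(got$p_value, 1e-6)

  expect_error(correlate_activation(d[1:2], assay), "at least 3")
  flat <- data.frame(variant_id = names(d), readout = 1)
  expect_error(correlate_activation(d, flat), "constant")
})

test_that("null activation data yields null-scale correlations", {
  set.seed(17)
  hits <- 0L
  for (i in 1:20) {
    d <- setNames(runif(200), paste0("v", 1:200))
    assay <- data.frame(variant_id = names(d), readout = rnorm(200))
    ca <- correlate_activation(d, assay)
    if (abs(ca$coefficient) < 0.2 && ca$p_value > 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("embedding regression detects exact and planted associations", {
  # composites with a one-dimensional gradient dominating variance
  set.seed(23)
  n <- 24L
  grad <- seq(-1, 1, length.out = n)
  comps <- lapply(seq_len(n), function(i) {
    matrix(grad[i], 8, 8) + matrix(rnorm(64, sd = 0.01), 8, 8)
  })
  names(comps) <- paste0("v", seq_len(n))

  er <- embed_and_regress(comps,
                          data.frame(variant_id = names(comps), readout = 0),
                          method = "pca")
  # readout equal to dimension 1 exactly: perfect fit
  assay <- data.frame(variant_id = names(comps),
                      readout = er$embedding[, 1])
  er2 <- embed_and_regress(comps, assay, method = "pca")
  expect_lt(er2$regression_p, 1e-10)
  expect_gt(abs(er2$per_dim_correlations$r[1]), 0.999)

  # PCA embedding is bit-reproducible
  er3 <- embed_and_regress(comps, assay, method = "pca")
  expect_identical(er2$embedding, er3$embedding)

  expect_error(embed_and_regress(comps[1:3], assay, n_dims = 2,
                                 method = "pca"), "at least")
})

test_that("umap embedding runs with a fixed seed when uwot is present", {
  skip_if_not_installed("uwot")
  set.seed(29)
  comps <- lapply(1:30, function(i) matrix(rnorm(36, mean = i %% 3), 6, 6))
  names(comps) <- paste0("v", 1:30)
  assay <- data.frame(variant_id = names(comps), readout = rnorm(30))
  e1 <- embed_and_regress(comps, assay, method = "umap", seed = 7)
  e2 <- embed_and_regress(comps, assay, method = "umap", seed = 7)
  expect_equal(e1$embedding, e2$embedding)
  expect_equal(dim(e1$embedding), c(30L, 2L))
})

test_that("variant difference maps localize planted charge changes", {
  cfg <- fast_config(seed = 3)
  ref <- "ALWGPAPAA"                       # neutral P6
  acid <- "ALWGPDPAA"                      # D at P6: gain of negative
  basic <- "ALWGPKPAA"                     # K at P6: gain of positive
  imgs <- lapply(c(ref, acid, basic), function(s) {
    render_surface(generate_phla_structure(s, cfg), "TOP", cfg)
  })
  names(imgs) <- c(ref, acid, basic)
  comps <- lapply(imgs, function(i) i$composite)
  regions <- attr(imgs[[ref]], "position_regions")

  # variant identical to the reference: all-zero map
  vdm0 <- variant_difference_map(comps[ref], comps[[ref]], regions)
  expect_true(all(vdm0 == 0))

  vdm <- variant_difference_map(comps[c(acid, basic)], comps[[ref]],
                                regions)
  # largest-magnitude entry at P6; acidic positive, basic negative
  expect_equal(colnames(vdm)[which.max(abs(vdm[acid, ]))], "P6")
  expect_gt(vdm[acid, "P6"], 0)
  expect_lt(vdm[basic, "P6"], 0)

  empty <- regions
  empty$P4 <- integer(0)
  expect_error(variant_difference_map(comps[acid], comps[[ref]], empty),
               "empty position region")

  # residue view: residues never seen at a position are NA, not zero
  vdr <- variant_difference_map(comps[c(acid, basic)], comps[[ref]],
                                regions, by = "residue",
                                variant_sequences = setNames(c(acid, basic),
                                                             c(acid, basic)))
  expect_true(is.na(vdr["W", "P1"]))      # W never appears at P1
  expect_false(is.na(vdr["D", "P6"]))
  expect_equal(vdr["D", "P6"], vdm[acid, "P6"])
})

test_that("combination scan covers the requested grid and flags charge", {
  # residue tables where ONLY charge varies across variants
  set.seed(41)
  ids <- paste0("v", 0:14)
  tabs <- lapply(seq_along(ids), function(i) {
    toy_residue_table(epi_charges = c(0, 0, 0, 0, 0, (i - 1) / 10, 0, 0, 0))
  })
  names(tabs) <- ids
  assay <- data.frame(variant_id = ids[-1],
                      readout = 50 - 30 * (seq_along(ids[-1]) / 10) +
                        rnorm(14, sd = 0.5))

  configs <- do.call(c, lapply(list("c", c("c", "XYZ"), c("c", "XYZ", "r")),
                               function(s) list(
                                 list(components = s, trimmed = FALSE),
                                 list(components = s, trimmed = TRUE))))
  scan <- combination_scan(tabs, assay, reference_id = "v0",
                           configs = configs)
  expect_equal(nrow(scan), 6L)
  expect_true(all(is.na(scan$error)))
  expect_true(all(scan$rho[grepl("c", scan$components)] < -0.9))

  # configs without charge cannot resolve the (constant-geometry) distances
  bad <- combination_scan(tabs, assay, reference_id = "v0",
                          configs = list(list(components = "XYZ",
                                              trimmed = FALSE)))
  expect_false(is.na(bad$error[1]))
})
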