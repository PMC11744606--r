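test_that("generated structures have the fixed 276+99+9 topology", {
  cfg <- fast_config(seed = 2)
  st <- generate_phla_structure("GILGFVFTL", cfg)
  rows <- aggregate_residues(st)
  expect_equal(nrow(rows), 384L)
  expect_equal(sum(rows$role == "HLA"), 276L)
  expect_equal(sum(rows$role == "B2M"), 99L)
  expect_equal(sum(rows$role == "EPITOPE"), 9L)

  # planted charge: D at P6 gives a negative mean charge there
  st_d <- generate_phla_structure("ALWGPDPAA", cfg)
  epi <- apply_scope(aggregate_residues(st_d), "EPITOPE")
  expect_lt(epi$charge[6], 0)
  expect_equal(epi$charge[1], 0)
  # K positive, H weakly positive
  epi_k <- apply_scope(aggregate_residues(
    generate_phla_structure("ALWGPKPAA", cfg)), "EPITOPE")
  expect_gt(epi_k$charge[6], 0)

  # determinism: same sequence + seed -> identical structure
  expect_identical(generate_phla_structure("GILGFVFTL", cfg)$atoms,
                   st$atoms)
  expect_error(generate_phla_structure("ALWGPDPAX", cfg), "non-standard")
  expect_error(generate_phla_structure("ALWGPDPA", cfg), "9-mer")
})

test_that("rendered surfaces encode charge in the expected channels", {
  cfg <- fast_config(seed = 2)
  neutral <- render_surface(generate_phla_structure("ALWGPAPAA", cfg),
                            "TOP", cfg)
  inside <- neutral$alpha == 1
  expect_gt(sum(inside), 0)
  # the epitope region of an all-neutral peptide has red == blue
  regions <- attr(neutral, "position_regions")
  expect_named(regions, paste0("P", 1:9))
  px <- unlist(regions)
  expect_equal(neutral$red[px], neutral$blue[px])

  # acidic P6 vs neutral P6: composite difference positive, localized at P6
  acid <- render_surface(generate_phla_structure("ALWGPDPAA", cfg),
                         "TOP", cfg)
  delta <- acid$composite - neutral$composite
  expect_gt(mean(delta[regions$P6]), 0)
  expect_gt(mean(delta[regions$P6]), abs(mean(delta[regions$P1])))

  # rotating the view moves the projected footprint centroid
  centroid <- function(img) {
    w <- which(img$alpha == 1, arr.ind = TRUE)
    colMeans(w)
  }
  top <- centroid(neutral)
  tilted <- centroid(render_surface(generate_phla_structure("ALWGPAPAA",
                                                            cfg),
                                    "YP10", cfg))
  expect_gt(sqrt(sum((top - tilted)^2)), 0)
  expect_error(render_surface(generate_phla_structure("ALWGPAPAA", cfg),
                              "Z90", cfg), "unknown perspective")
})

test_that("generated TCR tables plant recoverable cross-reactive structure", {
  cfg <- fast_config(seed = 6)
  tcr <- generate_tcr_table(cfg, n_background = 40L, n_cross = 5L,
                            n_decoys = 4L)
  rec <- load_tcr_table(tcr)
  # retained rows = planted promiscuous (12 + 10) + cross + background;
  # every decoy fails exactly one filter
  drops <- attr(rec, "drop_counts")
  expect_equal(unname(drops[c("species", "mhc_class", "length", "allele")]),
               rep(4L, 4))
  planted <- attr(tcr, "planted_sets")
  sets <- find_crossreactive(rec)
  expect_equal(sort(sets[[1]]$epitopes), sort(planted[[1]]$epitopes))
  expect_equal(vapply(sets[1:2], function(s) length(s$epitopes),
                      integer(1)), c(12L, 10L))
  # exactly one 12-set and one 10-set
  sizes <- vapply(sets, function(s) length(s$epitopes), integer(1))
  expect_equal(sum(sizes == 12L), 1L)
  expect_equal(sum(sizes == 10L), 1L)

  # planted sets share positions 3/6/7 but have low overall identity
  eps <- sets[[1]]$epitopes
  pfm <- position_frequency_matrix(eps)
  expect_equal(sort(apply(pfm, 2, max), decreasing = TRUE)[1:3],
               rep(1, 3), ignore_attr = TRUE)
  expect_true(all(apply(pfm[, c(3, 6, 7)], 2, max) == 1))
  ident <- crossreactive_identity_profile(eps)
  expect_gt(mean(ident <= 100 / 3 + 1e-9), 0.5)
})

test_that("activation assays encode the planted monotone dependence", {
  d <- setNames(seq(0.2, 4, length.out = 30), paste0("v", 1:30))
  noiseless <- generate_activation_assay(
    d, synthetic_config(seed = 1, planted_slope = -2, noise_sd = 0)
  )
  expect_equal(correlate_activation(d, noiseless)$coefficient, -1)
  expect_true(all(noiseless$readout >= 0))

  # zero slope: no dependence planted
  flat <- generate_activation_assay(
    d, synthetic_config(seed = 1, planted_slope = 0, noise_sd = 1)
  )
  expect_gt(correlate_activation(d, flat)$p_value, 0.01)

  # seed determinism
  again <- generate_activation_assay(
    d, synthetic_config(seed = 1, planted_slope = -2, noise_sd = 0)
  )
  expect_identical(noiseless, again)
  expect_error(synthetic_config(planted_slope = 1), "<= 0")
})

test_that("epitope pools carry exact overlap and mimicry structure", {
  cfg0 <- fast_config(seed = 8, n_self = 200L, n_viral = 150L,
                      n_tumor = 20L, shared_fraction = 0)
  pools0 <- generate_epitope_pools(cfg0)
  expect_equal(shared_sequence_census(pools0$self$sequence,
                                      pools0$viral$sequence)$shared_count,
               0L)

  cfg <- fast_config(seed = 8, n_self = 2000L, n_viral = 1500L,
                     n_tumor = 30L, shared_fraction = 0.005)
  pools <- generate_epitope_pools(cfg)
  cen <- shared_sequence_census(pools$self$sequence, pools$viral$sequence)
  expect_equal(cen$restricted_count, 2000L)
  expect_equal(cen$shared_count, 10L)     # round(0.005 * 2000), exact
  expect_equal(nrow(pools$viral), 1500L)
  expect_false(any(duplicated(pools$self$sequence)))
  expect_false(any(duplicated(pools$viral$sequence)))

  # viral pool is less redundant than the self pool
  expect_lt(redundancy_profile(pools$viral$multiplicity)$fraction_redundant,
            redundancy_profile(pools$self$multiplicity)$fraction_redundant)

  # tumor mimics: one conservative substitution from their parent
  tum <- pools$tumor
  expect_equal(nrow(tum), 30L)
  same_chars <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }, tum$sequence, tum$parent)
  expect_true(all(same_chars == 8L))
  expect_true(all(tum$parent[tum$planted_origin == "SELF"] %in%
                    pools$self$sequence))
  expect_true(all(tum$parent[tum$planted_origin == "VIRAL"] %in%
                    pools$viral$sequence))

  # seed determinism
  pools2 <- generate_epitope_pools(cfg)
  expect_identical(pools, pools2)
})
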