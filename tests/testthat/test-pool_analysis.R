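test_that("anchor trimming removes P2 and the C-terminal anchor", {
  expect_equal(trim_anchor_positions("ALWGPDPAA"), "AWGPDPA")
  expect_equal(trim_anchor_positions("SLFNTVATL"), "SFNTVAT")
  expect_equal(trim_anchor_positions("ALWGPDPAAV"), "AWGPDPAA")  # decamer
  # 8- and 11-mers pass through untrimmed
  expect_equal(trim_anchor_positions("ALWGPDPA"), "ALWGPDPA")
  expect_equal(trim_anchor_positions("ALWGPDPAAVL"), "ALWGPDPAAVL")
  # trimming is not idempotent: a trimmed 7-mer would shorten again if
  # its length were re-admitted
  expect_equal(trim_anchor_positions("AWGPDPANL", lengths = 9L), "AGPDPAN")
  expect_error(trim_anchor_positions("AL"), "too short")
})

test_that("shared-sequence census equals brute-force set intersection", {
  expect_equal(
    shared_sequence_census(c("ALWGPDPAA", "SLFNTVATL"), c("GILGFVFTL")),
    list(restricted_count = 2L, shared_count = 0L, shared_percent = 0)
  )
  expect_error(shared_sequence_census(c("ALWGPDPAA", "ALWGPDPA"),
                                      "GILGFVFTL"), "mixed")

  set.seed(19)
  mk_pool <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "D", "K", "L", "S"), 9, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  self <- mk_pool(1000)
  viral <- mk_pool(1000)
  cen <- shared_sequence_census(self, viral)
  expect_equal(cen$restricted_count, length(unique(self)))
  expect_equal(cen$shared_count,
               length(intersect(unique(self), unique(viral))))

  # trimming can only merge sequences: shared count never decreases
  cen_tr <- shared_sequence_census(self, viral, trimmed = TRUE)
  expect_gte(cen_tr$shared_count, cen$shared_count)
})

test_that("shared percentages use 2 significant figures", {
  expect_equal(shared_percent(1, 8), 12)    # 12.5 -> 2 sf
  expect_equal(shared_percent(0, 100), 0)
  expect_error(shared_percent(1, 0), "positive")
})

test_that("redundancy profiles count multiplicities", {
  all_one <- redundancy_profile(c(1L, 1L, 1L))
  expect_equal(all_one$fraction_redundant, 0)
  mix <- redundancy_profile(c(2L, 2L, 1L))
  expect_equal(mix$fraction_redundant, 2 / 3)
  expect_equal(sum(mix$histogram), 3L)
})

test_that("pair-class medians and Kruskal-Wallis behave under shift", {
  set.seed(37)
  pairs <- data.frame(
    distance = c(rnorm(100, 10), rnorm(100, 10), rnorm(100, 20)),
    pair_class = rep(c("HH", "HV", "VV"), each = 100),
    stringsAsFactors = FALSE
  )
  res <- classify_pair_distances(pairs)
  for (cl in c("HH", "HV", "VV")) {
    expect_equal(res$medians[[cl]],
                 median(pairs$distance[pairs$pair_class == cl]))
  }
  expect_lt(res$kruskal_p, 1e-6)

  null_pairs <- transform(pairs, distance = rnorm(300, 10))
  expect_gt(classify_pair_distances(null_pairs)$kruskal_p, 1e-4)

  single <- pairs[pairs$pair_class == "HH", ]
  expect_warning(res1 <- classify_pair_distances(single), "single")
  expect_true(is.na(res1$kruskal_p))
  expect_equal(unname(res1$medians), median(single$distance))
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(43)
  p <- replicate(300, {
    kw <- classify_pair_distances(data.frame(
      distance = rnorm(60), pair_class = rep(c("HH", "HV", "VV"), 20)
    ))
    kw$kruskal_p
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("extreme pairs take each tail, sorted with canonical tie-break", {
  set.seed(47)
  pairs <- data.frame(
    id_a = sprintf("a%03d", 1:700), id_b = sprintf("b%03d", 1:700),
    distance = sample(rep(1:350, 2)), stringsAsFactors = FALSE
  )
  ex <- extreme_pairs(pairs, n_each = 300L)
  expect_equal(nrow(ex), 600L)
  low <- ex[ex$tail == "smallest", ]
  high <- ex[ex$tail == "largest", ]
  expect_lte(max(low$distance), min(high$distance))
  expect_false(is.unsorted(low$distance))
  expect_false(is.unsorted(high$distance))

  # matches a full-sort oracle
  srt <- pairs[order(pairs$distance, pairs$id_a, pairs$id_b), ]
  expect_equal(low$distance, srt$distance[1:300])
  expect_equal(high$id_a, srt$id_a[401:700])

  expect_error(extreme_pairs(pairs[1:100, ], n_each = 300L), "at least")
})

test_that("closest-match labels partition the tumor set", {
  pd <- data.frame(
    id_a = c("T1", "T1", "T2", "T2", "T3", "T3"),
    id_b = c("H1", "V1", "H1", "V1", "H1", "V1"),
    distance = c(1, 2, 5, 3, 4, 4),
    pair_class = c("TH", "TV", "TH", "TV", "TH", "TV"),
    stringsAsFactors = FALSE
  )
  cls <- closest_match_classification(c("T1", "T2", "T3"), pd)
  expect_equal(cls$label, c("CloserToHuman", "CloserToViral", "Tie"))
  expect_equal(cls$nearest_self_distance, c(1, 5, 4))
  expect_equal(nrow(cls), 3L)
  expect_equal(sum(table(cls$label)), 3L)   # labels partition the set
  expect_error(closest_match_classification("T9", pd), "T9")
})

test_that("resampling shift is seed-deterministic and calibrated", {
  set.seed(53)
  pool <- rnorm(600)
  null_shift <- resampling_shift(pool, pool, sizes = c(100L, 200L),
                                 reps = 200L, seed = 5L)
  expect_true(all(abs(null_shift$mean_d) < 0.1))

  shifted <- resampling_shift(pool + 1, pool, sizes = c(100L, 200L),
                              reps = 200L, seed = 5L)
  expect_true(all(abs(shifted$mean_d - 1) < 0.15))

  again <- resampling_shift(pool + 1, pool, sizes = c(100L, 200L),
                            reps = 200L, seed = 5L)
  expect_identical(shifted, again)
  expect_error(resampling_shift(pool[1:50], pool, sizes = 100L,
                                reps = 10L), "exceeds")
})

test_that("Atchley position comparison finds planted acidic enrichment", {
  at <- atchley_factors()
  expect_equal(dim(at), c(20L, 5L))
  expect_equal(rownames(at), phlacross:::AMINO_ACIDS)

  grp <- rep("ALWGPDPAA", 10)
  same <- atchley_position_compare(grp, grp)
  expect_equal(nrow(same), 45L)
  expect_true(all(same$p_value == 1))
  expect_equal(same$median_a, same$median_b)

  # medians match a direct lookup-and-median oracle
  set.seed(59)
  a_seqs <- replicate(20, paste(sample(phlacross:::AMINO_ACIDS, 9,
                                       replace = TRUE), collapse = ""))
  b_seqs <- replicate(20, paste(sample(phlacross:::AMINO_ACIDS, 9,
                                       replace = TRUE), collapse = ""))
  cmp <- atchley_position_compare(a_seqs, b_seqs)
  for (k in sample(nrow(cmp), 5)) {
    pos <- cmp$position[k]; f <- cmp$factor[k]
    expect_equal(cmp$median_a[k],
                 median(at[substr(a_seqs, pos, pos), f]))
  }

  # planted: group B acidic at P6, group A hydrophobic at P6
  a6 <- vapply(a_seqs, function(s) {
    substr(s, 6, 6) <- "L"; s
  }, character(1), USE.NAMES = FALSE)
  b6 <- vapply(b_seqs, function(s) {
    substr(s, 6, 6) <- sample(c("D", "E"), 1); s
  }, character(1), USE.NAMES = FALSE)
  planted <- atchley_position_compare(a6, b6)
  best <- planted[which.min(planted$p_value), ]
  expect_equal(best$position, 6)

  expect_error(atchley_position_compare("ALWGPDPA", grp), "nonamer")
})

test_that("amino-acid class contingency reports counts and percentages", {
  cm <- aa_class_map()
  expect_length(cm, 20L)
  expect_setequal(unique(cm),
                  c("Acid", "Basic", "Hydrophobic", "Neutral", "Polar"))

  # two toy groups with known P2 composition
  a <- c("ADAAAAAAA", "AKAAAAAAA", "ALAAAAAAA", "ALAAAAAAA")
  b <- c("ASAAAAAAA", "AGAAAAAAA")
  ct <- aa_class_contingency(a, b, position = 2)
  expect_equal(unname(ct$totals), c(4L, 2L))
  expect_equal(ct$counts["Hydrophobic", 1], 2L)
  expect_equal(ct$percent["Hydrophobic", 1], 50)
  expect_equal(unname(colSums(ct$counts)), c(4L, 2L))
  expect_error(aa_class_contingency(a, b, position = 15), "invalid position")
})
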