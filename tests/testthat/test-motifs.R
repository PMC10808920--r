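units6 <- unit_table(c("zi_1", "zi_2", "zi_3", "lgd_1", "lgd_2", "snr_1"),
                     c("ZI", "ZI", "ZI", "LGd", "LGd", "SNr"))

test_that("pair classification follows lag sign and area membership", {
  fit <- fake_fit(list(
    pair_row("zi_1", "lgd_1", "ZI", "LGd", 2, bin = 0.03),
    pair_row("snr_1", "zi_2", "SNr", "ZI", 4, bin = 0.02),
    pair_row("zi_1", "zi_2", "ZI", "ZI", 0),
    pair_row("zi_2", "zi_3", "ZI", "ZI", 3),
    pair_row("lgd_1", "lgd_2", "LGd", "LGd", 1),
    pair_row("lgd_1", "snr_1", "LGd", "SNr", 2),
    pair_row("zi_3", "lgd_2", "ZI", "LGd", 0)
  ), units6)
  m <- classify_motifs(fit)
  expect_equal(m$klass,
               c("pair_from_focal", "pair_to_focal", "pair_internal_focal",
                 "pair_internal_focal", "pair_internal_other",
                 "pair_external_other", "pair_synchronous"))
  # the worked delays: ZI leads LGd by 2 bins of 30 ms -> 60 ms out of ZI;
  # SNr leads ZI by 4 bins of 20 ms -> 80 ms into ZI
  expect_equal(m$delay_ms[1], 60)
  expect_equal(m$direction[1], 1L)
  expect_equal(m$delay_ms[2], 80)
  expect_equal(m$direction[2], -1L)
  expect_equal(m$partner_area[1], "LGd")
  expect_equal(m$partner_area[2], "SNr")
})

test_that("triplet classification agrees with the exhaustive rule checker", {
  focal <- "ZI"
  lag_sets <- list(c(0, 1, 2), c(0, 0, 2), c(0, 1, 1), c(0, 0, 0),
                   c(0, 2, 5))
  area_grid <- expand.grid(a1 = c("ZI", "MS"), a2 = c("ZI", "MS"),
                           a3 = c("ZI", "MS"), stringsAsFactors = FALSE)
  for (lags in lag_sets) {
    for (i in seq_len(nrow(area_grid))) {
      areas <- unlist(area_grid[i, ], use.names = FALSE)
      got <- assemblymotifs:::classify_triplet_row(areas, lags, focal)$klass
      expect_equal(got, oracle_classify_triplet(areas, lags, focal),
                   info = paste(c(areas, lags), collapse = ","))
    }
  }
})

test_that("three-area triplets are handled defensively as non-loop", {
  got <- assemblymotifs:::classify_triplet_row(c("MS", "ZI", "LGd"),
                                               c(0, 1, 2), "ZI")
  expect_equal(got$klass, "triplet_non_loop")
})

test_that("canonical loop examples classify as stated by the taxonomy", {
  fit <- fake_fit(list(
    triplet_row(c("zi_1", "lgd_1", "zi_2"), c("ZI", "LGd", "ZI"), c(0, 1, 2)),
    triplet_row(c("lgd_1", "zi_2", "lgd_2"), c("LGd", "ZI", "LGd"),
                c(0, 2, 5)),
    triplet_row(c("zi_1", "lgd_1", "zi_3"), c("ZI", "LGd", "ZI"), c(0, 0, 3))
  ), units6)
  m <- classify_motifs(fit)
  expect_equal(m$klass[m$order == 3],
               c("triplet_loop_focal", "triplet_loop_external",
                 "triplet_non_loop"))
})

test_that("pairwise support requires both chain-adjacent pairs", {
  rows <- list(
    pair_row("zi_1", "lgd_1", "ZI", "LGd", 1),
    pair_row("lgd_1", "zi_2", "LGd", "ZI", 1),
    triplet_row(c("zi_1", "lgd_1", "zi_2"), c("ZI", "LGd", "ZI"), c(0, 1, 2)),
    triplet_row(c("zi_2", "lgd_2", "zi_3"), c("ZI", "LGd", "ZI"), c(0, 1, 2))
  )
  fit <- fake_fit(rows, units6)
  m <- classify_motifs(fit)
  trip <- m[m$order == 3, ]
  expect_true(trip$pairwise_supported[1])
  expect_false(trip$pairwise_supported[2])
  expect_true(pairwise_support(c("zi_1", "lgd_1", "zi_2"), fit))
  expect_false(pairwise_support(c("zi_2", "lgd_2", "zi_3"), fit))
})

test_that("classification is total: every assembly receives exactly one class", {
  sc <- make_scenario("loops_mixed", seed = 9)
  m <- classify_motifs(detect_assemblies(sc$session))
  valid <- c("pair_synchronous", "pair_from_focal", "pair_to_focal",
             "pair_external_other", "pair_internal_focal",
             "pair_internal_other", "triplet_loop_focal",
             "triplet_loop_external", "triplet_non_loop")
  expect_true(all(m$klass %in% valid))
  expect_false(anyNA(m$klass))
})

test_that("coverage categories implement the at-least-half rule with ties counted", {
  # N = 13 partner areas available, unit paired with k = 7: 2k >= N
  ids <- c("zi_1", sprintf("x%02d_1", 1:13))
  areas <- c("ZI", sprintf("X%02d", 1:13))
  units <- unit_table(ids, areas)
  rows <- lapply(1:7, function(i) {
    pair_row("zi_1", sprintf("x%02d_1", i), "ZI", sprintf("X%02d", i), 1)
  })
  m <- classify_motifs(fake_fit(rows, units))
  cov <- assembly_coverage(m)
  expect_equal(cov$category[cov$unit_id == "zi_1"], "ge_half_not_all")
  expect_equal(cov$n_partner_areas[1], 7L)
  expect_equal(cov$n_areas_available[1], 13L)
})

test_that("coverage spans all five mutually exclusive categories", {
  ids <- c(sprintf("zi_%d", 1:5), "a_1", "b_1")
  units <- unit_table(ids, c(rep("ZI", 5), "A", "B"))
  rows <- list(
    pair_row("zi_2", "zi_3", "ZI", "ZI", 0),          # internal only (zi_2)
    pair_row("zi_3", "a_1", "ZI", "A", 1),            # zi_3: 1 of 2 ext
    pair_row("zi_4", "a_1", "ZI", "A", 1),            # zi_4: all ext
    pair_row("zi_4", "b_1", "ZI", "B", 2),
    pair_row("zi_5", "a_1", "ZI", "A", 1)             # zi_5: 1 of 2 -> >= half
  )
  cov <- assembly_coverage(classify_motifs(fake_fit(rows, units)))
  got <- setNames(cov$category, cov$unit_id)
  expect_equal(unname(got["zi_1"]), "no_int_no_ext")
  expect_equal(unname(got["zi_2"]), "only_int")
  expect_equal(unname(got["zi_3"]), "ge_half_not_all") # k=1, N=2: 2k >= N
  expect_equal(unname(got["zi_4"]), "all_ext")
  # with N = 2 external areas, k = 1 ties at half; lt_half needs N > 2k
  units3 <- unit_table(c("zi_9", "a_1", "b_1", "c_1"),
                       c("ZI", "A", "B", "C"))
  cov3 <- assembly_coverage(classify_motifs(fake_fit(
    list(pair_row("zi_9", "a_1", "ZI", "A", 1)), units3)))
  expect_equal(cov3$category, "lt_half_ext_at_least_1")
})

test_that("loop membership crosstab partitions focal units and fractions sum to one", {
  sc <- make_scenario("loops_mixed", seed = 5)
  m <- classify_motifs(detect_assemblies(sc$session))
  ct <- loop_membership_crosstab(m)
  n_focal <- sum(attr(m, "units")$area == "ZI")
  expect_equal(sum(ct$crosstab), n_focal)
  sums <- rowSums(ct$fractions)
  for (s in sums[rowSums(ct$crosstab) > 0]) expect_equal(unname(s), 1)
  # planted loop members land in the loop branch
  loop_units <- unique(unlist(lapply(
    Filter(function(p) anyDuplicated(p$lags_bins) == 0L &&
             length(p$unit_ids) == 3, sc$ground_truth$planted),
    function(p) p$unit_ids)))
  loop_zi <- intersect(loop_units,
                       attr(m, "units")$unit_id[attr(m, "units")$area == "ZI"])
  loops <- m[m$klass %in% c("triplet_loop_focal", "triplet_loop_external"), ]
  for (u in loop_zi) {
    expect_true(any(loops$unit_1 == u | loops$unit_2 == u | loops$unit_3 == u))
  }
})

test_that("no triplets puts every focal unit in the non-loop branch", {
  m <- classify_motifs(fake_fit(list(
    pair_row("zi_1", "lgd_1", "ZI", "LGd", 1)), units6))
  ct <- loop_membership_crosstab(m)
  expect_equal(sum(ct$crosstab["loop_like", ]), 0)
  expect_equal(sum(ct$crosstab["non_loop_only", ]), 3)
})
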