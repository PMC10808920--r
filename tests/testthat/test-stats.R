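test_that("normalized probabilities match their defining arithmetic", {
  expect_equal(p_pairs_ext(0, 5, 7), 0)
  expect_equal(p_pairs_ext(6, 3, 4), 0.5)
  expect_equal(p_pairs_ext(12, 3, 4), 1) # every cross pair an assembly
  expect_equal(p_pairs_int(0, 10), 0)
  expect_equal(p_pairs_int(3, 4), 0.5)
  expect_equal(p_looplike(0, 4, 3), 0)
  expect_equal(p_looplike(3, 3, 2), 1 / 3)
  expect_equal(p_looplike_structured(0, 4, 3), 0)
  expect_equal(p_looplike_structured(6, 3, 2), 1) # saturation
  expect_error(p_pairs_int(1, 1), "at least 2")
  expect_error(p_looplike(1, 1, 1), "no loop-like triple")
  expect_error(p_looplike_structured(1, 1, 5), "at least 2")
})

test_that("probability denominators equal exhaustive configuration counts", {
  for (n_a in 2:6) {
    expect_equal(choose(n_a, 2), oracle_n_internal_pairs(n_a))
    for (n_b in 1:6) {
      aba <- n_a * n_b * (n_a - 1)
      expect_equal(aba / 2, oracle_n_aba_triples(n_a, n_b))
      loop_denom <- n_a * n_b * (n_a - 1) + n_b * n_a * (n_b - 1)
      expect_equal(loop_denom / 2, oracle_n_loop_triples(n_a, n_b))
    }
  }
})

test_that("the expected loop probability equals the enumerated structure ratio", {
  expect_equal(expected_loop_prob(2, 1), 1)
  expect_equal(expected_loop_prob(3, 2), 2 / 3)
  expect_equal(oracle_n_aba_triples(3, 2) / oracle_n_loop_triples(3, 2), 2 / 3)
  for (n_a in 1:6) {
    for (n_b in 1:6) {
      if (n_a + n_b < 3) next
      enum <- oracle_n_loop_triples(n_a, n_b)
      if (enum > 0) {
        expect_equal(expected_loop_prob(n_a, n_b),
                     oracle_n_aba_triples(n_a, n_b) / enum)
      }
      if (n_a >= 1 && n_b >= 1) {
        expect_equal(expected_loop_prob(n_a, n_b) +
                       expected_loop_prob(n_b, n_a), 1)
      }
    }
  }
})

test_that("the Int-Ext index is 0.5 at equality and hits its boundaries", {
  expect_equal(int_ext_index(0.01, 0.01), 0.5)
  expect_equal(int_ext_index(0.02, 0), 1)
  expect_equal(int_ext_index(0, 0.02), 0)
  expect_warning(res <- int_ext_index(0, 0), "undefined")
  expect_true(is.nan(res))
})

test_that("directional binomial tests are exact, symmetric, and threshold-gated", {
  t1 <- binom_direction_test(8, 2)
  expect_true(t1$tested)
  expect_equal(t1$p_value, 0.109375, tolerance = 1e-12)
  expect_equal(t1$p_value, oracle_binom_two_sided(8, 10, 0.5),
               tolerance = 1e-12)
  expect_equal(binom_direction_test(2, 8)$p_value, t1$p_value,
               tolerance = 1e-15)
  expect_equal(binom_direction_test(5, 5)$p_value, 1)
  t2 <- binom_direction_test(4, 3)
  expect_false(t2$tested)
  expect_true(is.na(t2$p_value))
  set.seed(2)
  for (r in 1:20) {
    n <- sample(10:40, 1); x <- sample(0:n, 1)
    expect_equal(binom_direction_test(x, n - x)$p_value,
                 oracle_binom_two_sided(x, n, 0.5), tolerance = 1e-12)
  }
})

test_that("loop-structure tests use the combinatorial null", {
  # equal unit counts: null 0.5, observed exactly at the null -> p = 1
  t0 <- binom_loop_test(6, 12, 4, 4)
  expect_equal(t0$null_prob, 0.5)
  expect_equal(t0$p_value, 1)
  t1 <- binom_loop_test(9, 12, 4, 4)
  expect_equal(t1$p_value, oracle_binom_two_sided(9, 12, 0.5),
               tolerance = 1e-12)
  # degenerate null: with 2 vs 1 units only A->B->A exists
  t2 <- binom_loop_test(12, 12, 2, 1)
  expect_equal(t2$null_prob, 1)
  expect_equal(t2$p_value, 1)
  expect_false(binom_loop_test(3, 5, 4, 4)$tested)
  set.seed(5)
  for (r in 1:20) {
    n_a <- sample(2:8, 1); n_b <- sample(2:8, 1)
    n <- sample(10:30, 1); x <- sample(0:n, 1)
    expect_equal(binom_loop_test(x, n, n_a, n_b)$p_value,
                 oracle_binom_two_sided(x, n, expected_loop_prob(n_a, n_b)),
                 tolerance = 1e-9)
  }
})

test_that("the doubled-tail method is a valid alternative and caps at 1", {
  t <- binom_direction_test(8, 2, method = "double")
  expect_equal(t$p_value,
               min(1, 2 * min(pbinom(8, 10, 0.5),
                              pbinom(7, 10, 0.5, lower.tail = FALSE))))
  expect_lte(binom_direction_test(5, 5, method = "double")$p_value, 1)
})

test_that("loop-structure test keeps its nominal size under the combinatorial null", {
  set.seed(11)
  n_a <- 5; n_b <- 3
  p0 <- expected_loop_prob(n_a, n_b)
  n_rep <- 2000
  n <- 25
  draws <- rbinom(n_rep, n, p0)
  p <- vapply(draws, function(x) binom_loop_test(x, n, n_a, n_b)$p_value,
              numeric(1))
  expect_lte(mean(p <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("session pooling sums numerators and denominators, not ratios", {
  base <- function(sid, n_pairs, n_a, n_b) {
    data.frame(session_id = sid, area_a = "ZI", area_b = "MS",
               n_a = n_a, n_b = n_b,
               n_pairs_from = n_pairs, n_pairs_to = 0L, n_pairs_sync = 0L,
               n_pairs_ext = n_pairs, n_pairs_int_focal = 0L,
               n_loops_aba = 0L, n_loops_bab = 0L, n_loops_total = 0L,
               denom_ext = n_a * n_b, denom_int = choose(n_a, 2),
               denom_loop = n_a * n_b * (n_a - 1) + n_b * n_a * (n_b - 1),
               denom_loop_aba = n_a * n_b * (n_a - 1),
               stringsAsFactors = FALSE)
  }
  s1 <- base("a", 1L, 2L, 5L) # denom 10
  s2 <- base("b", 1L, 5L, 8L) # denom 40
  pooled <- pool_sessions(list(s1, s2))
  expect_equal(pooled$n_pairs_ext / pooled$denom_ext, 2 / 50)
  expect_false(isTRUE(all.equal(2 / 50, mean(c(1 / 10, 1 / 40)))))
  # single session is the identity
  p1 <- pool_sessions(list(s1))
  expect_equal(p1$n_pairs_ext / p1$denom_ext, 0.1)
  # order invariance and associativity
  pooled_rev <- pool_sessions(list(s2, s1))
  expect_equal(pooled$n_pairs_ext, pooled_rev$n_pairs_ext)
  expect_equal(pooled$denom_ext, pooled_rev$denom_ext)
  s3 <- base("c", 3L, 4L, 4L)
  left <- pool_sessions(list(pool_sessions(list(s1, s2)), s3))
  flat <- pool_sessions(list(s1, s2, s3))
  expect_equal(left$n_pairs_ext, flat$n_pairs_ext)
  expect_equal(left$denom_ext, flat$denom_ext)
  expect_error(pool_sessions(list()), "nothing to pool")
})

test_that("area statistics aggregate a classified motif set consistently", {
  units <- unit_table(c("zi_1", "zi_2", "zi_3", "ms_1", "ms_2", "lgd_1"),
                      c("ZI", "ZI", "ZI", "MS", "MS", "LGd"))
  rows <- list(
    pair_row("zi_1", "ms_1", "ZI", "MS", 2),
    pair_row("ms_2", "zi_2", "MS", "ZI", 1),
    pair_row("zi_1", "ms_2", "ZI", "MS", 0),
    pair_row("zi_1", "zi_2", "ZI", "ZI", 1),
    pair_row("zi_1", "lgd_1", "ZI", "LGd", 3),
    triplet_row(c("zi_1", "ms_1", "zi_2"), c("ZI", "MS", "ZI"), c(0, 1, 2)),
    triplet_row(c("ms_1", "zi_3", "ms_2"), c("MS", "ZI", "MS"), c(0, 1, 3))
  )
  m <- classify_motifs(fake_fit(rows, units))
  st <- area_pair_stats(m)
  ms <- st[st$area_b == "MS", ]
  expect_equal(ms$n_pairs_from, 1L)
  expect_equal(ms$n_pairs_to, 1L)
  expect_equal(ms$n_pairs_sync, 1L)
  expect_equal(ms$n_pairs_ext, 3L)
  expect_equal(ms$n_loops_aba, 1L)
  expect_equal(ms$n_loops_bab, 1L)
  expect_equal(ms$n_pairs_int_focal, 1L)
  expect_equal(ms$n_a, 3L)
  expect_equal(ms$n_b, 2L)
  sm <- area_pair_summary(st)
  expect_equal(sm$p_ext[sm$area_b == "MS"], 3 / 6)
  expect_equal(sm$p_int[sm$area_b == "MS"], 1 / 3)
  expect_equal(sm$p_loop[sm$area_b == "MS"],
               2 * 2 / (3 * 2 * 2 + 2 * 3 * 1))
  expect_equal(sm$int_ext[sm$area_b == "MS"], (1 / 2) / (1 / 2 + 1 / 3))
})

test_that("area ranking is descending with alphabetical tie-breaks", {
  tab <- data.frame(area_a = "ZI", area_b = c("B", "A", "C"),
                    p_ext = c(0.1, 0.3, 0.1), p_loop = c(0.2, 0.1, 0.3),
                    p_sync = c(0.05, 0.05, 0.05))
  r <- rank_areas(tab, "pairs")
  expect_equal(r$area_b, c("A", "B", "C"))
  r2 <- rank_areas(tab, "loops")
  expect_equal(r2$area_b, c("C", "B", "A"))
  expect_equal(rank_areas(tab, "sync")$area_b, c("A", "B", "C"))
  expect_error(rank_areas(tab[0, ], "pairs"), "empty")
})
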