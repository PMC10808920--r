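# Independent oracles and small fixture builders used across the suite.

# Brute-force lagged coincidence count: double loop over bins.
oracle_profile <- function(x_a, x_b, max_lag, binarize = TRUE) {
  if (binarize) {
    x_a <- as.integer(x_a > 0)
    x_b <- as.integer(x_b > 0)
  }
  n <- length(x_a)
  lags <- -max_lag:max_lag
  out <- integer(length(lags))
  for (k in seq_along(lags)) {
    l <- lags[k]
    acc <- 0L
    for (t in seq_len(n)) {
      u <- t + l
      if (u >= 1L && u <= n) acc <- acc + min(x_a[t], x_b[u])
    }
    out[k] <- acc
  }
  names(out) <- lags
  out
}

# Exact two-sided binomial p-value by tail-sum enumeration
# (minimum-likelihood rule: sum P(k) over outcomes no more likely than x).
oracle_binom_two_sided <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Exhaustive enumeration of unit configurations on labeled toy areas.
oracle_n_internal_pairs <- function(n_a) {
  if (n_a < 2) return(0L)
  ncol(utils::combn(n_a, 2))
}

# Unordered A->B->A triples: a pair {a1, a2} from A plus a middle b from B.
oracle_n_aba_triples <- function(n_a, n_b) {
  if (n_a < 2 || n_b < 1) return(0L)
  oracle_n_internal_pairs(n_a) * n_b
}

oracle_n_loop_triples <- function(n_a, n_b) {
  oracle_n_aba_triples(n_a, n_b) + oracle_n_aba_triples(n_b, n_a)
}

# Rule-checker for the triplet taxonomy, written straight from the
# definition: strictly sequential chain, flanking units in one area,
# middle unit in the other, exactly two areas involved.
oracle_classify_triplet <- function(areas, lags, focal) {
  strictly_sequential <- anyDuplicated(lags) == 0L
  flanks_match <- areas[1] == areas[3]
  middle_differs <- areas[2] != areas[1]
  spans_two <- length(unique(areas)) == 2L
  if (!(strictly_sequential && flanks_match && middle_differs && spans_two)) {
    return("triplet_non_loop")
  }
  if (areas[1] == focal) return("triplet_loop_focal")
  if (areas[2] == focal) return("triplet_loop_external")
  "triplet_non_loop"
}

# Minimal assembly_set with hand-written assembly rows, for classifier and
# reporting tests that do not need the detector.
fake_fit <- function(rows, units, focal = "ZI", session_id = "fx",
                     duration = 100) {
  empty <- data.frame(
    order = integer(0), unit_1 = character(0), unit_2 = character(0),
    unit_3 = character(0), area_1 = character(0), area_2 = character(0),
    area_3 = character(0), lag_1 = integer(0), lag_2 = integer(0),
    lag_3 = integer(0), bin_size = numeric(0), count = integer(0),
    p_value = numeric(0), p_adj = numeric(0), stringsAsFactors = FALSE)
  asm <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(assemblies = asm, session_id = session_id,
                 duration = duration, focal_area = focal, units = units,
                 config = detection_config(), n_pair_tests = 0L),
            class = "assembly_set")
}

pair_row <- function(u1, u2, a1, a2, lag, bin = 0.03, count = 50,
                     p = 1e-6) {
  data.frame(order = 2L, unit_1 = u1, unit_2 = u2, unit_3 = NA,
             area_1 = a1, area_2 = a2, area_3 = NA,
             lag_1 = 0L, lag_2 = as.integer(lag), lag_3 = NA_integer_,
             bin_size = bin, count = count, p_value = p, p_adj = p,
             stringsAsFactors = FALSE)
}

triplet_row <- function(u, a, lags, bin = 0.03, count = 30, p = 1e-6) {
  data.frame(order = 3L, unit_1 = u[1], unit_2 = u[2], unit_3 = u[3],
             area_1 = a[1], area_2 = a[2], area_3 = a[3],
             lag_1 = as.integer(lags[1]), lag_2 = as.integer(lags[2]),
             lag_3 = as.integer(lags[3]),
             bin_size = bin, count = count, p_value = p, p_adj = p,
             stringsAsFactors = FALSE)
}

unit_table <- function(ids, areas) {
  data.frame(unit_id = ids, area = areas, n_spikes = 1000L,
             stringsAsFactors = FALSE)
}

# Small random session for property tests.
random_session <- function(seed, n_units = 4, duration = 50, rate = 4) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    spikes <- lapply(seq_len(n_units), function(i) {
      sort(runif(rpois(1, rate * duration), 0, duration))
    })
    names(spikes) <- sprintf("u%d", seq_len(n_units))
    spike_session(spikes, rep(c("ZI", "MS"), length.out = n_units),
                  duration = duration)
  })
}
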