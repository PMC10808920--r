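#' Normalized assembly probabilities
#'
#' The raw number of detected assemblies scales with how many units were
#' recorded, so counts are normalized by the number of configurations of
#' that type available on the recorded unit sets:
#' \describe{
#'   \item{`p_pairs_ext`}{cross-area pairs: `n / (nA * nB)`.}
#'   \item{`p_pairs_int`}{within-area pairs: `n / choose(nA, 2)`.}
#'   \item{`p_looplike`}{loop-like triplets of either structure:
#'     `2n / (nA*nB*(nA-1) + nB*nA*(nB-1))`.}
#'   \item{`p_looplike_structured`}{loop-like triplets with fixed chain
#'     A->B->A: `2n / (nA*nB*(nA-1))`.}
#' }
#' Denominators equal the number of distinct unit configurations of the
#' corresponding kind (an unordered pair `{a1, a2}` with a middle unit `b`
#' yields `nA*(nA-1)/2 * nB` loop-like A->B->A triples, hence the factor 2).
#'
#' @param n_pairs,n_loops,n_aba observed assembly counts.
#' @param n_a,n_b unit counts of the two areas (post spike filter).
#' @return a probability.
#' @export
p_pairs_ext <- function(n_pairs, n_a, n_b) {
  if (any(n_a < 1) || any(n_b < 1)) stop("unit counts must be >= 1",
                                         call. = FALSE)
  n_pairs / (n_a * n_b)
}

#' @rdname p_pairs_ext
#' @export
p_pairs_int <- function(n_pairs, n_a) {
  if (any(n_a < 2)) stop("need at least 2 units for internal pairs",
                         call. = FALSE)
  n_pairs / choose(n_a, 2)
}

#' @rdname p_pairs_ext
#' @export
p_looplike <- function(n_loops, n_a, n_b) {
  denom <- n_a * n_b * (n_a - 1) + n_b * n_a * (n_b - 1)
  if (any(denom <= 0)) {
    stop("no loop-like triple can be formed on these unit counts",
         call. = FALSE)
  }
  2 * n_loops / denom
}

#' @rdname p_pairs_ext
#' @export
p_looplike_structured <- function(n_aba, n_a, n_b) {
  if (any(n_a < 2)) stop("A->B->A structure needs at least 2 units in A",
                         call. = FALSE)
  2 * n_aba / (n_a * n_b * (n_a - 1))
}

#' Internal-versus-external coupling index
#'
#' `p_ext / (p_ext + p_int)`, in `[0, 1]`: exactly 0.5 when the probability
#' of forming a cross-area pair equals the probability of forming a
#' within-focal pair, above 0.5 when external coupling is the more likely.
#'
#' @param p_ext,p_int external and internal pair-assembly probabilities.
#' @return the index, or `NaN` (with a warning) when both inputs are zero.
#' @export
int_ext_index <- function(p_ext, p_int) {
  if (any(p_ext < 0) || any(p_int < 0)) stop("probabilities must be >= 0",
                                             call. = FALSE)
  out <- ifelse(p_ext + p_int > 0, p_ext / (p_ext + p_int), NaN)
  if (anyNA(out)) warning("int_ext_index undefined when both probabilities are zero")
  out
}

#' Combinatorial null probability of the A->B->A loop structure
#'
#' Given `nA` and `nB` recorded units, the share of all possible loop-like
#' triples that have the A->B->A structure is
#' `nA*nB*(nA-1) / (nA*nB*(nA-1) + nB*nA*(nB-1)) = (nA-1)/(nA+nB-2)`.
#'
#' @param n_a,n_b unit counts of the two areas.
#' @return null probability in `[0, 1]`.
#' @export
expected_loop_prob <- function(n_a, n_b) {
  if (any(n_a + n_b < 3)) stop("need at least 3 units overall", call. = FALSE)
  (n_a - 1) / (n_a + n_b - 2)
}

#' Exact binomial asymmetry tests
#'
#' `binom_direction_test` asks whether assemblies flow preferentially in one
#' direction between two areas: under the null both directions are
#' equiprobable (p0 = 0.5). `binom_loop_test` asks whether one loop
#' structure (A->B->A vs B->A->B) is over-represented relative to the
#' combinatorial null [expected_loop_prob()], which accounts for the unequal
#' numbers of possible triples of each type. Both are exact two-sided tests;
#' areas contributing fewer than `min_total` assemblies are flagged
#' `tested = FALSE` rather than tested, because the binomial test is
#' uninformative on tiny counts.
#'
#' @param n_from,n_to directional assembly counts (from/to the focal area).
#' @param n_aba count of A->B->A loop-like triplets.
#' @param n_total total loop-like triplets for the area pair.
#' @param n_a,n_b unit counts determining the combinatorial null.
#' @param min_total inclusion threshold on the total count.
#' @param method `"minlik"` (sum of outcome probabilities no larger than the
#'   observed outcome's, as in [stats::binom.test()]) or `"double"`
#'   (doubled smaller tail, capped at 1).
#' @return a `binom_asym_test` list: `p_value`, `estimate` (observed
#'   fraction), `null_prob`, `n`, `tested`.
#' @export
binom_direction_test <- function(n_from, n_to, min_total = 10,
                                 method = c("minlik", "double")) {
  binom_asym_test(n_from, n_from + n_to, p0 = 0.5, min_total = min_total,
                  method = match.arg(method))
}

#' @rdname binom_direction_test
#' @export
binom_loop_test <- function(n_aba, n_total, n_a, n_b, min_total = 10,
                            method = c("minlik", "double")) {
  if (n_aba > n_total) stop("n_aba cannot exceed n_total", call. = FALSE)
  binom_asym_test(n_aba, n_total, p0 = expected_loop_prob(n_a, n_b),
                  min_total = min_total, method = match.arg(method))
}

binom_asym_test <- function(x, n, p0, min_total, method) {
  if (x < 0 || n < 0 || x > n) stop("invalid counts", call. = FALSE)
  if (n < min_total) {
    out <- list(p_value = NA_real_, estimate = if (n > 0) x / n else NA_real_,
                null_prob = p0, n = n, tested = FALSE)
  } else {
    p <- if (method == "minlik") {
      stats::binom.test(x, n, p = p0, alternative = "two.sided")$p.value
    } else {
      lower <- stats::pbinom(x, n, p0)
      upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
      min(1, 2 * min(lower, upper))
    }
    out <- list(p_value = min(1, p), estimate = x / n, null_prob = p0,
                n = n, tested = TRUE)
  }
  class(out) <- "binom_asym_test"
  out
}

#' @export
print.binom_asym_test <- function(x, ...) {
  if (!x$tested) {
    cat(sprintf("not tested (n = %d below inclusion threshold)\n", x$n))
  } else {
    cat(sprintf("exact binomial: %.3f observed vs %.3f expected (n = %d), p = %.4g\n",
                x$estimate, x$null_prob, x$n, x$p_value))
  }
  invisible(x)
}

#' Per-area-pair assembly statistics
#'
#' Aggregates a classified `motif_set` into one row per (focal, partner)
#' area pair: unit counts, directional/synchronous pair counts, loop-like
#' triplet counts by structure, and the combinatorial denominators needed to
#' normalize and pool them. Focal-internal pair counts are carried on every
#' row (columns `n_pairs_int_focal`, `denom_int`).
#'
#' @param motifs a `motif_set` from [classify_motifs()].
#' @return data.frame of class `area_pair_stats`, one row per partner area.
#' @export
area_pair_stats <- function(motifs) {
  units <- attr(motifs, "units")
  focal <- attr(motifs, "focal_area")
  n_focal <- sum(units$area == focal)
  partners <- setdiff(sort(unique(units$area)), focal)
  n_int <- sum(motifs$order == 2L & motifs$klass == "pair_internal_focal")
  rows <- lapply(partners, function(b) {
    n_b <- sum(units$area == b)
    sel <- !is.na(motifs$partner_area) & motifs$partner_area == b
    m <- motifs[sel, , drop = FALSE]
    n_from <- sum(m$klass == "pair_from_focal")
    n_to <- sum(m$klass == "pair_to_focal")
    n_sync <- sum(m$klass == "pair_synchronous")
    n_aba <- sum(m$klass == "triplet_loop_focal")
    n_bab <- sum(m$klass == "triplet_loop_external")
    data.frame(
      session_id = attr(motifs, "session_id"),
      area_a = focal, area_b = b, n_a = n_focal, n_b = n_b,
      n_pairs_from = n_from, n_pairs_to = n_to, n_pairs_sync = n_sync,
      n_pairs_ext = n_from + n_to + n_sync,
      n_pairs_int_focal = n_int,
      n_loops_aba = n_aba, n_loops_bab = n_bab,
      n_loops_total = n_aba + n_bab,
      denom_ext = n_focal * n_b,
      denom_int = choose(n_focal, 2),
      denom_loop = n_focal * n_b * (n_focal - 1) + n_b * n_focal * (n_b - 1),
      denom_loop_aba = n_focal * n_b * (n_focal - 1),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("area_pair_stats", "data.frame")
  out
}

#' Pool per-session area-pair statistics
#'
#' When an area pair was recorded in several sessions, pooled probabilities
#' divide the summed assembly counts by the summed combinatorial
#' denominators — not the mean of per-session ratios, which would weight a
#' small session as much as a large one.
#'
#' @param per_session list of `area_pair_stats` (one per session) or a
#'   single row-bound `area_pair_stats` covering several sessions.
#' @return pooled `area_pair_stats` with one row per (area_a, area_b);
#'   `session_id` concatenates the pooled sessions and `n_a`, `n_b` sum the
#'   per-session unit counts.
#' @export
pool_sessions <- function(per_session) {
  if (inherits(per_session, "data.frame")) per_session <- list(per_session)
  if (!length(per_session)) stop("nothing to pool", call. = FALSE)
  tab <- do.call(rbind, lapply(per_session, as.data.frame))
  count_cols <- c("n_a", "n_b", "n_pairs_from", "n_pairs_to", "n_pairs_sync",
                  "n_pairs_ext", "n_pairs_int_focal", "n_loops_aba",
                  "n_loops_bab", "n_loops_total", "denom_ext", "denom_int",
                  "denom_loop", "denom_loop_aba")
  if (length(unique(tab$area_a)) > 1L) {
    stop("mismatched focal areas across sessions", call. = FALSE)
  }
  split_key <- paste(tab$area_a, tab$area_b, sep = "->")
  pooled <- lapply(split(tab, split_key), function(g) {
    out <- g[1L, , drop = FALSE]
    out$session_id <- paste(sort(unique(g$session_id)), collapse = "+")
    out[count_cols] <- lapply(g[count_cols], sum)
    out
  })
  out <- do.call(rbind, pooled)
  out <- out[order(out$area_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("area_pair_stats", "data.frame")
  out
}

#' Assembly probabilities and asymmetry tests per area pair
#'
#' Computes, for each (focal, partner) row of an `area_pair_stats` table,
#' the normalized probabilities, the Int-Ext index, and the exact binomial
#' asymmetry tests for pair direction and loop structure.
#'
#' @param stats an `area_pair_stats` table (possibly pooled).
#' @param min_total inclusion threshold for the binomial tests.
#' @return the table augmented with `p_ext`, `p_int`, `p_sync`, `p_from`,
#'   `p_to`, `p_loop`, `p_loop_aba`, `int_ext`, `expected_aba`,
#'   `dir_p_value`, `dir_tested`, `loop_p_value`, `loop_tested`.
#' @export
area_pair_summary <- function(stats, min_total = 10) {
  s <- as.data.frame(stats)
  s$p_ext <- s$n_pairs_ext / s$denom_ext
  s$p_from <- s$n_pairs_from / s$denom_ext
  s$p_to <- s$n_pairs_to / s$denom_ext
  s$p_sync <- s$n_pairs_sync / s$denom_ext
  s$p_int <- ifelse(s$denom_int > 0, s$n_pairs_int_focal / s$denom_int, NA)
  s$p_loop <- ifelse(s$denom_loop > 0, 2 * s$n_loops_total / s$denom_loop, NA)
  s$p_loop_aba <- ifelse(s$denom_loop_aba > 0,
                         2 * s$n_loops_aba / s$denom_loop_aba, NA)
  s$int_ext <- ifelse(s$p_ext + s$p_int > 0,
                      s$p_ext / (s$p_ext + s$p_int), NaN)
  s$expected_aba <- (s$n_a - 1) / (s$n_a + s$n_b - 2)
  dir_tests <- lapply(seq_len(nrow(s)), function(i) {
    binom_direction_test(s$n_pairs_from[i], s$n_pairs_to[i],
                         min_total = min_total)
  })
  loop_tests <- lapply(seq_len(nrow(s)), function(i) {
    binom_loop_test(s$n_loops_aba[i], s$n_loops_total[i], s$n_a[i], s$n_b[i],
                    min_total = min_total)
  })
  s$dir_p_value <- vapply(dir_tests, function(t) t$p_value, numeric(1))
  s$dir_tested <- vapply(dir_tests, function(t) t$tested, logical(1))
  s$loop_p_value <- vapply(loop_tests, function(t) t$p_value, numeric(1))
  s$loop_tested <- vapply(loop_tests, function(t) t$tested, logical(1))
  class(s) <- c("area_pair_summary", "data.frame")
  s
}

#' Rank partner areas by assembly probability
#'
#' @param summary_tab an [area_pair_summary()] table.
#' @param metric `"pairs"` (external pair probability), `"loops"`
#'   (loop-like probability) or `"sync"` (synchronous pair probability).
#' @return the table sorted by the metric, descending; ties broken
#'   alphabetically by partner area.
#' @export
rank_areas <- function(summary_tab, metric = c("pairs", "loops", "sync")) {
  metric <- match.arg(metric)
  if (!nrow(summary_tab)) stop("empty statistics table", call. = FALSE)
  col <- switch(metric, pairs = "p_ext", loops = "p_loop", sync = "p_sync")
  v <- summary_tab[[col]]
  v[is.na(v)] <- -Inf
  out <- summary_tab[order(-v, summary_tab$area_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
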