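#' Temporal-resolution grid for assembly detection
#'
#' The default grid spans characteristic bin widths of 10-100 ms with
#' matching maximum lags chosen so that the largest detectable delay
#' (`bin_size * max_lag`) stays below 200 ms at every resolution.
#'
#' @param bin_sizes bin widths in seconds.
#' @param max_lags maximum tested lag (in bins) at each resolution; must be
#'   parallel to `bin_sizes`.
#' @return a `bin_grid` list with elements `bin_sizes` and `max_lags`.
#' @export
bin_grid <- function(bin_sizes = c(0.01, 0.015, 0.02, 0.025, 0.03,
                                   0.04, 0.05, 0.06, 0.08, 0.1),
                     max_lags = c(19L, 12L, 9L, 7L, 6L, 4L, 3L, 2L, 2L, 1L)) {
  if (length(bin_sizes) != length(max_lags)) {
    stop("bin_sizes and max_lags must have equal length", call. = FALSE)
  }
  if (any(bin_sizes <= 0) || any(max_lags < 0)) {
    stop("bin_sizes must be positive and max_lags nonnegative", call. = FALSE)
  }
  structure(list(bin_sizes = as.numeric(bin_sizes),
                 max_lags = as.integer(max_lags)),
            class = "bin_grid")
}

#' Detection settings
#'
#' @param grid a [bin_grid()].
#' @param alpha significance level for the corrected pairwise tests.
#' @param lag_correction multiply each pairwise p-value by the number of
#'   tested lags (Bonferroni over lags).
#' @param pair_correction family for the Holm step: `"holm-global"` adjusts
#'   across every (pair, resolution) test of a run, controlling the run-wise
#'   family-wise error rate; `"holm-resolution"` adjusts within each
#'   resolution separately; `"none"` disables it.
#' @param n_chunks number of contiguous blocks used to estimate expected
#'   coincidence counts chunk-wise, which absorbs slow firing-rate
#'   non-stationarities.
#' @param binarize analyze occupied bins (0/1) rather than raw counts.
#' @param max_order stop agglomeration at this assembly order (2 or 3).
#' @return a `detection_config` list.
#' @export
detection_config <- function(grid = bin_grid(), alpha = 0.05,
                             lag_correction = TRUE,
                             pair_correction = c("holm-global",
                                                 "holm-resolution", "none"),
                             n_chunks = 5L, binarize = TRUE,
                             max_order = 3L) {
  pair_correction <- match.arg(pair_correction)
  stopifnot(inherits(grid, "bin_grid"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (n_chunks < 1) stop("n_chunks must be >= 1", call. = FALSE)
  if (!max_order %in% c(2L, 3L)) stop("max_order must be 2 or 3", call. = FALSE)
  structure(list(grid = grid, alpha = alpha,
                 lag_correction = isTRUE(lag_correction),
                 pair_correction = pair_correction,
                 n_chunks = as.integer(n_chunks),
                 binarize = isTRUE(binarize),
                 max_order = as.integer(max_order)),
            class = "detection_config")
}

#' Lagged coincidence profile of two binned trains
#'
#' For each lag `l` in `-max_lag:max_lag` counts the coincidences
#' `c(l) = sum_t min(xA(t), xB(t+l))` over the bins where both series are
#' defined; with `binarize = TRUE` the counts are first thresholded at one
#' spike per bin, so `c(l)` counts bins in which a spike of A is followed,
#' `l` bins later, by a spike of B.
#'
#' @param x_a,x_b equal-length vectors of per-bin spike counts.
#' @param max_lag maximum lag in bins.
#' @param binarize threshold counts at 1 before counting coincidences.
#' @return named integer vector of coincidence counts, names `-L ... L`.
#' @export
coincidence_profile <- function(x_a, x_b, max_lag, binarize = TRUE) {
  if (length(x_a) != length(x_b)) {
    stop("x_a and x_b must have equal length", call. = FALSE)
  }
  if (max_lag < 0) stop("max_lag must be >= 0", call. = FALSE)
  lags <- seq.int(-max_lag, max_lag)
  if (binarize) {
    prof <- sparse_profile(which(x_a > 0), which(x_b > 0), as.integer(max_lag))
  } else {
    n <- length(x_a)
    prof <- vapply(lags, function(l) {
      ta <- seq.int(max(1L, 1L - l), min(n, n - l))
      if (!length(ta)) return(0L)
      as.integer(sum(pmin(x_a[ta], x_b[ta + l])))
    }, integer(1))
  }
  names(prof) <- lags
  prof
}

# Coincidence profile from sorted occupied-bin indices. prof[l + L + 1] is
# the number of index pairs (a in A, b in B) with b - a = l.
sparse_profile <- function(occ_a, occ_b, max_lag) {
  L <- max_lag
  if (!length(occ_a) || !length(occ_b)) return(integer(2L * L + 1L))
  lo <- findInterval(occ_a - L - 0.5, occ_b)
  hi <- findInterval(occ_a + L + 0.5, occ_b)
  cnt <- hi - lo
  keep <- cnt > 0L
  if (!any(keep)) return(integer(2L * L + 1L))
  pos <- sequence(cnt[keep], from = lo[keep] + 1L)
  diffs <- occ_b[pos] - rep.int(occ_a[keep], cnt[keep])
  tabulate(diffs + L + 1L, nbins = 2L * L + 1L)
}

# Lag selection: maximal count, ties resolved to smallest |l|, then the
# negative lag before the positive one.
best_lag <- function(prof, max_lag) {
  lags <- seq.int(-max_lag, max_lag)
  ord <- order(abs(lags), lags)
  best <- ord[which.max(prof[ord])]
  list(lag = lags[best], count = as.integer(prof[best]))
}

# Chunk boundaries (bin indices) for the non-stationarity correction.
chunk_edges <- function(n_bins, n_chunks) {
  k <- min(n_chunks, n_bins)
  round(seq(0L, n_bins, length.out = k + 1L))
}

# Per-chunk occupied-bin counts of one unit.
chunk_counts <- function(occ, edges) {
  if (!length(occ)) return(integer(length(edges) - 1L))
  tabulate(findInterval(occ - 0.5, edges), nbins = length(edges) - 1L)
}

# Expected total coincidences under independence, summed chunk-wise:
# mu = sum_k T_k * p_hat_Ak * p_hat_Bk = sum_k cA_k * cB_k / T_k.
chunked_mu <- function(counts_a, counts_b, edges) {
  t_k <- diff(edges)
  ok <- t_k > 0
  sum(counts_a[ok] * counts_b[ok] / t_k[ok])
}

# Upper-tail Poisson p for >= count coincidences, Bonferroni over lags.
lagged_p <- function(count, mu, max_lag, lag_correction) {
  p <- stats::ppois(count - 1L, mu, lower.tail = FALSE)
  if (lag_correction) p <- p * (2L * max_lag + 1L)
  min(1, p)
}

#' Pairwise lagged-coordination test
#'
#' Selects the lag maximizing the coincidence profile of two binned trains
#' and tests the maximal count against a chunk-wise Poisson null: the bins
#' are split into `n_chunks` contiguous blocks, the expected coincidences in
#' block k are `T_k * pA_k * pB_k` from the empirical occupancy
#' probabilities, and the total null count is Poisson with the summed mean.
#' The upper-tail p-value is Bonferroni-corrected for the number of lags
#' examined.
#'
#' @param x_a,x_b equal-length per-bin spike-count vectors.
#' @param max_lag maximum lag in bins.
#' @param config a [detection_config()] (only `n_chunks`, `binarize` and
#'   `lag_correction` are used here).
#' @return list with `lag` (best lag, sign means `x_b` trails `x_a`),
#'   `count`, `expected` (null mean), and `p_value`.
#' @export
pair_test <- function(x_a, x_b, max_lag, config = detection_config()) {
  prof <- coincidence_profile(x_a, x_b, max_lag, binarize = config$binarize)
  bl <- best_lag(prof, max_lag)
  n <- length(x_a)
  edges <- chunk_edges(n, config$n_chunks)
  if (config$binarize) {
    ca <- chunk_counts(which(x_a > 0), edges)
    cb <- chunk_counts(which(x_b > 0), edges)
    mu <- chunked_mu(ca, cb, edges)
  } else {
    t_k <- diff(edges)
    idx <- findInterval(seq_len(n) - 0.5, edges)
    sa <- vapply(seq_along(t_k), function(k) sum(x_a[idx == k]), numeric(1))
    sb <- vapply(seq_along(t_k), function(k) sum(x_b[idx == k]), numeric(1))
    mu <- chunked_mu(sa, sb, edges)
  }
  if (bl$count == 0L) {
    return(list(lag = 0L, count = 0L, expected = mu, p_value = 1))
  }
  list(lag = bl$lag, count = bl$count, expected = mu,
       p_value = lagged_p(bl$count, mu, max_lag, config$lag_correction))
}

#' Detect pair and triplet cell assemblies across temporal resolutions
#'
#' The central estimator of the package. For every resolution of the grid
#' the parallel spike trains are binned and binarized, every unit pair is
#' tested for lagged coordination ([pair_test()]), and the pairwise p-values
#' are Holm-adjusted (by default across the whole run, which controls the
#' probability of reporting any spurious assembly on independent data).
#' Each significant pair is then agglomerated: its aligned joint-activation
#' vector is treated as a new unit and tested against every remaining unit;
#' significant extensions become order-3 assemblies whose lag structure
#' composes the pair's lag with the extension lag. Assemblies with identical
#' unit sets found at several resolutions are collapsed to the one with the
#' smallest p-value, so each assembly is reported at its optimal temporal
#' resolution.
#'
#' @param session a [spike_session()] (apply [filter_min_spikes()] first).
#' @param config a [detection_config()].
#' @return an object of class `assembly_set`: list with `assemblies` (a
#'   data.frame with one row per assembly: `order`, `unit_1..3`,
#'   `area_1..3`, `lag_1..3` in bins relative to the first unit, `bin_size`,
#'   `count`, `p_value` (lag-corrected), `p_adj` (Holm)), plus `session_id`,
#'   `duration`, `focal_area`, `units`, `config` and `n_pair_tests`.
#' @examples
#' sc <- make_scenario("pairs_easy", seed = 42)
#' fit <- detect_assemblies(sc$session)
#' fit
#' @export
detect_assemblies <- function(session, config = detection_config()) {
  stopifnot(inherits(session, "spike_session"))
  n_units <- nrow(session$units)
  if (n_units < 2L) stop("need at least 2 units to detect assemblies",
                         call. = FALSE)
  ids <- session$units$unit_id
  grid <- config$grid
  n_res <- length(grid$bin_sizes)
  pair_idx <- utils::combn(n_units, 2L)

  pair_rows <- vector("list", n_res)
  res_cache <- vector("list", n_res)
  for (r in seq_len(n_res)) {
    b <- grid$bin_sizes[r]
    L <- grid$max_lags[r]
    t_bins <- max(1L, as.integer(ceiling(session$duration / b - 1e-9)))
    occ <- lapply(session$spikes, occupied_bins,
                  bin_size = b, n_bins = t_bins)
    edges <- chunk_edges(t_bins, config$n_chunks)
    ccnt <- lapply(occ, chunk_counts, edges = edges)
    res_cache[[r]] <- list(occ = occ, edges = edges, ccnt = ccnt,
                           t_bins = t_bins, bin = b, L = L)
    m <- ncol(pair_idx)
    lag <- integer(m); cnt <- integer(m); pv <- numeric(m)
    for (k in seq_len(m)) {
      i <- pair_idx[1L, k]; j <- pair_idx[2L, k]
      prof <- sparse_profile(occ[[i]], occ[[j]], L)
      bl <- best_lag(prof, L)
      lag[k] <- bl$lag; cnt[k] <- bl$count
      pv[k] <- if (bl$count == 0L) 1 else {
        lagged_p(bl$count, chunked_mu(ccnt[[i]], ccnt[[j]], edges),
                 L, config$lag_correction)
      }
    }
    pair_rows[[r]] <- data.frame(res = r, i = pair_idx[1L, ],
                                 j = pair_idx[2L, ], lag = lag,
                                 count = cnt, p_value = pv)
  }
  pairs <- do.call(rbind, pair_rows)
  pairs$p_adj <- switch(
    config$pair_correction,
    "holm-global" = stats::p.adjust(pairs$p_value, method = "holm"),
    "holm-resolution" = stats::ave(pairs$p_value, pairs$res,
                                   FUN = function(p) stats::p.adjust(p, "holm")),
    "none" = pairs$p_value
  )
  sig_pairs <- pairs[pairs$p_adj <= config$alpha, , drop = FALSE]

  # Agglomeration: aligned pair activation vector vs every third unit.
  trip <- NULL
  if (config$max_order >= 3L && nrow(sig_pairs)) {
    cand <- vector("list", nrow(sig_pairs) * max(0L, n_units - 2L))
    ci <- 0L
    for (k in seq_len(nrow(sig_pairs))) {
      row <- sig_pairs[k, ]
      rc <- res_cache[[row$res]]
      z <- rc$occ[[row$i]]
      z <- z[z %in% (rc$occ[[row$j]] - row$lag)]
      if (!length(z)) next
      zc <- chunk_counts(z, rc$edges)
      for (u in seq_len(n_units)) {
        if (u == row$i || u == row$j) next
        prof <- sparse_profile(z, rc$occ[[u]], rc$L)
        bl <- best_lag(prof, rc$L)
        if (bl$count == 0L) next
        p <- lagged_p(bl$count, chunked_mu(zc, rc$ccnt[[u]], rc$edges),
                      rc$L, config$lag_correction)
        ci <- ci + 1L
        cand[[ci]] <- data.frame(res = row$res, i = row$i, j = row$j,
                                 u = u, lag_pair = row$lag,
                                 lag_ext = bl$lag, count = bl$count,
                                 p_value = p)
      }
    }
    if (ci > 0L) {
      cand <- do.call(rbind, cand[seq_len(ci)])
      cand$p_adj <- switch(
        config$pair_correction,
        "holm-global" = stats::p.adjust(cand$p_value, method = "holm"),
        "holm-resolution" = stats::ave(cand$p_value, cand$res,
                                       FUN = function(p) stats::p.adjust(p, "holm")),
        "none" = cand$p_value
      )
      trip <- cand[cand$p_adj <= config$alpha, , drop = FALSE]
    }
  }

  asm <- build_assembly_frame(sig_pairs, trip, session, grid)
  structure(
    list(assemblies = asm,
         session_id = session$session_id,
         duration = session$duration,
         focal_area = session$focal_area,
         units = session$units,
         config = config,
         n_pair_tests = nrow(pairs)),
    class = "assembly_set"
  )
}

# Canonicalize records and collapse duplicate unit sets to minimal p.
build_assembly_frame <- function(sig_pairs, trip, session, grid) {
  ids <- session$units$unit_id
  areas <- session$units$area
  rows <- list()
  if (!is.null(sig_pairs) && nrow(sig_pairs)) {
    for (k in seq_len(nrow(sig_pairs))) {
      r <- sig_pairs[k, ]
      u <- c(r$i, r$j); l <- c(0L, r$lag)
      if (r$lag < 0L) { u <- rev(u); l <- c(0L, -r$lag) }
      if (r$lag == 0L && ids[u[1]] > ids[u[2]]) u <- rev(u)
      rows[[length(rows) + 1L]] <- data.frame(
        order = 2L, unit_1 = ids[u[1]], unit_2 = ids[u[2]], unit_3 = NA,
        area_1 = areas[u[1]], area_2 = areas[u[2]], area_3 = NA,
        lag_1 = 0L, lag_2 = l[2], lag_3 = NA_integer_,
        bin_size = grid$bin_sizes[r$res], count = r$count,
        p_value = r$p_value, p_adj = r$p_adj,
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(trip) && nrow(trip)) {
    for (k in seq_len(nrow(trip))) {
      r <- trip[k, ]
      u <- c(r$i, r$j, r$u)
      l <- c(0L, r$lag_pair, r$lag_ext)
      l <- l - min(l)
      ord <- order(l, ids[u])
      u <- u[ord]; l <- l[ord]
      rows[[length(rows) + 1L]] <- data.frame(
        order = 3L, unit_1 = ids[u[1]], unit_2 = ids[u[2]], unit_3 = ids[u[3]],
        area_1 = areas[u[1]], area_2 = areas[u[2]], area_3 = areas[u[3]],
        lag_1 = l[1], lag_2 = l[2], lag_3 = l[3],
        bin_size = grid$bin_sizes[r$res], count = r$count,
        p_value = r$p_value, p_adj = r$p_adj,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(order = integer(0), unit_1 = character(0),
                      unit_2 = character(0), unit_3 = character(0),
                      area_1 = character(0), area_2 = character(0),
                      area_3 = character(0), lag_1 = integer(0),
                      lag_2 = integer(0), lag_3 = integer(0),
                      bin_size = numeric(0), count = integer(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE))
  }
  asm <- do.call(rbind, rows)
  key <- apply(asm[c("unit_1", "unit_2", "unit_3")], 1L, function(u) {
    paste(sort(stats::na.omit(u)), collapse = "|")
  })
  ord <- order(key, asm$p_value, asm$bin_size)
  asm <- asm[ord, , drop = FALSE]
  key <- key[ord]
  asm <- asm[!duplicated(key), , drop = FALSE]
  asm <- asm[order(asm$order, asm$p_value, asm$unit_1, asm$unit_2), ,
             drop = FALSE]
  rownames(asm) <- NULL
  asm
}

#' @export
print.assembly_set <- function(x, ...) {
  n2 <- sum(x$assemblies$order == 2L)
  n3 <- sum(x$assemblies$order == 3L)
  cat(sprintf(
    "<assembly_set> session %s: %d pair and %d triplet assemblies (%d units, %d pairwise tests)\n",
    x$session_id, n2, n3, nrow(x$units), x$n_pair_tests))
  if (nrow(x$assemblies)) {
    show <- utils::head(x$assemblies[c("order", "unit_1", "unit_2", "unit_3",
                                       "lag_2", "lag_3", "bin_size",
                                       "count", "p_value")], 10L)
    print(show, row.names = FALSE)
    if (nrow(x$assemblies) > 10L) {
      cat(sprintf("  ... %d more\n", nrow(x$assemblies) - 10L))
    }
  }
  invisible(x)
}

#' @export
summary.assembly_set <- function(object, ...) {
  asm <- object$assemblies
  out <- list(
    session_id = object$session_id,
    n_pairs = sum(asm$order == 2L),
    n_triplets = sum(asm$order == 3L),
    n_sync_pairs = sum(asm$order == 2L & asm$lag_2 == 0L),
    bin_size_table = table(asm$bin_size),
    n_units = nrow(object$units),
    alpha = object$config$alpha
  )
  class(out) <- "summary.assembly_set"
  out
}

#' @export
print.summary.assembly_set <- function(x, ...) {
  cat(sprintf("Assemblies in session %s (alpha = %g):\n", x$session_id,
              x$alpha))
  cat(sprintf("  pairs: %d (%d synchronous), triplets: %d, units: %d\n",
              x$n_pairs, x$n_sync_pairs, x$n_triplets, x$n_units))
  if (length(x$bin_size_table)) {
    cat("  optimal bin sizes (s):\n")
    print(x$bin_size_table)
  }
  invisible(x)
}

#' @export
plot.assembly_set <- function(x, ...) {
  asm <- x$assemblies
  if (!nrow(asm)) {
    graphics::plot.new()
    graphics::title("no assemblies detected")
    return(invisible(x))
  }
  delays <- c(asm$lag_2, asm$lag_3[!is.na(asm$lag_3)]) *
    c(asm$bin_size, asm$bin_size[!is.na(asm$lag_3)]) * 1000
  graphics::hist(delays, breaks = seq(-5, max(delays) + 10, by = 10),
                 main = "Assembly activation delays",
                 xlab = "delay from first unit (ms)", col = "grey70", ...)
  invisible(x)
}
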