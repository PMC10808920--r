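#' Specify a planted assembly
#'
#' Describes one coordinated activation pattern to superimpose on background
#' activity: an ordered set of 2 or 3 units, the integer lag of each unit
#' (in bins) relative to the first, the bin width, the number of planted
#' activations, the probability that each unit participates in a given
#' activation, and a within-bin uniform time jitter.
#'
#' @param unit_ids ordered character vector of 2 or 3 unit ids (order of
#'   activation; the same unit may not appear twice).
#' @param lags_bins integer lags relative to the first unit; `lags_bins[1]`
#'   must be 0, the rest nonnegative.
#' @param bin_size seconds; the characteristic temporal resolution of the
#'   planted pattern (delay of unit i = `lags_bins[i] * bin_size`).
#' @param n_activations number of coordinated events to plant.
#' @param participation_prob probability each unit fires in a given event.
#' @param jitter spikes are placed at `t_event + lag*bin_size + U(0, jitter)`;
#'   defaults to `bin_size / 2` so planted lags survive binning misalignment
#'   in expectation.
#' @return a `planted_assembly` list.
#' @export
planted_assembly <- function(unit_ids, lags_bins, bin_size,
                             n_activations = 300, participation_prob = 0.9,
                             jitter = bin_size / 2) {
  if (!length(unit_ids) %in% c(2L, 3L)) {
    stop("a planted assembly has 2 or 3 units", call. = FALSE)
  }
  if (anyDuplicated(unit_ids)) stop("unit_ids must be distinct", call. = FALSE)
  if (length(lags_bins) != length(unit_ids) || lags_bins[1] != 0 ||
      any(lags_bins < 0) || any(lags_bins != round(lags_bins))) {
    stop("lags_bins must be integers with first element 0 and the rest >= 0",
         call. = FALSE)
  }
  stop_if_not_scalar_pos(bin_size, "bin_size")
  if (n_activations < 1) stop("n_activations must be >= 1", call. = FALSE)
  if (participation_prob <= 0 || participation_prob > 1) {
    stop("participation_prob must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(unit_ids = as.character(unit_ids),
         lags_bins = as.integer(lags_bins),
         bin_size = bin_size,
         n_activations = as.integer(n_activations),
         participation_prob = participation_prob,
         jitter = jitter),
    class = "planted_assembly"
  )
}

#' Generate independent background spike trains
#'
#' Simulates homogeneous or rate-modulated Poisson units per area. With
#' `rate_modulation = "block"` the session is divided into five equal epochs
#' whose rate multipliers (common to all units, mean 1) emulate slow
#' state/task-block changes; `"sinusoid"` applies a full-session sinusoidal
#' rate envelope via thinning.
#'
#' @param n_units_per_area named integer vector, area label -> unit count.
#' @param rates per-unit rates in Hz: a single value, a vector (one per
#'   unit), or `"loguniform"` to draw rates log-uniformly from 0.5-10 Hz,
#'   the realistic heterogeneity of cortical/subcortical units.
#' @param duration session length in seconds.
#' @param seed integer seed; the same seed reproduces the session exactly.
#' @param rate_modulation `"none"`, `"block"` or `"sinusoid"`.
#' @param session_id,focal_area passed to [spike_session()].
#' @return a [spike_session()] whose unit ids are `<area>_<k>` (lower case).
#' @export
gen_background <- function(n_units_per_area, rates = "loguniform",
                           duration, seed,
                           rate_modulation = c("none", "block", "sinusoid"),
                           session_id = "sim", focal_area = "ZI") {
  rate_modulation <- match.arg(rate_modulation)
  stop_if_not_scalar_pos(duration, "duration")
  if (is.null(names(n_units_per_area)) || any(n_units_per_area < 1)) {
    stop("n_units_per_area must be a named vector of positive counts",
         call. = FALSE)
  }
  areas <- rep(names(n_units_per_area), n_units_per_area)
  n <- length(areas)
  ids <- unlist(lapply(names(n_units_per_area), function(a) {
    sprintf("%s_%d", tolower(a), seq_len(n_units_per_area[[a]]))
  }))
  with_seed(seed, {
    r <- if (identical(rates, "loguniform")) {
      exp(stats::runif(n, log(0.5), log(10)))
    } else {
      rep_len(as.numeric(rates), n)
    }
    if (any(r <= 0)) stop("rates must be positive", call. = FALSE)
    spikes <- lapply(r, function(rate) {
      gen_poisson_train(rate, duration, rate_modulation)
    })
    names(spikes) <- ids
    spike_session(spikes, areas, duration = duration,
                  session_id = session_id, focal_area = focal_area)
  })
}

# Five-epoch multiplier pattern for "block" modulation (mean 1).
block_multipliers <- function() c(0.5, 1.5, 0.5, 1.5, 1.0)

gen_poisson_train <- function(rate, duration, rate_modulation) {
  switch(
    rate_modulation,
    none = {
      n <- stats::rpois(1, rate * duration)
      sort(stats::runif(n, 0, duration))
    },
    block = {
      m <- block_multipliers()
      k <- length(m)
      edges <- seq(0, duration, length.out = k + 1)
      t <- unlist(lapply(seq_len(k), function(i) {
        n <- stats::rpois(1, rate * m[i] * (edges[i + 1] - edges[i]))
        stats::runif(n, edges[i], edges[i + 1])
      }))
      sort(t)
    },
    sinusoid = {
      # thinning from the envelope maximum rate*(1+depth)
      depth <- 0.5
      rmax <- rate * (1 + depth)
      n <- stats::rpois(1, rmax * duration)
      t <- stats::runif(n, 0, duration)
      keep <- stats::runif(n) <
        (1 + depth * sin(2 * pi * t / duration)) / (1 + depth)
      sort(t[keep])
    }
  )
}

#' Superimpose a planted assembly on a session
#'
#' Draws `n_activations` event times uniformly over the portion of the
#' session where the full lag pattern fits; at each event every unit
#' independently (with `participation_prob`) receives one extra spike at
#' `t_event + lag*bin_size + U(0, jitter)`. Background and planted spikes are
#' merged and re-sorted, so excess coincidences add to (never replace) the
#' background statistics.
#'
#' @param session a [spike_session()].
#' @param spec a [planted_assembly()].
#' @param seed integer seed.
#' @return the augmented [spike_session()]; attribute `"event_times"` holds
#'   the planted event times.
#' @export
plant_assembly <- function(session, spec, seed) {
  stopifnot(inherits(spec, "planted_assembly"))
  missing <- setdiff(spec$unit_ids, session$units$unit_id)
  if (length(missing)) {
    stop("unknown unit(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  span <- max(spec$lags_bins) * spec$bin_size + spec$jitter
  if (span >= session$duration) {
    stop("lag pattern does not fit in the session duration", call. = FALSE)
  }
  with_seed(seed, {
    events <- sort(stats::runif(spec$n_activations, 0,
                                session$duration - span))
    out <- session
    for (j in seq_along(spec$unit_ids)) {
      uid <- spec$unit_ids[j]
      fire <- stats::runif(spec$n_activations) <= spec$participation_prob
      t_new <- events[fire] + spec$lags_bins[j] * spec$bin_size +
        stats::runif(sum(fire), 0, spec$jitter)
      t_new <- t_new[t_new <= session$duration]
      out$spikes[[uid]] <- sort(c(out$spikes[[uid]], t_new))
    }
    out$units$n_spikes <- vapply(out$spikes, length, integer(1))
    attr(out, "event_times") <- events
    out
  })
}

#' Benchmark scenarios with known ground truth
#'
#' Deterministic, documented simulation scenarios used throughout the test
#' suite and the surrogate controls:
#' \describe{
#'   \item{`null_independent`}{20 independent Poisson units (10 ZI, 10 MS),
#'     1000 s, no planted structure — the false-positive control.}
#'   \item{`pairs_easy`}{20 units (10 ZI, 10 LGd), 900 s, twelve planted
#'     pairs (distinct unit sets) spanning from-focal, to-focal, synchronous
#'     and within-area patterns; includes the canonical 60 ms (lag 2, bin
#'     0.03 s) and 80 ms (lag 4, bin 0.02 s) delays.}
#'   \item{`loops_mixed`}{16 units (8 ZI, 8 MS), 900 s, two planted
#'     ZI->MS->ZI loops, one MS->ZI->MS loop and one non-loop triplet with a
#'     synchronous leading pair.}
#'   \item{`nonstationary`}{as `null_independent` but with five-epoch block
#'     rate modulation common to all units.}
#' }
#'
#' @param name scenario id.
#' @param seed integer seed; the same `(name, seed)` reproduces the session
#'   byte-for-byte.
#' @return a list with elements `session` (a [spike_session()]) and
#'   `ground_truth` (class `ground_truth`: `planted`, a list of
#'   [planted_assembly()] specs; `background_rates`; `seed`; `duration`).
#' @export
make_scenario <- function(name = c("null_independent", "pairs_easy",
                                   "loops_mixed", "nonstationary"),
                          seed = 1L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  planted <- list()
  if (name %in% c("null_independent", "nonstationary")) {
    sess <- gen_background(
      c(ZI = 10L, MS = 10L), duration = 1000, seed = seed,
      rate_modulation = if (name == "nonstationary") "block" else "none",
      session_id = paste0(name, "_", seed)
    )
  } else if (name == "pairs_easy") {
    sess <- gen_background(c(ZI = 10L, LGd = 10L), duration = 900,
                           seed = seed, session_id = paste0(name, "_", seed))
    pair_spec <- list(
      # from-focal: ZI leads; the 60 ms delay is lag 2 at bin 0.03 s
      list(u = c("zi_1", "lgd_1"), lags = c(0L, 2L), bin = 0.03),
      list(u = c("zi_2", "lgd_2"), lags = c(0L, 2L), bin = 0.03),
      list(u = c("zi_3", "lgd_3"), lags = c(0L, 1L), bin = 0.05),
      list(u = c("zi_4", "lgd_4"), lags = c(0L, 3L), bin = 0.02),
      # to-focal: partner leads; the 80 ms delay is lag 4 at bin 0.02 s
      list(u = c("lgd_5", "zi_5"), lags = c(0L, 4L), bin = 0.02),
      list(u = c("lgd_6", "zi_6"), lags = c(0L, 2L), bin = 0.04),
      list(u = c("lgd_7", "zi_7"), lags = c(0L, 1L), bin = 0.03),
      # synchronous (0 lag)
      list(u = c("zi_8", "lgd_8"), lags = c(0L, 0L), bin = 0.03),
      list(u = c("zi_9", "lgd_9"), lags = c(0L, 0L), bin = 0.02),
      # internal pairs (both areas represented)
      list(u = c("zi_10", "zi_1"), lags = c(0L, 1L), bin = 0.03),
      list(u = c("lgd_10", "lgd_4"), lags = c(0L, 2L), bin = 0.03),
      list(u = c("zi_5", "zi_2"), lags = c(0L, 0L), bin = 0.03)
    )
    for (i in seq_along(pair_spec)) {
      ps <- pair_spec[[i]]
      spec <- planted_assembly(ps$u, ps$lags, ps$bin,
                               n_activations = 350, participation_prob = 0.9)
      planted[[i]] <- spec
      sess <- plant_assembly(sess, spec, seed = seed + 1000L + i)
    }
  } else { # loops_mixed
    sess <- gen_background(c(ZI = 8L, MS = 8L), duration = 900,
                           seed = seed, session_id = paste0(name, "_", seed))
    trip_spec <- list(
      list(u = c("zi_1", "ms_1", "zi_2"), lags = c(0L, 1L, 2L), bin = 0.03),
      list(u = c("zi_3", "ms_2", "zi_4"), lags = c(0L, 2L, 3L), bin = 0.025),
      list(u = c("ms_3", "zi_5", "ms_4"), lags = c(0L, 1L, 2L), bin = 0.03),
      # non-loop: synchronous leading pair
      list(u = c("zi_6", "ms_5", "zi_7"), lags = c(0L, 0L, 3L), bin = 0.03)
    )
    for (i in seq_along(trip_spec)) {
      ts <- trip_spec[[i]]
      spec <- planted_assembly(ts$u, ts$lags, ts$bin,
                               n_activations = 350, participation_prob = 0.9)
      planted[[i]] <- spec
      sess <- plant_assembly(sess, spec, seed = seed + 2000L + i)
    }
  }
  truth <- structure(
    list(planted = planted,
         background_rates = sess$units$n_spikes / sess$duration,
         seed = seed, duration = sess$duration, scenario = name),
    class = "ground_truth"
  )
  list(session = sess, ground_truth = truth)
}

#' Serialize ground truth to JSON
#' @param truth a `ground_truth` object from [make_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(scenario = truth$scenario, seed = truth$seed,
         duration = truth$duration,
         planted = lapply(truth$planted, function(p) {
           list(unit_ids = p$unit_ids, lags_bins = p$lags_bins,
                bin_size = p$bin_size, n_activations = p$n_activations,
                participation_prob = p$participation_prob, jitter = p$jitter)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
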