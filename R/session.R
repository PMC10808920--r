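#' Construct a session of parallel spike trains
#'
#' A `spike_session` bundles the simultaneously recorded units of one
#' recording session: per-unit spike times (seconds), an area label per unit,
#' the recording duration, and the focal area against which motifs are later
#' classified (the zona incerta, `"ZI"`, by default).
#'
#' @param spikes named list; one numeric vector of spike times (seconds) per
#'   unit, names are unit ids. Times are sorted internally.
#' @param areas character vector of area labels, one per unit (recycled names
#'   must match `names(spikes)` if named).
#' @param duration recording span in seconds; `NULL` uses the latest spike.
#' @param session_id identifier for the session.
#' @param focal_area area label used as the reference ("focal") area.
#' @return An object of class `spike_session` with elements `session_id`,
#'   `duration`, `focal_area`, `units` (data.frame: `unit_id`, `area`,
#'   `n_spikes`) and `spikes` (named list of sorted spike-time vectors).
#' @examples
#' s <- spike_session(list(zi_1 = c(0.5, 1.2), ms_1 = c(0.9)),
#'                    areas = c("ZI", "MS"), duration = 10)
#' s
#' @export
spike_session <- function(spikes, areas, duration = NULL,
                          session_id = "s1", focal_area = "ZI") {
  if (!is.list(spikes) || length(spikes) == 0L) {
    stop("no units: `spikes` must be a non-empty named list", call. = FALSE)
  }
  ids <- names(spikes)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("every unit needs a non-empty name", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate unit_id in session", call. = FALSE)
  if (length(areas) != length(spikes)) {
    stop("`areas` must have one label per unit", call. = FALSE)
  }
  spikes <- lapply(spikes, function(t) {
    t <- as.numeric(t)
    if (anyNA(t)) stop("NA spike time", call. = FALSE)
    if (length(t) && min(t) < 0) stop("negative spike time", call. = FALSE)
    sort(t)
  })
  maxt <- suppressWarnings(max(0, unlist(spikes, use.names = FALSE)))
  if (is.null(duration)) duration <- maxt
  stop_if_not_scalar_pos(duration, "duration")
  if (maxt > duration) {
    stop("spike time exceeds session duration", call. = FALSE)
  }
  structure(
    list(
      session_id = as.character(session_id),
      duration = as.numeric(duration),
      focal_area = as.character(focal_area),
      units = data.frame(
        unit_id = ids,
        area = as.character(areas),
        n_spikes = vapply(spikes, length, integer(1)),
        row.names = NULL, stringsAsFactors = FALSE
      ),
      spikes = spikes
    ),
    class = "spike_session"
  )
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf(
    "<spike_session> %s: %d units, %d areas, %.1f s (focal: %s)\n",
    x$session_id, nrow(x$units), length(unique(x$units$area)),
    x$duration, x$focal_area
  ))
  tab <- table(x$units$area)
  cat("  units/area:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.spike_session <- function(object, ...) {
  rates <- object$units$n_spikes / object$duration
  out <- list(
    session_id = object$session_id,
    duration = object$duration,
    n_units = nrow(object$units),
    areas = sort(unique(object$units$area)),
    focal_area = object$focal_area,
    rate_range_hz = range(rates),
    total_spikes = sum(object$units$n_spikes)
  )
  class(out) <- "summary.spike_session"
  out
}

#' @export
print.summary.spike_session <- function(x, ...) {
  cat(sprintf("Session %s: %.1f s, %d units in %d areas (focal %s)\n",
              x$session_id, x$duration, x$n_units, length(x$areas),
              x$focal_area))
  cat(sprintf("  %d spikes total; unit rates %.2f-%.2f Hz\n",
              x$total_spikes, x$rate_range_hz[1], x$rate_range_hz[2]))
  invisible(x)
}

#' Areas recorded in a session
#' @param session a [spike_session()].
#' @return character vector of area labels.
#' @export
session_areas <- function(session) sort(unique(session$units$area))

#' Restrict a session to a subset of areas
#'
#' Mirrors running the detector on one area (internal assemblies) or on the
#' union of the focal area and a single partner (cross-regional assemblies).
#'
#' @param session a [spike_session()].
#' @param areas area labels to keep.
#' @return a [spike_session()] containing only units from `areas`.
#' @export
subset_areas <- function(session, areas) {
  keep <- session$units$area %in% areas
  if (!any(keep)) stop("no units in the requested areas", call. = FALSE)
  spike_session(session$spikes[keep], session$units$area[keep],
                duration = session$duration, session_id = session$session_id,
                focal_area = session$focal_area)
}

#' Read a spikes table
#'
#' Reads a TSV with header `unit_id  area  session_id  time_s`, one spike per
#' row, into a [spike_session()]. Times are sorted per unit; duplicate
#' timestamps within a unit are retained (multi-unit bins are legitimate).
#'
#' @param path path to the spikes TSV.
#' @param duration recording span in seconds, or `NULL` to use the latest
#'   spike time in the file.
#' @param units_path optional TSV `unit_id  area  session_id` declaring units
#'   (including silent ones that emit no spikes).
#' @param focal_area focal area label for downstream motif classification.
#' @return a [spike_session()].
#' @seealso [write_spikes()] for the inverse.
#' @export
read_spikes <- function(path, duration = NULL, units_path = NULL,
                        focal_area = "ZI") {
  expected <- c("unit_id", "area", "session_id", "time_s")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!identical(sort(names(tab)), sort(expected))) {
    stop(sprintf("spikes table must have exactly columns %s (got %s)",
                 paste(expected, collapse = ", "),
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  for (col in expected[1:3]) tab[[col]] <- as.character(tab[[col]])
  tab$time_s <- as.numeric(tab$time_s)
  if (anyNA(tab$time_s)) stop("malformed time_s values", call. = FALSE)
  if (nrow(tab) == 0L && is.null(units_path)) {
    stop("no units in spikes table", call. = FALSE)
  }
  if (nrow(tab) && any(tab$time_s < 0)) {
    stop("negative spike time in table", call. = FALSE)
  }
  sess_ids <- unique(tab$session_id)
  if (length(sess_ids) > 1L) {
    stop("spikes table mixes several session_id values; split first",
         call. = FALSE)
  }
  unit_area <- unique(tab[c("unit_id", "area")])
  if (anyDuplicated(unit_area$unit_id)) {
    stop("unit_id mapped to more than one area", call. = FALSE)
  }
  if (!is.null(units_path)) {
    utab <- utils::read.delim(units_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    need <- c("unit_id", "area", "session_id")
    if (!identical(sort(names(utab)), sort(need))) {
      stop("units table must have exactly columns unit_id, area, session_id",
           call. = FALSE)
    }
    extra <- !(utab$unit_id %in% unit_area$unit_id)
    unit_area <- rbind(unit_area, utab[extra, c("unit_id", "area")])
    if (length(sess_ids) == 0L) sess_ids <- unique(utab$session_id)
  }
  spikes <- split(tab$time_s, factor(tab$unit_id, levels = unit_area$unit_id))
  spike_session(spikes, unit_area$area, duration = duration,
                session_id = sess_ids[1], focal_area = focal_area)
}

#' Write a session as a spikes table
#'
#' @param session a [spike_session()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(session, path) {
  n <- session$units$n_spikes
  tab <- data.frame(
    unit_id = rep(session$units$unit_id, n),
    area = rep(session$units$area, n),
    session_id = session$session_id,
    time_s = unlist(session$spikes, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop sparsely firing units
#'
#' Retains units with strictly more than `min_spikes` spikes over the whole
#' session (the customary inclusion rule for assembly analysis: a unit with
#' exactly `min_spikes` spikes is removed). The removed unit ids are attached
#' as attribute `"removed_units"` for logging.
#'
#' @param session a [spike_session()].
#' @param min_spikes inclusion threshold; keep units with `n_spikes > min_spikes`.
#' @return the filtered [spike_session()] (possibly with zero units), with
#'   attribute `removed_units`.
#' @export
filter_min_spikes <- function(session, min_spikes = 100) {
  if (!is.numeric(min_spikes) || length(min_spikes) != 1L || min_spikes < 0) {
    stop("`min_spikes` must be a single nonnegative number", call. = FALSE)
  }
  keep <- session$units$n_spikes > min_spikes
  removed <- session$units$unit_id[!keep]
  out <- session
  out$units <- session$units[keep, , drop = FALSE]
  rownames(out$units) <- NULL
  out$spikes <- session$spikes[keep]
  attr(out, "removed_units") <- removed
  out
}

#' Bin a session into a units-by-bins count matrix
#'
#' Bins are half-open intervals `[t*bin, (t+1)*bin)` anchored at time 0; a
#' spike exactly at the session duration is clipped into the final bin so the
#' total count is conserved for every bin size.
#'
#' @param session a [spike_session()].
#' @param bin_size bin width in seconds.
#' @return integer matrix (units x bins) with unit ids as row names;
#'   attributes `bin_size` and `convention` record the binning rule.
#' @export
bin_session <- function(session, bin_size) {
  stop_if_not_scalar_pos(bin_size, "bin_size")
  n_bins <- max(1L, as.integer(ceiling(session$duration / bin_size - 1e-9)))
  m <- matrix(0L, nrow = nrow(session$units), ncol = n_bins,
              dimnames = list(session$units$unit_id, NULL))
  for (i in seq_along(session$spikes)) {
    idx <- spike_bin_index(session$spikes[[i]], bin_size, n_bins)
    if (length(idx)) {
      cnt <- tabulate(idx, nbins = n_bins)
      m[i, ] <- cnt
    }
  }
  attr(m, "bin_size") <- bin_size
  attr(m, "convention") <- "half-open [t*bin,(t+1)*bin), t=duration clipped into last bin"
  m
}

# Map spike times to 1-based bin indices; spikes at (or numerically beyond)
# the last edge land in the final bin.
spike_bin_index <- function(times, bin_size, n_bins) {
  if (!length(times)) return(integer(0))
  idx <- floor(times / bin_size) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

# Sorted unique occupied-bin indices of one unit (binarized view).
occupied_bins <- function(times, bin_size, n_bins) {
  unique(spike_bin_index(times, bin_size, n_bins))
}
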