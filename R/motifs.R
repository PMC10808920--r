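#' Classify detected assemblies relative to a focal area
#'
#' Sorts every pair assembly into the directional taxonomy (from/to the
#' focal area, synchronous, internal to the focal area, internal to another
#' area, or external between two non-focal areas) and every triplet into
#' loop-like versus non-loop-like motifs. A loop-like triplet is a strictly
#' sequential chain A-then-B-then-A whose first and last (distinct) units
#' share an area while the middle unit sits in the other area:
#' `triplet_loop_focal` when the flanking units are focal (ZI->X->ZI) and
#' `triplet_loop_external` when they are external (X->ZI->X). Triplets with
#' any synchronous sub-activation, a different chain order, or spanning
#' three areas are `triplet_non_loop`.
#'
#' @param fit an `assembly_set` from [detect_assemblies()].
#' @param focal focal area label; defaults to the session's.
#' @return a `motif_set`: the assembly data.frame augmented with `klass`,
#'   `partner_area` (the non-focal area involved, or `NA`), `delay_ms`
#'   (total span of the activation chain), `direction` (+1 leading unit in
#'   focal, -1 trailing into focal, 0 otherwise) and, for triplets,
#'   `pairwise_supported` (both chain-adjacent pairs also significant at the
#'   pairwise level). Carries `focal_area`, `units`, `session_id`,
#'   `duration` as attributes.
#' @export
classify_motifs <- function(fit, focal = fit$focal_area) {
  stopifnot(inherits(fit, "assembly_set"))
  asm <- fit$assemblies
  n <- nrow(asm)
  klass <- character(n); partner <- rep(NA_character_, n)
  direction <- integer(n); supported <- rep(NA, n)
  pair_keys <- pair_unit_keys(asm)
  for (k in seq_len(n)) {
    row <- asm[k, ]
    if (row$order == 2L) {
      cl <- classify_pair_row(row$area_1, row$area_2, row$lag_2, focal)
      klass[k] <- cl$klass; partner[k] <- cl$partner
      direction[k] <- cl$direction
    } else {
      cl <- classify_triplet_row(c(row$area_1, row$area_2, row$area_3),
                                 c(row$lag_1, row$lag_2, row$lag_3), focal)
      klass[k] <- cl$klass; partner[k] <- cl$partner
      supported[k] <- all(c(
        paste(sort(c(row$unit_1, row$unit_2)), collapse = "|"),
        paste(sort(c(row$unit_2, row$unit_3)), collapse = "|")
      ) %in% pair_keys)
    }
  }
  asm$klass <- klass
  asm$partner_area <- partner
  asm$direction <- direction
  asm$delay_ms <- 1000 * asm$bin_size *
    ifelse(asm$order == 2L, asm$lag_2, asm$lag_3)
  asm$pairwise_supported <- supported
  structure(asm, class = c("motif_set", "data.frame"),
            focal_area = focal, units = fit$units,
            session_id = fit$session_id, duration = fit$duration)
}

pair_unit_keys <- function(asm) {
  p <- asm[asm$order == 2L, , drop = FALSE]
  if (!nrow(p)) return(character(0))
  vapply(seq_len(nrow(p)), function(i) {
    paste(sort(c(p$unit_1[i], p$unit_2[i])), collapse = "|")
  }, character(1))
}

# Taxonomy for one pair; areas are the canonical (leader, trailer) labels.
classify_pair_row <- function(area_1, area_2, lag, focal) {
  both_focal <- area_1 == focal && area_2 == focal
  if (both_focal) {
    return(list(klass = "pair_internal_focal", partner = NA_character_,
                direction = 0L))
  }
  if (area_1 == area_2) {
    return(list(klass = "pair_internal_other", partner = area_1,
                direction = 0L))
  }
  if (area_1 != focal && area_2 != focal) {
    return(list(klass = "pair_external_other", partner = NA_character_,
                direction = 0L))
  }
  partner <- if (area_1 == focal) area_2 else area_1
  if (lag == 0L) {
    return(list(klass = "pair_synchronous", partner = partner,
                direction = 0L))
  }
  if (area_1 == focal) {
    list(klass = "pair_from_focal", partner = partner, direction = 1L)
  } else {
    list(klass = "pair_to_focal", partner = partner, direction = -1L)
  }
}

# Taxonomy for one triplet; inputs are canonically ordered (lags
# nondecreasing, first = 0).
classify_triplet_row <- function(areas, lags, focal) {
  partner <- setdiff(unique(areas), focal)
  partner <- if (length(partner) == 1L) partner else NA_character_
  sequential <- lags[1] < lags[2] && lags[2] < lags[3]
  two_areas <- length(unique(areas)) == 2L
  looplike <- sequential && two_areas &&
    areas[1] == areas[3] && areas[2] != areas[1]
  if (!looplike) {
    return(list(klass = "triplet_non_loop", partner = partner))
  }
  if (areas[1] == focal) {
    list(klass = "triplet_loop_focal", partner = areas[2])
  } else if (areas[2] == focal) {
    list(klass = "triplet_loop_external", partner = areas[1])
  } else {
    # loop not involving the focal area at all
    list(klass = "triplet_non_loop", partner = partner)
  }
}

#' Pairwise support of a triplet
#'
#' Checks whether the two chain-adjacent unit pairs of a triplet (first and
#' second, second and third units of the activation sequence) were also
#' returned as significant pair assemblies.
#'
#' @param units ordered character vector of the triplet's three unit ids.
#' @param fit an `assembly_set` (its order-2 assemblies are consulted).
#' @return logical flag.
#' @export
pairwise_support <- function(units, fit) {
  stopifnot(length(units) == 3L)
  keys <- pair_unit_keys(fit$assemblies)
  all(c(paste(sort(units[1:2]), collapse = "|"),
        paste(sort(units[2:3]), collapse = "|")) %in% keys)
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> session %s, focal area %s: %d assemblies\n",
              attr(x, "session_id"), attr(x, "focal_area"), nrow(x)))
  if (nrow(x)) print(table(x$klass))
  invisible(x)
}

#' @export
summary.motif_set <- function(object, ...) {
  tab <- table(object$klass)
  trip <- object[object$order == 3L, , drop = FALSE]
  loops <- trip[trip$klass %in% c("triplet_loop_focal",
                                  "triplet_loop_external"), , drop = FALSE]
  out <- list(klass_table = tab,
              n_loops = nrow(loops),
              support_fraction = if (nrow(loops)) {
                mean(loops$pairwise_supported)
              } else NA_real_)
  class(out) <- "summary.motif_set"
  out
}

#' @export
print.summary.motif_set <- function(x, ...) {
  print(x$klass_table)
  if (!is.na(x$support_fraction)) {
    cat(sprintf("loop-like triplets with full pairwise support: %.0f%%\n",
                100 * x$support_fraction))
  }
  invisible(x)
}

#' @export
plot.motif_set <- function(x, ...) {
  ext <- x[x$klass %in% c("pair_from_focal", "pair_to_focal",
                          "pair_synchronous"), , drop = FALSE]
  if (!nrow(ext)) {
    graphics::plot.new(); graphics::title("no external pair assemblies")
    return(invisible(x))
  }
  signed <- ext$delay_ms * ifelse(ext$klass == "pair_to_focal", -1, 1)
  lim <- max(abs(signed), 10)
  graphics::hist(signed, breaks = seq(-lim - 10, lim + 10, by = 10),
                 main = sprintf("Cross-regional delays (focal %s)",
                                attr(x, "focal_area")),
                 xlab = "signed delay (ms); negative = to focal",
                 col = "grey70", ...)
  invisible(x)
}

#' Per-unit assembly coverage of the focal area
#'
#' For each focal-area unit counts the external areas with which it forms at
#' least one pair assembly (`k`) out of the `N` external areas available in
#' the session, and whether it forms any internal pair. Units are placed in
#' exactly one of five mutually exclusive categories: `no_int_no_ext`,
#' `only_int`, `lt_half_ext_at_least_1` (`0 < 2k < N`), `ge_half_not_all`
#' (`2k >= N`, `k < N`), `all_ext` (`k = N`).
#'
#' @param motifs a `motif_set` from [classify_motifs()].
#' @return data.frame with one row per focal unit: `unit_id`, `category`,
#'   `n_partner_areas`, `n_areas_available`, `internal` (any internal pair).
#' @export
assembly_coverage <- function(motifs) {
  units <- attr(motifs, "units")
  focal <- attr(motifs, "focal_area")
  focal_units <- units$unit_id[units$area == focal]
  ext_areas <- setdiff(unique(units$area), focal)
  n_avail <- length(ext_areas)
  pairs <- motifs[motifs$order == 2L, , drop = FALSE]
  res <- lapply(focal_units, function(uid) {
    inv <- pairs$unit_1 == uid | pairs$unit_2 == uid
    p <- pairs[inv, , drop = FALSE]
    internal <- any(p$klass == "pair_internal_focal")
    ext <- p[p$klass %in% c("pair_from_focal", "pair_to_focal",
                            "pair_synchronous"), , drop = FALSE]
    k <- length(unique(ext$partner_area))
    category <- if (k == 0L) {
      if (internal) "only_int" else "no_int_no_ext"
    } else if (k == n_avail) {
      "all_ext"
    } else if (2L * k >= n_avail) {
      "ge_half_not_all"
    } else {
      "lt_half_ext_at_least_1"
    }
    data.frame(unit_id = uid, category = category, n_partner_areas = k,
               n_areas_available = n_avail, internal = internal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res) %||%
    data.frame(unit_id = character(0), category = character(0),
               n_partner_areas = integer(0), n_areas_available = integer(0),
               internal = logical(0))
  out
}

#' Cross-tabulate loop membership against coverage
#'
#' Splits the focal units by whether they take part in at least one
#' loop-like triplet, cross-tabulates that split against the coverage
#' categories of [assembly_coverage()], and reports, within each branch, the
#' share of focal units that pair internally with at least half of the other
#' focal units.
#'
#' @param motifs a `motif_set`.
#' @return list with `crosstab` (loop membership x coverage counts),
#'   `fractions` (coverage fractions within each branch, each summing to 1),
#'   and `internal_half_fraction` (named: share of units coupled to >= half
#'   of the other focal units, per branch).
#' @export
loop_membership_crosstab <- function(motifs) {
  units <- attr(motifs, "units")
  focal <- attr(motifs, "focal_area")
  focal_units <- units$unit_id[units$area == focal]
  cov <- assembly_coverage(motifs)
  loops <- motifs[motifs$klass %in% c("triplet_loop_focal",
                                      "triplet_loop_external"), ,
                  drop = FALSE]
  in_loop <- vapply(focal_units, function(uid) {
    any(loops$unit_1 == uid | loops$unit_2 == uid | loops$unit_3 == uid)
  }, logical(1))
  branch <- factor(ifelse(in_loop, "loop_like", "non_loop_only"),
                   levels = c("loop_like", "non_loop_only"))
  categories <- c("no_int_no_ext", "only_int", "lt_half_ext_at_least_1",
                  "ge_half_not_all", "all_ext")
  cat_f <- factor(cov$category, levels = categories)
  crosstab <- table(branch, cat_f, dnn = c("membership", "coverage"))
  fractions <- prop.table(crosstab + 0, margin = 1)
  fractions[is.nan(fractions)] <- NA
  # internal coordination: paired with >= half of the other focal units
  pairs <- motifs[motifs$order == 2L &
                    motifs$klass == "pair_internal_focal", , drop = FALSE]
  n_other <- length(focal_units) - 1L
  half_int <- vapply(focal_units, function(uid) {
    partners <- unique(c(pairs$unit_2[pairs$unit_1 == uid],
                         pairs$unit_1[pairs$unit_2 == uid]))
    n_other > 0L && 2L * length(partners) >= n_other
  }, logical(1))
  internal_half_fraction <- vapply(levels(branch), function(b) {
    sel <- branch == b
    if (!any(sel)) return(NA_real_)
    mean(half_int[sel])
  }, numeric(1))
  list(crosstab = crosstab, fractions = fractions,
       internal_half_fraction = internal_half_fraction)
}
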