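#' Export the focal-area coordination graph
#'
#' Builds the directed area graph: the focal area in the center, one node
#' per partner area, an edge focal->partner weighted by the probability of
#' "from focal" directional assemblies and an edge partner->focal weighted
#' by the "to focal" probability. Zero-probability edges are omitted. With
#' `sync = TRUE` an undirected graph weighted by the synchronous-pair
#' probability is written instead.
#'
#' @param summary_tab an [area_pair_summary()] table.
#' @param path output file path.
#' @param fmt `"graphml"`, `"dot"` or `"tsv"` (edge list).
#' @param sync write the undirected synchronous-probability variant.
#' @return `path`, invisibly. The igraph object is attached as attribute
#'   `"graph"`.
#' @export
export_area_graph <- function(summary_tab, path,
                              fmt = c("graphml", "dot", "tsv"),
                              sync = FALSE) {
  fmt <- match.arg(fmt)
  if (!nrow(summary_tab)) stop("empty statistics table", call. = FALSE)
  focal <- summary_tab$area_a[1]
  if (sync) {
    edges <- data.frame(from = focal, to = summary_tab$area_b,
                        weight = summary_tab$p_sync,
                        stringsAsFactors = FALSE)
  } else {
    edges <- rbind(
      data.frame(from = focal, to = summary_tab$area_b,
                 weight = summary_tab$p_from, stringsAsFactors = FALSE),
      data.frame(from = summary_tab$area_b, to = focal,
                 weight = summary_tab$p_to, stringsAsFactors = FALSE)
    )
  }
  edges <- edges[edges$weight > 0, , drop = FALSE]
  nodes <- unique(c(focal, summary_tab$area_b))
  g <- igraph::graph_from_data_frame(edges, directed = !sync,
                                     vertices = data.frame(name = nodes))
  write_graph_file(g, path, fmt, edges)
  out <- path
  attr(out, "graph") <- g
  invisible(out)
}

#' Export the neuron-area coordination graph
#'
#' Undirected bipartite-plus-internal graph of one session: one node per
#' focal unit and one per external area; an edge between two focal units
#' when they share an internal assembly, and between a focal unit and an
#' area when the unit forms at least one assembly with units of that area.
#'
#' @param motifs a `motif_set`.
#' @param path output file path.
#' @param fmt `"graphml"`, `"dot"` or `"tsv"`.
#' @return `path`, invisibly; igraph object as attribute `"graph"`.
#' @export
export_neuron_graph <- function(motifs, path,
                                fmt = c("graphml", "dot", "tsv")) {
  fmt <- match.arg(fmt)
  units <- attr(motifs, "units")
  focal <- attr(motifs, "focal_area")
  focal_units <- units$unit_id[units$area == focal]
  if (!length(focal_units)) stop("no focal units", call. = FALSE)
  ext_areas <- setdiff(unique(units$area), focal)
  pairs <- motifs[motifs$order == 2L, , drop = FALSE]
  internal <- pairs[pairs$klass == "pair_internal_focal", , drop = FALSE]
  edges <- NULL
  if (nrow(internal)) {
    e <- t(apply(internal[c("unit_1", "unit_2")], 1L, sort))
    edges <- unique(data.frame(from = e[, 1], to = e[, 2],
                               stringsAsFactors = FALSE))
  }
  ext <- pairs[pairs$klass %in% c("pair_from_focal", "pair_to_focal",
                                  "pair_synchronous"), , drop = FALSE]
  if (nrow(ext)) {
    uid <- ifelse(ext$area_1 == focal, ext$unit_1, ext$unit_2)
    edges <- rbind(edges,
                   unique(data.frame(from = uid, to = ext$partner_area,
                                     stringsAsFactors = FALSE)))
  }
  nodes <- data.frame(name = c(focal_units, ext_areas),
                      type = rep(c("unit", "area"),
                                 c(length(focal_units), length(ext_areas))),
                      stringsAsFactors = FALSE)
  edges <- edges %||% data.frame(from = character(0), to = character(0))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  write_graph_file(g, path, fmt, edges)
  out <- path
  attr(out, "graph") <- g
  invisible(out)
}

write_graph_file <- function(g, path, fmt, edges) {
  if (fmt == "tsv") {
    tab <- edges
    if (!is.null(tab$weight)) {
      tab$weight <- formatC(tab$weight, digits = 17, format = "g")
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = fmt)
  }
  invisible(path)
}

#' Summary tables of the motif analysis
#'
#' Machine-readable bundle of the analysis summaries: partner-area rankings
#' by pair/loop/synchronous probability, the directional-versus-synchronous
#' percentage split (within external and within focal-internal pairs),
#' coverage-category percentages, loop-membership percentages, and the
#' signed-delay histogram per area pair (negative delays are "to focal").
#'
#' @param motifs a `motif_set`.
#' @param summary_tab an [area_pair_summary()] table for the same session(s).
#' @param delay_bin_ms width of the delay histogram bins, milliseconds.
#' @return list of data.frames: `ranking_pairs`, `ranking_loops`,
#'   `ranking_sync`, `directional_split`, `coverage_pct`,
#'   `loop_membership_pct`, `delay_histogram`.
#' @export
summary_tables <- function(motifs, summary_tab, delay_bin_ms = 10) {
  rank_cols <- c("area_a", "area_b", "n_a", "n_b", "p_ext", "p_loop",
                 "p_sync", "int_ext")
  rk <- function(metric) {
    r <- rank_areas(summary_tab, metric)
    r[intersect(rank_cols, names(r))]
  }
  pairs <- motifs[motifs$order == 2L, , drop = FALSE]
  split_tab <- function(sel) {
    p <- pairs[sel, , drop = FALSE]
    n <- nrow(p)
    n_dir <- sum(p$lag_2 > 0L)
    data.frame(n = n,
               pct_directional = if (n) 100 * n_dir / n else NA_real_,
               pct_synchronous = if (n) 100 * (n - n_dir) / n else NA_real_)
  }
  directional_split <- rbind(
    cbind(group = "external",
          split_tab(pairs$klass %in% c("pair_from_focal", "pair_to_focal",
                                       "pair_synchronous"))),
    cbind(group = "internal_focal",
          split_tab(pairs$klass == "pair_internal_focal"))
  )
  cov <- assembly_coverage(motifs)
  categories <- c("no_int_no_ext", "only_int", "lt_half_ext_at_least_1",
                  "ge_half_not_all", "all_ext")
  cov_tab <- table(factor(cov$category, levels = categories))
  coverage_pct <- data.frame(
    category = categories,
    n_units = as.integer(cov_tab),
    pct = if (nrow(cov)) 100 * as.integer(cov_tab) / nrow(cov) else NA_real_,
    stringsAsFactors = FALSE)
  ct <- loop_membership_crosstab(motifs)
  membership_n <- rowSums(ct$crosstab)
  loop_membership_pct <- data.frame(
    membership = names(membership_n),
    n_units = as.integer(membership_n),
    pct = if (sum(membership_n)) {
      100 * as.integer(membership_n) / sum(membership_n)
    } else NA_real_,
    internal_half_pct = 100 * ct$internal_half_fraction,
    stringsAsFactors = FALSE)
  ext <- pairs[pairs$klass %in% c("pair_from_focal", "pair_to_focal",
                                  "pair_synchronous"), , drop = FALSE]
  delay_histogram <- if (nrow(ext)) {
    signed <- ext$delay_ms * ifelse(ext$klass == "pair_to_focal", -1, 1)
    bin <- delay_bin_ms * floor(signed / delay_bin_ms)
    agg <- stats::aggregate(list(n = signed),
                            by = list(partner_area = ext$partner_area,
                                      delay_bin_ms = bin), FUN = length)
    agg[order(agg$partner_area, agg$delay_bin_ms), , drop = FALSE]
  } else {
    data.frame(partner_area = character(0), delay_bin_ms = numeric(0),
               n = integer(0))
  }
  list(ranking_pairs = rk("pairs"), ranking_loops = rk("loops"),
       ranking_sync = rk("sync"), directional_split = directional_split,
       coverage_pct = coverage_pct, loop_membership_pct = loop_membership_pct,
       delay_histogram = delay_histogram)
}

#' Write the summary bundle to disk
#'
#' @param tables output of [summary_tables()].
#' @param dir output directory (created if missing); each table is written
#'   as `<name>.tsv` plus a combined `report.json`.
#' @return `dir`, invisibly.
#' @export
write_summary_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(tables, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
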