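#' Aggregate child-rank subgroups for higher-rank lottery analysis
#'
#' For each annotated group at `rank`, its subgroups are the distinct
#' annotated names at the immediately lower rank among the group's features;
#' a subgroup's per-sample abundance is the sum of its members' abundances.
#' Features annotated at `rank` but unannotated at the child rank are
#' dropped from that group's aggregation, so abundance from two different
#' unknown lineages is never pooled.
#'
#' @param table a relative `abundance_table`.
#' @param lineage lineage data.frame covering the table's features.
#' @param rank a rank above the table's base rank.
#' @return list with `table` (an `abundance_table` whose features are
#'   `"<group>|<subgroup>"` aggregates), `groups` (named list mapping each
#'   group at `rank` to its aggregate feature ids) and `subgroup_names`
#'   (map aggregate id -> child-rank name). Single-subgroup groups are kept
#'   here; [hierarchical_lottery_scan()] excludes them from analysis.
#' @export
aggregate_subgroups <- function(table, lineage, rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  ri <- match(rank, TAXONOMIC_RANKS)
  if (ri >= match(base_rank(lineage), TAXONOMIC_RANKS))
    stop("rank '", rank, "' is not above the table's base rank")
  child <- TAXONOMIC_RANKS[ri + 1L]
  lineage <- lineage[feature_ids(table), , drop = FALSE]
  ok <- !is.na(lineage[[rank]]) & !is.na(lineage[[child]])
  if (!any(ok))
    return(list(table = NULL, groups = structure(list(), rank = rank),
                subgroup_names = character()))
  key <- paste(lineage[[rank]][ok], lineage[[child]][ok], sep = "|")
  feats <- rownames(lineage)[ok]
  agg <- rowsum(table$values[feats, , drop = FALSE], key, reorder = TRUE)
  sub_table <- abundance_table(agg, "relative")
  parents <- sub("\\|.*$", "", rownames(agg))
  groups <- split(rownames(agg), parents)
  list(table = sub_table,
       groups = structure(groups[order(names(groups))], rank = rank),
       subgroup_names = stats::setNames(sub("^[^|]*\\|", "", rownames(agg)),
                                        rownames(agg)))
}

rank_letter <- function(rank) substr(rank, 1L, 1L)

#' Lottery statistics at every taxonomic rank above the base
#'
#' Walks the ranks from one above the table's base rank up to phylum. At
#' each rank every group's subgroups (child-rank aggregates) are treated as
#' single entities and scored with [group_lottery_stats()]; a group's
#' statistics thus never depend on how abundance is distributed *within* a
#' subgroup. Groups with fewer than two subgroups are skipped, and the group
#' abundance filter is re-applied independently at every rank (after which
#' the subgroup count is re-checked).
#'
#' @param table a relative `abundance_table`.
#' @param lineage lineage data.frame covering the table's features.
#' @param cfg a [metric_config()].
#' @param filter_cfg a [filter_config()] re-applied per rank.
#' @return data.frame as [lottery_scan()], with single-letter rank labels
#'   (p/c/o/f/g) in `rank`; empty (with a warning) when the lineage spans
#'   only the base rank.
#' @export
hierarchical_lottery_scan <- function(table, lineage, cfg = metric_config(),
                                      filter_cfg = filter_config()) {
  base <- base_rank(lineage[feature_ids(table), , drop = FALSE])
  bi <- match(base, TAXONOMIC_RANKS)
  pi <- match("phylum", TAXONOMIC_RANKS)
  if (bi - 1L < pi) {
    warning("lineage spans only the base rank; nothing to aggregate")
    return(lottery_scan(table, structure(list(), rank = NULL), cfg))
  }
  out <- lapply(seq(bi - 1L, pi), function(ri) {
    rank <- TAXONOMIC_RANKS[ri]
    agg <- aggregate_subgroups(table, lineage, rank)
    if (is.null(agg$table)) return(NULL)
    groups <- agg$groups[lengths(agg$groups) >= 2L]
    groups <- filter_groups(agg$table, structure(groups, rank = rank),
                            filter_cfg)
    groups <- structure(groups[lengths(groups) >= 2L], rank = rank)
    df <- lottery_scan(agg$table, groups, cfg, rank = rank_letter(rank))
    df
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out))
    return(lottery_scan(table, structure(list(), rank = NULL), cfg))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
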