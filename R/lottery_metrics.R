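#' Configuration of the lottery statistics
#'
#' @param winner_cutoff within-group fraction a member must strictly exceed
#'   to be the sample's winner; must lie in (0.5, 1) so at most one winner
#'   can exist per sample. Default 0.9.
#' @param sample_inclusion_min_group_abundance a sample enters a group's
#'   statistics only if the group's summed abundance strictly exceeds this
#'   (default 0.005, i.e. 0.5%).
#' @param prevalence_threshold,diversity_threshold classification thresholds:
#'   lottery-like groups have winner prevalence strictly above the first and
#'   normalized winner diversity strictly above the second (defaults 0.75 and
#'   0.25).
#' @param top_k optional: restrict the group to its `k` most abundant members
#'   (largest mean relative abundance over included samples) and renormalize
#'   within that subset.
#' @return a `metric_config` list.
#' @export
metric_config <- function(winner_cutoff = 0.9,
                          sample_inclusion_min_group_abundance = 0.005,
                          prevalence_threshold = 0.75,
                          diversity_threshold = 0.25,
                          top_k = NULL) {
  if (winner_cutoff <= 0.5 || winner_cutoff >= 1)
    stop("winner_cutoff must lie in (0.5, 1)")
  thr <- c(sample_inclusion_min_group_abundance, prevalence_threshold,
           diversity_threshold)
  if (any(thr <= 0 | thr >= 1)) stop("thresholds must lie in (0, 1)")
  if (!is.null(top_k) && top_k < 1L) stop("top_k must be >= 1")
  structure(list(winner_cutoff = winner_cutoff,
                 sample_inclusion_min_group_abundance =
                   sample_inclusion_min_group_abundance,
                 prevalence_threshold = prevalence_threshold,
                 diversity_threshold = diversity_threshold,
                 top_k = if (is.null(top_k)) NULL else as.integer(top_k)),
            class = "metric_config")
}

#' Within-group relative abundances of one sample
#'
#' Each member's abundance divided by the group's summed abundance in that
#' sample; fractions sum to 1.
#'
#' @param table a relative `abundance_table`.
#' @param members character vector of member feature ids.
#' @param sample a sample id.
#' @return named numeric vector of fractions, or `NULL` when the group's
#'   abundance in the sample is zero (the sample is undefined for this
#'   group, not an error).
#' @export
within_group_fractions <- function(table, members, sample) {
  v <- stats::setNames(table$values[members, sample], members)
  tot <- sum(v)
  if (tot == 0) return(NULL)
  v / tot
}

#' Call the lottery winner of one sample
#'
#' The winner is the unique member whose within-group fraction strictly
#' exceeds `winner_cutoff`; since the cutoff exceeds 0.5 at most one such
#' member can exist. Ties for the maximum are broken lexicographically by
#' member id (they cannot affect the winner call itself).
#'
#' @param fractions named fractions from [within_group_fractions()].
#' @param cfg a [metric_config()].
#' @return list with `winner` (member id or `NA`) and `winner_fraction`
#'   (the maximum within-group fraction).
#' @export
call_winner <- function(fractions, cfg = metric_config()) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  ord <- order(-fractions, names(fractions))
  top <- fractions[ord[1L]]
  list(winner = if (top > cfg$winner_cutoff) names(top) else NA_character_,
       winner_fraction = unname(top))
}

shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Shannon entropy of a within-group abundance vector
#'
#' Base-2 entropy of the fractions, with the convention 0*log(0) = 0. For a
#' k-member group the reference value under perfectly even abundances is
#' `log2(k)`.
#'
#' @inheritParams call_winner
#' @return entropy in bits.
#' @export
per_sample_entropy <- function(fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  shannon_bits(fractions)
}

top_k_members <- function(table, members, included, k) {
  if (length(members) <= k) return(members)
  mean_ab <- rowMeans(table$values[members, included, drop = FALSE])
  members[order(-mean_ab, members)][seq_len(k)]
}

#' Lottery statistics for one taxonomic group
#'
#' Computes, over the samples where the group's abundance strictly exceeds
#' the inclusion floor: the winner call per sample, the winner prevalence
#' (fraction of included samples with a winner), the winner frequency table,
#' and the normalized winner diversity — the base-2 Shannon entropy of the
#' winner frequencies divided by `log2` of the number of distinct winners.
#' Conventions: a single distinct winner gives diversity 0; no winner at all
#' gives diversity `NA`.
#'
#' @param table a relative `abundance_table`.
#' @param members member feature ids of the group.
#' @param cfg a [metric_config()]; `cfg$top_k` restricts to the k most
#'   abundant members with renormalization.
#' @param group_name,rank labels carried into the result.
#' @return object of class `group_lottery_result`.
#' @export
group_lottery_stats <- function(table, members, cfg = metric_config(),
                                group_name = NA_character_, rank = NA_character_) {
  gab <- group_abundance(table, members)
  included <- names(gab)[gab > cfg$sample_inclusion_min_group_abundance]
  if (!length(included))
    stop("group ", group_name,
         " below inclusion threshold in all samples")
  if (!is.null(cfg$top_k))
    members <- top_k_members(table, members, included, cfg$top_k)
  sub <- table$values[members, included, drop = FALSE]
  tot <- colSums(sub)
  # with top_k the restricted members can be jointly absent from a sample;
  # such samples carry no defined fractions and are dropped
  included <- included[tot > 0]
  if (!length(included))
    stop("group ", group_name,
         " below inclusion threshold in all samples")
  sub <- sub[, tot > 0, drop = FALSE]
  tot <- tot[tot > 0]
  frac <- sweep(sub, 2L, tot, "/")
  top_idx <- apply(frac, 2L, function(f) order(-f, members)[1L])
  top_frac <- frac[cbind(top_idx, seq_along(included))]
  winners <- ifelse(top_frac > cfg$winner_cutoff, members[top_idx],
                    NA_character_)
  winner_counts <- table(factor(winners[!is.na(winners)], levels = members))
  winner_counts <- winner_counts[winner_counts > 0]
  n_distinct <- length(winner_counts)
  diversity <- if (n_distinct == 0L) NA_real_
  else if (n_distinct == 1L) 0
  else {
    p <- as.numeric(winner_counts) / sum(winner_counts)
    shannon_bits(p) / log2(n_distinct)
  }
  entropy <- apply(frac, 2L, shannon_bits)
  structure(list(
    group_name = group_name,
    rank = rank,
    members = members,
    n_included_samples = length(included),
    winner_prevalence = sum(!is.na(winners)) / length(included),
    winner_counts = stats::setNames(as.integer(winner_counts),
                                    names(winner_counts)),
    n_distinct_winners = n_distinct,
    winner_diversity_normalized = diversity,
    per_sample_entropy = stats::setNames(as.numeric(entropy), included),
    winner_calls = data.frame(sample_id = included,
                              winner = winners,
                              winner_fraction = as.numeric(top_frac),
                              group_abundance = as.numeric(gab[included]),
                              stringsAsFactors = FALSE, row.names = NULL)),
    class = "group_lottery_result")
}

#' @export
print.group_lottery_result <- function(x, ...) {
  cat(sprintf(
    "group %s (%s): %d samples, prevalence %.3f, %d winners, diversity %s\n",
    x$group_name, x$rank, x$n_included_samples, x$winner_prevalence,
    x$n_distinct_winners,
    if (is.na(x$winner_diversity_normalized)) "NA"
    else sprintf("%.3f", x$winner_diversity_normalized)))
  invisible(x)
}

#' Classify a group's assembly schema
#'
#' `lottery_like` iff winner prevalence strictly exceeds the prevalence
#' threshold and normalized winner diversity strictly exceeds the diversity
#' threshold; `fixed_winner` for high prevalence with at-threshold-or-lower
#' diversity; otherwise `non_lottery`. Groups with no winner at all
#' (diversity `NA`) are `non_lottery`.
#'
#' @param result a `group_lottery_result`.
#' @param cfg a [metric_config()].
#' @return one of `"lottery_like"`, `"fixed_winner"`, `"non_lottery"`.
#' @export
classify_group <- function(result, cfg = metric_config()) {
  prev <- result$winner_prevalence
  div <- result$winner_diversity_normalized
  if (is.na(div)) return("non_lottery")
  if (prev > cfg$prevalence_threshold) {
    if (div > cfg$diversity_threshold) "lottery_like" else "fixed_winner"
  } else "non_lottery"
}

#' Lottery statistics for every group in a table
#'
#' @param table a relative `abundance_table`.
#' @param groups named member list ([build_groups()]), typically already
#'   passed through [filter_groups()].
#' @param cfg a [metric_config()].
#' @param rank rank label for the output (defaults to the groups' attribute).
#' @return data.frame with one row per group that has at least one included
#'   sample: `rank`, `group`, `n_samples`, `winner_prevalence`, `n_winners`,
#'   `winner_diversity`, `classification`.
#' @export
lottery_scan <- function(table, groups, cfg = metric_config(),
                         rank = attr(groups, "rank")) {
  rows <- lapply(names(groups), function(g) {
    res <- tryCatch(group_lottery_stats(table, groups[[g]], cfg,
                                        group_name = g, rank = rank),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(rank = if (is.null(rank)) NA_character_ else rank,
               group = g,
               n_samples = res$n_included_samples,
               winner_prevalence = res$winner_prevalence,
               n_winners = res$n_distinct_winners,
               winner_diversity = res$winner_diversity_normalized,
               classification = classify_group(res, cfg),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(rank = character(), group = character(),
                      n_samples = integer(), winner_prevalence = numeric(),
                      n_winners = integer(), winner_diversity = numeric(),
                      classification = character(), stringsAsFactors = FALSE)
  out
}

#' Robustness sweep over metric-configuration variants
#'
#' Recomputes one group's lottery statistics under each configuration
#' variant. Three axes are supported: the winner cutoff, the OTU-inclusion
#' abundance threshold (the feature filter is re-applied at that threshold
#' and the member set re-intersected), and a top-k member restriction.
#'
#' @param table a relative `abundance_table`.
#' @param members member feature ids of the group.
#' @param winner_cutoffs,otu_min_abundances,top_ks vectors of values for each
#'   axis (`NA` in `top_ks` means no restriction); the sweep is the full
#'   grid.
#' @param cfg baseline [metric_config()] supplying the unswept parameters.
#' @param filter_cfg baseline [filter_config()] for the feature-filter axis.
#' @return data.frame with the grid columns plus `n_samples`,
#'   `winner_prevalence`, `n_winners`, `winner_diversity`.
#' @export
sensitivity_sweep <- function(table, members,
                              winner_cutoffs = 0.9,
                              otu_min_abundances = 0.0005,
                              top_ks = NA,
                              cfg = metric_config(),
                              filter_cfg = filter_config()) {
  grid <- expand.grid(winner_cutoff = winner_cutoffs,
                      otu_min_abundance = otu_min_abundances,
                      top_k = top_ks, KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("empty sweep grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fcfg <- filter_cfg
    fcfg$otu_min_abundance <- grid$otu_min_abundance[i]
    kept <- feature_ids(filter_features(table, fcfg))
    mem <- intersect(members, kept)
    vcfg <- cfg
    vcfg$winner_cutoff <- grid$winner_cutoff[i]
    vcfg$top_k <- if (is.na(grid$top_k[i])) NULL else
      as.integer(grid$top_k[i])
    res <- if (length(mem))
      tryCatch(group_lottery_stats(table, mem, vcfg),
               error = function(e) NULL) else NULL
    cbind(grid[i, , drop = FALSE],
          data.frame(
            n_samples = if (is.null(res)) 0L else res$n_included_samples,
            winner_prevalence = if (is.null(res)) NA_real_ else
              res$winner_prevalence,
            n_winners = if (is.null(res)) 0L else res$n_distinct_winners,
            winner_diversity = if (is.null(res)) NA_real_ else
              res$winner_diversity_normalized))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Deterministic sample ordering for within-group heatmaps
#'
#' Included samples are grouped into contiguous blocks by the identity of
#' their most abundant member; blocks are ordered by descending size and
#' samples within a block by decreasing fraction of that member. Ties are
#' broken lexicographically (member id for the dominant member and block
#' order, sample id within blocks), so the ordering is reproducible.
#'
#' @inheritParams group_lottery_stats
#' @return data.frame in display order: `sample_id`, `dominant_member`,
#'   `dominant_fraction`, `group_abundance`.
#' @export
order_samples_for_display <- function(table, members, cfg = metric_config()) {
  gab <- group_abundance(table, members)
  included <- names(gab)[gab > cfg$sample_inclusion_min_group_abundance]
  if (!length(included)) stop("no included samples for display ordering")
  sub <- table$values[members, included, drop = FALSE]
  frac <- sweep(sub, 2L, colSums(sub), "/")
  dom_idx <- apply(frac, 2L, function(f) order(-f, members)[1L])
  df <- data.frame(sample_id = included,
                   dominant_member = members[dom_idx],
                   dominant_fraction = frac[cbind(dom_idx,
                                                  seq_along(included))],
                   group_abundance = as.numeric(gab[included]),
                   stringsAsFactors = FALSE)
  block_size <- table(df$dominant_member)
  df$block_rank <- rank_blocks(df$dominant_member, block_size)
  df <- df[order(df$block_rank, -df$dominant_fraction, df$sample_id), ]
  df$block_rank <- NULL
  rownames(df) <- NULL
  df
}

rank_blocks <- function(dominant, block_size) {
  ord <- names(block_size)[order(-as.integer(block_size), names(block_size))]
  match(dominant, ord)
}
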