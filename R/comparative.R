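#' Spearman comparison of lottery parameters between two datasets
#'
#' Correlates one lottery parameter (winner prevalence or normalized winner
#' diversity) over the (rank, group) pairs shared by two [lottery_scan()]
#' result tables; groups missing from either dataset are excluded.
#'
#' @param a,b data.frames as returned by [lottery_scan()] /
#'   [hierarchical_lottery_scan()].
#' @param parameter `"prevalence"` or `"diversity"`.
#' @return list with `rho`, `p_value`, `n_shared_groups` and the paired
#'   `table` (rank, group, value_a, value_b).
#' @export
compare_datasets <- function(a, b, parameter = c("prevalence", "diversity")) {
  parameter <- match.arg(parameter)
  col <- if (parameter == "prevalence") "winner_prevalence" else
    "winner_diversity"
  paired <- merge(a[, c("rank", "group", col)],
                  b[, c("rank", "group", col)],
                  by = c("rank", "group"), suffixes = c("_a", "_b"))
  names(paired)[3:4] <- c("value_a", "value_b")
  paired <- paired[stats::complete.cases(paired), , drop = FALSE]
  if (nrow(paired) < 3L)
    stop("need at least 3 shared groups, found ", nrow(paired))
  ct <- suppressWarnings(stats::cor.test(paired$value_a, paired$value_b,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_shared_groups = nrow(paired), table = paired)
}

#' Select genera for the genome gene-content comparison
#'
#' Only genus-rank groups with normalized winner diversity strictly above
#' the diversity threshold in the primary dataset are eligible (excluding
#' fixed-winner genera). The high-prevalence class requires winner
#' prevalence strictly above the prevalence threshold in the primary dataset
#' *and* in at least one other dataset; the low class is prevalence strictly
#' below the threshold in the primary. Genera at exactly the threshold, or
#' high in the primary only, remain `unclassified`.
#'
#' @param results named list of [lottery_scan()] tables, one per dataset.
#' @param primary name of the primary dataset within `results`.
#' @param cfg a [metric_config()] supplying the thresholds.
#' @return data.frame: `genus`, `class` in
#'   `{lottery_like, non_lottery, unclassified}`.
#' @export
select_genome_comparison_groups <- function(results, primary,
                                            cfg = metric_config()) {
  if (length(results) < 2L || !primary %in% names(results))
    stop("need >= 2 datasets including the primary '", primary, "'")
  prim <- results[[primary]]
  prim <- prim[prim$rank %in% c("genus", "g"), , drop = FALSE]
  eligible <- prim[!is.na(prim$winner_diversity) &
                     prim$winner_diversity > cfg$diversity_threshold, ,
                   drop = FALSE]
  others <- results[setdiff(names(results), primary)]
  cls <- vapply(seq_len(nrow(eligible)), function(i) {
    g <- eligible$group[i]
    p <- eligible$winner_prevalence[i]
    if (p > cfg$prevalence_threshold) {
      confirmed <- any(vapply(others, function(df) {
        df <- df[df$rank %in% c("genus", "g") & df$group == g, ,
                 drop = FALSE]
        nrow(df) > 0 && any(df$winner_prevalence > cfg$prevalence_threshold)
      }, logical(1L)))
      if (confirmed) "lottery_like" else "unclassified"
    } else if (p < cfg$prevalence_threshold) "non_lottery" else "unclassified"
  }, character(1L))
  out <- data.frame(genus = eligible$group, class = cls,
                    stringsAsFactors = FALSE)
  if (!any(out$class == "lottery_like") || !any(out$class == "non_lottery"))
    stop("genome comparison requires both a high- and a low-prevalence class")
  out
}

#' Validate a genome gene-count table
#'
#' Contract for the per-species gene-count input (species averaged over
#' their genomes): columns `species_id`, `genus`, `n_genes_total`,
#' `n_genes_ko`, `n_genes_no_ko`, with `total = ko + no_ko` and all counts
#' non-negative.
#'
#' @param genomes data.frame to validate.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_genome_table <- function(genomes) {
  needed <- c("species_id", "genus", "n_genes_total", "n_genes_ko",
              "n_genes_no_ko")
  miss <- setdiff(needed, colnames(genomes))
  if (length(miss))
    stop("genome table lacks column(s): ", paste(miss, collapse = ", "))
  counts <- genomes[, c("n_genes_total", "n_genes_ko", "n_genes_no_ko")]
  if (any(counts < 0)) stop("gene counts must be non-negative")
  if (any(genomes$n_genes_total !=
            genomes$n_genes_ko + genomes$n_genes_no_ko))
    stop("n_genes_total must equal n_genes_ko + n_genes_no_ko")
  if (anyDuplicated(genomes$species_id))
    stop("duplicate species_id: ",
         genomes$species_id[duplicated(genomes$species_id)][1L])
  genomes
}

#' Compare genome gene counts between assembly classes
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of per-species gene counts
#' between lottery-like and non-lottery genera, run on total, KO-annotated
#' or unannotated counts. Welch's t test is available behind `test`. No
#' multiple-testing correction is applied across the three count fields.
#'
#' @param genomes validated genome table ([validate_genome_table()]).
#' @param classes data.frame from [select_genome_comparison_groups()] (or a
#'   compatible `genus`/`class` frame).
#' @param field `"total"`, `"ko_annotated"` or `"unannotated"`.
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @return list with `statistic`, `p_value`, `n` per class and per-class
#'   median summaries.
#' @export
compare_gene_counts <- function(genomes, classes,
                                field = c("total", "ko_annotated",
                                          "unannotated"),
                                test = c("wilcoxon", "welch")) {
  field <- match.arg(field)
  test <- match.arg(test)
  genomes <- validate_genome_table(genomes)
  col <- switch(field, total = "n_genes_total", ko_annotated = "n_genes_ko",
                unannotated = "n_genes_no_ko")
  cls <- classes$class[match(genomes$genus, classes$genus)]
  unmapped <- is.na(cls) | cls == "unclassified"
  if (any(unmapped))
    warning(sum(unmapped), " species not mappable to a classified genus; ",
            "dropped")
  genomes <- genomes[!unmapped, , drop = FALSE]
  cls <- cls[!unmapped]
  x <- genomes[[col]][cls == "lottery_like"]
  y <- genomes[[col]][cls == "non_lottery"]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 species per class (got ", length(x), " and ",
         length(y), ")")
  ht <- if (test == "wilcoxon")
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  else stats::t.test(x, y, alternative = "two.sided")
  list(field = field, test = test,
       statistic = unname(ht$statistic), p_value = ht$p.value,
       n_lottery = length(x), n_non_lottery = length(y),
       median_lottery = stats::median(x),
       median_non_lottery = stats::median(y))
}

#' Assemble and write the full report bundle
#'
#' Collects the pipeline's result tables — per-genus lottery statistics
#' (scatter-plot data), per-group ordered sample matrices, hierarchical
#' statistics, cross-dataset comparison, turnover census and gene-count
#' comparison — and writes each as TSV under `out_dir`, plus a
#' `run_metadata.tsv` log of configuration and seed. Re-running with the
#' same inputs, seed and configuration reproduces the bundle byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param genus_stats,hierarchy_stats data.frames from [lottery_scan()] /
#'   [hierarchical_lottery_scan()].
#' @param ordered_samples optional named list (group -> data.frame from
#'   [order_samples_for_display()]).
#' @param cross_dataset optional result of [compare_datasets()].
#' @param turnover optional result of [turnover_census()].
#' @param gene_comparison optional list of [compare_gene_counts()] results.
#' @param config,seed recorded in the metadata log.
#' @return invisible named character vector of the files written.
#' @export
build_report <- function(out_dir, genus_stats = NULL, hierarchy_stats = NULL,
                         ordered_samples = NULL, cross_dataset = NULL,
                         turnover = NULL, gene_comparison = NULL,
                         config = list(), seed = NA_integer_) {
  if (is.null(genus_stats) && is.null(hierarchy_stats) &&
      is.null(turnover) && is.null(gene_comparison))
    stop("nothing to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written[[name]] <<- path
  }
  if (!is.null(genus_stats)) emit(genus_stats, "group_stats.tsv")
  if (!is.null(hierarchy_stats)) emit(hierarchy_stats, "hierarchy_stats.tsv")
  if (!is.null(ordered_samples)) {
    all_ord <- do.call(rbind, lapply(names(ordered_samples), function(g)
      cbind(group = g, ordered_samples[[g]])))
    emit(all_ord, "ordered_samples.tsv")
  }
  if (!is.null(cross_dataset)) {
    emit(cross_dataset$table, "cross_dataset_pairs.tsv")
    emit(data.frame(rho = cross_dataset$rho,
                    p_value = cross_dataset$p_value,
                    n_shared_groups = cross_dataset$n_shared_groups),
         "cross_dataset_summary.tsv")
  }
  if (!is.null(turnover)) {
    emit(turnover$records, "turnover_records.tsv")
    emit(data.frame(n_pairs_examined = turnover$n_pairs_examined,
                    n_pairs_with_turnover = turnover$n_pairs_with_turnover),
         "turnover_summary.tsv")
  }
  if (!is.null(gene_comparison)) {
    emit(do.call(rbind, lapply(gene_comparison, function(x)
      data.frame(field = x$field, test = x$test, statistic = x$statistic,
                 p_value = x$p_value, n_lottery = x$n_lottery,
                 n_non_lottery = x$n_non_lottery,
                 median_lottery = x$median_lottery,
                 median_non_lottery = x$median_non_lottery))),
      "gene_count_comparison.tsv")
  }
  cfg_flat <- unlist(config)
  emit(data.frame(key = c("seed", names(cfg_flat)),
                  value = c(as.character(seed),
                            as.character(cfg_flat))),
       "run_metadata.tsv")
  invisible(written)
}
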