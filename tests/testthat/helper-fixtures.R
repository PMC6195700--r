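# Fixture builders and independent brute-force oracles. The oracles are
# written as plain loops over the raw matrix, sharing no code with the
# package internals they check.

make_table <- function(values, kind = "relative") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("OTU", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  abundance_table(values, kind)
}

# random relative table: features get lognormal weights, columns normalized
random_relative_table <- function(n_features, n_samples) {
  m <- matrix(rlnorm(n_features * n_samples, sdlog = 2),
              nrow = n_features)
  m <- sweep(m, 2L, colSums(m), "/")
  make_table(m)
}

simple_lineage <- function(feature_ids, genus) {
  parse_lineage_strings(
    setNames(paste0("k__B; p__P; c__C; o__O; f__F; g__", genus),
             feature_ids),
    feature_ids)
}

# ---- naive recomputation of the lottery statistics (triple loop) ----
naive_group_stats <- function(values, members, cutoff = 0.9,
                              floor_ab = 0.005) {
  n_winner <- 0L
  n_included <- 0L
  winner_ids <- character(0L)
  for (s in colnames(values)) {
    gab <- 0
    for (m in members) gab <- gab + values[m, s]
    if (gab <= floor_ab) next
    n_included <- n_included + 1L
    for (m in members) {
      if (values[m, s] / gab > cutoff) {
        n_winner <- n_winner + 1L
        winner_ids <- c(winner_ids, m)
      }
    }
  }
  if (n_included == 0L) return(NULL)
  counts <- table(winner_ids)
  H <- 0
  for (cnt in counts) {
    p <- cnt / sum(counts)
    H <- H - p * log2(p)
  }
  diversity <- if (length(counts) == 0L) NA_real_
  else if (length(counts) == 1L) 0
  else H / log2(length(counts))
  list(n_included = n_included,
       prevalence = n_winner / n_included,
       counts = counts,
       diversity = diversity)
}

# naive turnover census over a metadata-indexed table
naive_turnover_census <- function(values, groups, metadata, cutoff = 0.9,
                                  floor_ab = 0.005) {
  examined <- 0L
  turned <- 0L
  for (g in names(groups)) {
    for (subj in unique(metadata$subject_id)) {
      samples <- metadata$sample_id[metadata$subject_id == subj]
      samples <- samples[order(metadata$time_point[match(samples,
                                                         metadata$sample_id)])]
      winners <- character(0L)
      eligible_tp <- 0L
      for (s in samples) {
        gab <- sum(values[groups[[g]], s])
        if (gab <= floor_ab) next
        eligible_tp <- eligible_tp + 1L
        for (m in groups[[g]])
          if (values[m, s] / gab > cutoff) winners <- c(winners, m)
      }
      if (eligible_tp >= 2L) {
        examined <- examined + 1L
        if (length(unique(winners)) >= 2L) turned <- turned + 1L
      }
    }
  }
  list(examined = examined, turned = turned)
}

# exact winner-prevalence for k iid Poisson(lambda) members, by enumeration
poisson_prevalence_oracle <- function(k, lambda, cutoff = 0.9,
                                      max_count = 30L) {
  counts <- 0:max_count
  mass <- dpois(counts, lambda)
  grids <- do.call(expand.grid, rep(list(counts), k))
  p <- apply(do.call(expand.grid, rep(list(mass), k)), 1L, prod)
  tot <- rowSums(grids)
  keep <- p > 1e-12 & tot > 0
  winner <- apply(grids, 1L, max) / pmax(tot, 1L) > cutoff
  sum(p[keep & winner]) / sum(p[keep])
}
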