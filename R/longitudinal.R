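#' Detect lottery-winner turnover in one subject's time series
#'
#' A (subject, group) pair is *eligible* when at least two time points have
#' group abundance strictly above the 0.5% inclusion floor. Turnover is
#' declared iff two time points carry different non-missing winner calls;
#' time points without a winner never create turnover, and a winner that
#' reverts to the initial member still counts (the predicate is existential,
#' not sequential). The full timeline is retained for visualization.
#'
#' @param timeline data.frame with columns `time_point`, `winner`
#'   (member id or `NA`) and `group_abundance`, one row per time point.
#' @param cfg a [metric_config()] supplying the group-abundance floor.
#' @param subject_id,group_name labels carried into the record.
#' @return object of class `turnover_record`: the ordered timeline plus
#'   `eligible` and `turnover` flags.
#' @export
detect_turnover <- function(timeline, cfg = metric_config(),
                            subject_id = NA_character_,
                            group_name = NA_character_) {
  if (!nrow(timeline)) stop("timeline must contain at least one time point")
  if (anyDuplicated(timeline$time_point))
    stop("duplicate time point for subject ", subject_id, ": ",
         timeline$time_point[duplicated(timeline$time_point)][1L])
  ord <- order(timeline$time_point)
  if (any(is.na(ord)) || any(is.na(timeline$time_point)))
    stop("unsortable time points for subject ", subject_id)
  timeline <- timeline[ord, , drop = FALSE]
  floor_ab <- cfg$sample_inclusion_min_group_abundance
  at_floor <- timeline$group_abundance > floor_ab
  eligible <- sum(at_floor) >= 2L
  winners <- timeline$winner[at_floor & !is.na(timeline$winner)]
  structure(list(subject_id = subject_id,
                 group_name = group_name,
                 timeline = timeline,
                 n_eligible_timepoints = sum(at_floor),
                 eligible = eligible,
                 winners = unique(winners),
                 turnover = eligible && length(unique(winners)) >= 2L),
            class = "turnover_record")
}

#' Winner-turnover census across all subjects and groups
#'
#' For every group (typically those passing the cohort-level group filter)
#' and every subject with time-series metadata, winners are called per time
#' point with the standard 0.9 within-group cutoff, pairs are screened for
#' eligibility (two time points above the 0.5% group-abundance floor), and
#' turnover is flagged per [detect_turnover()].
#'
#' @param table a relative `abundance_table`.
#' @param groups named member list ([build_groups()] / [filter_groups()]).
#' @param metadata data.frame with `sample_id`, `subject_id`, `time_point`
#'   covering every sample of `table`.
#' @param cfg a [metric_config()].
#' @return list with `n_pairs_examined` (eligible pairs), `n_pairs_with_turnover`,
#'   and `records`, a data.frame over all (subject, group) pairs: subject,
#'   group, n_timepoints, n_eligible_timepoints, winners (time-ordered,
#'   comma-joined, `.` for no winner), eligible, turnover.
#' @export
turnover_census <- function(table, groups, metadata, cfg = metric_config()) {
  needed <- c("sample_id", "subject_id", "time_point")
  miss_col <- setdiff(needed, colnames(metadata))
  if (length(miss_col))
    stop("metadata lacks required column(s): ",
         paste(miss_col, collapse = ", "))
  miss <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(miss))
    stop("samples missing subject/time metadata: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  bad <- metadata$sample_id[is.na(metadata$subject_id) |
                              is.na(metadata$time_point)]
  bad <- intersect(bad, sample_ids(table))
  if (length(bad))
    stop("samples with missing subject/time values: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  md <- metadata[match(sample_ids(table), metadata$sample_id), ]
  rows <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    gab <- group_abundance(table, members)
    for (subj in unique(md$subject_id)) {
      sel <- md$subject_id == subj
      samples <- md$sample_id[sel]
      winners <- vapply(samples, function(s) {
        if (gab[s] <= cfg$sample_inclusion_min_group_abundance)
          return(NA_character_)
        fr <- within_group_fractions(table, members, s)
        call_winner(fr, cfg)$winner
      }, character(1L))
      rec <- detect_turnover(
        data.frame(time_point = md$time_point[sel],
                   winner = unname(winners),
                   group_abundance = as.numeric(gab[samples]),
                   stringsAsFactors = FALSE),
        cfg, subject_id = subj, group_name = g)
      tl <- rec$timeline
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj, group = g,
        n_timepoints = nrow(tl),
        n_eligible_timepoints = rec$n_eligible_timepoints,
        winners = paste(ifelse(is.na(tl$winner), ".", tl$winner),
                        collapse = ","),
        eligible = rec$eligible,
        turnover = rec$turnover,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(subject_id = character(), group = character(),
                          n_timepoints = integer(),
                          n_eligible_timepoints = integer(),
                          winners = character(), eligible = logical(),
                          turnover = logical(), stringsAsFactors = FALSE)
  list(n_pairs_examined = sum(records$eligible),
       n_pairs_with_turnover = sum(records$turnover),
       records = records)
}
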