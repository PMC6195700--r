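with_seed_if <- function(seed, code) {
  if (is.null(seed)) code() else withr::with_seed(as.integer(seed), code())
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[1L] <- 1  # numerically degenerate draw, all mass to one
  g / sum(g)
}

#' Stick-breaking species-abundance null
#'
#' Random partitions of the unit interval used as the null model for
#' within-group abundance vectors. Two variants: `gem` performs sequential
#' `Beta(1, theta)` stick breaks with the final remainder assigned to the
#' last piece; `broken_stick` cuts the interval at `n - 1` uniform points
#' and returns the segment lengths.
#'
#' @param n number of pieces (>= 1).
#' @param theta GEM concentration (default 1); larger values give more even
#'   pieces.
#' @param variant `"gem"` or `"broken_stick"`.
#' @param seed optional integer seed (the global RNG state is untouched).
#' @return numeric vector of `n` non-negative fractions summing to 1.
#' @export
stick_breaking_abundances <- function(n, theta = 1,
                                      variant = c("gem", "broken_stick"),
                                      seed = NULL) {
  variant <- match.arg(variant)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (theta <= 0) stop("theta must be positive")
  with_seed_if(seed, function() {
    if (n == 1L) return(1)
    if (variant == "gem") {
      breaks <- stats::rbeta(n - 1L, 1, theta)
      remaining <- cumprod(c(1, 1 - breaks[-(n - 1L)]))
      c(breaks * remaining, prod(1 - breaks))
    } else {
      diff(c(0, sort(stats::runif(n - 1L)), 1))
    }
  })
}

#' Specify a within-group assembly schema
#'
#' Defines how a group's abundance is split among its members in each
#' sample. `lottery`: a winner drawn from `winner_distribution` takes a
#' fraction drawn from `Uniform(winner_fraction_min, winner_fraction_max)`
#' (default (0.92, 1), i.e. always above the 0.9 winner cutoff) and the
#' remainder is allocated among the losers. `fixed_winner`: the same with a
#' point-mass winner distribution. `coexistence`: a symmetric Dirichlet over
#' all members.
#'
#' @param schema `"lottery"`, `"fixed_winner"` or `"coexistence"`.
#' @param n_members number of members (>= 1).
#' @param winner_distribution probabilities over members (lottery); defaults
#'   to uniform. For `fixed_winner` a point mass on `fixed_winner_index`.
#' @param winner_fraction_min,winner_fraction_max support of the winner's
#'   within-group fraction.
#' @param loser_allocation `"stick_breaking"` (GEM over the non-winners) or
#'   `"symmetric_dirichlet"`.
#' @param coexistence_concentration Dirichlet concentration for the
#'   coexistence schema (default 10, strongly even).
#' @param stick_theta GEM parameter for stick-breaking loser allocation.
#' @param fixed_winner_index member index receiving the point mass.
#' @return a `schema_spec` list.
#' @export
schema_spec <- function(schema = c("lottery", "fixed_winner", "coexistence"),
                        n_members = 5L,
                        winner_distribution = NULL,
                        winner_fraction_min = 0.92,
                        winner_fraction_max = 1,
                        loser_allocation = c("stick_breaking",
                                             "symmetric_dirichlet"),
                        coexistence_concentration = 10,
                        stick_theta = 1,
                        fixed_winner_index = 1L) {
  schema <- match.arg(schema)
  loser_allocation <- match.arg(loser_allocation)
  n_members <- as.integer(n_members)
  if (n_members < 1L) stop("n_members must be >= 1")
  if (schema == "fixed_winner") {
    winner_distribution <- rep(0, n_members)
    winner_distribution[fixed_winner_index] <- 1
  } else if (is.null(winner_distribution)) {
    winner_distribution <- rep(1 / n_members, n_members)
  }
  if (length(winner_distribution) != n_members ||
      abs(sum(winner_distribution) - 1) > 1e-9)
    stop("winner_distribution must be a probability vector over members")
  if (winner_fraction_min >= winner_fraction_max ||
      winner_fraction_min <= 0 || winner_fraction_max > 1)
    stop("winner fraction law must have 0 < min < max <= 1")
  structure(list(schema = schema, n_members = n_members,
                 winner_distribution = winner_distribution,
                 winner_fraction_min = winner_fraction_min,
                 winner_fraction_max = winner_fraction_max,
                 loser_allocation = loser_allocation,
                 coexistence_concentration = coexistence_concentration,
                 stick_theta = stick_theta),
            class = "schema_spec")
}

draw_within_group <- function(spec) {
  k <- spec$n_members
  if (spec$schema == "coexistence") {
    return(list(fractions = rdirichlet1(rep(spec$coexistence_concentration,
                                            k)),
                winner = NA_integer_, winner_fraction = NA_real_))
  }
  w <- sample.int(k, 1L, prob = spec$winner_distribution)
  wf <- stats::runif(1L, spec$winner_fraction_min, spec$winner_fraction_max)
  fr <- numeric(k)
  fr[w] <- wf
  if (k > 1L) {
    losers <- if (spec$loser_allocation == "stick_breaking")
      stick_breaking_abundances(k - 1L, spec$stick_theta)
    else rdirichlet1(rep(1, k - 1L))
    fr[-w] <- (1 - wf) * losers
  } else fr[w] <- 1
  list(fractions = fr, winner = w, winner_fraction = wf)
}

#' Specify a synthetic community
#'
#' The two-step assembly model: in each sample, the total abundance (100%)
#' is first allocated among groups by a symmetric Dirichlet; each group's
#' share is then split among its members by the group's schema.
#'
#' @param schemas named list of [schema_spec()]s, one per group; names are
#'   used as genus names (`g__<name>`).
#' @param n_samples number of samples.
#' @param read_depth expected reads per sample, or `Inf` for noise-free
#'   relative abundances.
#' @param group_concentration Dirichlet concentration of the group
#'   allocation (default 5: all groups routinely well above the 0.5%
#'   inclusion floor).
#' @param lineages optional named list of named character vectors
#'   (rank -> `"x__Name"`) overriding the default flat lineages.
#' @return a `community_spec` list.
#' @export
community_spec <- function(schemas, n_samples = 100L, read_depth = Inf,
                           group_concentration = 5,
                           lineages = NULL) {
  if (!length(schemas) || is.null(names(schemas)) ||
      anyDuplicated(names(schemas)))
    stop("schemas must be a uniquely named list")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (!is.infinite(read_depth) && read_depth < 1)
    stop("read_depth must be >= 1 or Inf")
  structure(list(schemas = schemas, n_samples = as.integer(n_samples),
                 read_depth = read_depth,
                 group_concentration = group_concentration,
                 lineages = lineages),
            class = "community_spec")
}

default_lineage <- function(group) {
  c(kingdom = "k__Bacteria", phylum = "p__SimPhylum", class = "c__SimClass",
    order = "o__SimOrder", family = "f__SimFamily",
    genus = paste0("g__", group))
}

spec_feature_frame <- function(spec) {
  rows <- lapply(names(spec$schemas), function(g) {
    k <- spec$schemas[[g]]$n_members
    lin <- if (!is.null(spec$lineages)) spec$lineages[[g]] else
      default_lineage(g)
    data.frame(feature_id = sprintf("%s_OTU%02d", g, seq_len(k)),
               group = g,
               lineage = paste(lin, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a community under the two-step assembly model
#'
#' @param spec a [community_spec()].
#' @param seed integer seed; identical seeds reproduce identical tables.
#' @return list with `table` (an `abundance_table`; Poisson counts when
#'   `read_depth` is finite, otherwise exact relative abundances), `lineage`
#'   (data.frame for [build_groups()]), `groups` (the true membership), and
#'   `truth` — one row per (sample, group): schema, group allocation, true
#'   winner feature id (`NA` for coexistence) and its drawn fraction.
#' @export
simulate_community <- function(spec, seed = NULL) {
  feats <- spec_feature_frame(spec)
  groups <- split(feats$feature_id, feats$group)
  groups <- structure(groups[names(spec$schemas)], rank = "genus")
  n_groups <- length(spec$schemas)
  with_seed_if(seed, function() {
    rel <- matrix(0, nrow = nrow(feats), ncol = spec$n_samples,
                  dimnames = list(feats$feature_id,
                                  sprintf("S%04d", seq_len(spec$n_samples))))
    truth <- vector("list", spec$n_samples * n_groups)
    for (s in seq_len(spec$n_samples)) {
      alloc <- rdirichlet1(rep(spec$group_concentration, n_groups))
      for (gi in seq_len(n_groups)) {
        g <- names(spec$schemas)[gi]
        sc <- spec$schemas[[gi]]
        d <- draw_within_group(sc)
        rel[groups[[g]], s] <- alloc[gi] * d$fractions
        truth[[(s - 1L) * n_groups + gi]] <- data.frame(
          sample_id = colnames(rel)[s], group = g, schema = sc$schema,
          group_allocation = alloc[gi],
          true_winner = if (is.na(d$winner)) NA_character_ else
            groups[[g]][d$winner],
          true_winner_fraction = d$winner_fraction,
          stringsAsFactors = FALSE)
      }
    }
    tab <- if (is.infinite(spec$read_depth)) {
      abundance_table(rel, "relative")
    } else {
      counts <- matrix(stats::rpois(length(rel), rel * spec$read_depth),
                       nrow = nrow(rel), dimnames = dimnames(rel))
      abundance_table(counts, "counts")
    }
    list(table = tab,
         lineage = parse_lineage_strings(
           stats::setNames(feats$lineage, feats$feature_id)),
         groups = groups,
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Winner-prevalence inflation under Poisson sampling noise
#'
#' Simulates a group whose members all sit at the same true abundance `a`
#' (so the true winner prevalence is zero), draws per-member counts
#' `Poisson(a * read_depth)`, and reports the fraction of samples in which
#' sampling noise alone creates an artificial winner. Used to choose the
#' minimum-abundance floor below which winner calls are unreliable.
#'
#' @param n_members members per group (>= 2).
#' @param abundance_grid true per-member abundances to evaluate.
#' @param read_depth expected total reads per sample.
#' @param n_reps samples simulated per grid point.
#' @param winner_cutoff within-group fraction defining a winner.
#' @param seed integer seed.
#' @return data.frame per grid point: `abundance`, `expected_count` (per
#'   member), `n_retained` (samples with nonzero total), `winner_prevalence`
#'   and its Monte-Carlo standard error.
#' @export
poisson_noise_sweep <- function(n_members, abundance_grid, read_depth = 5000,
                                n_reps = 2000, winner_cutoff = 0.9,
                                seed = NULL) {
  if (!length(abundance_grid)) stop("abundance grid must be non-empty")
  if (any(abundance_grid <= 0)) stop("grid abundances must be > 0")
  if (n_members < 2L) stop("n_members must be >= 2")
  with_seed_if(seed, function() {
    rows <- lapply(abundance_grid, function(a) {
      counts <- matrix(stats::rpois(n_reps * n_members, a * read_depth),
                       nrow = n_reps)
      tot <- rowSums(counts)
      keep <- tot > 0
      win <- apply(counts[keep, , drop = FALSE], 1L, max) /
        tot[keep] > winner_cutoff
      p <- mean(win)
      data.frame(abundance = a, expected_count = a * read_depth,
                 n_retained = sum(keep), winner_prevalence = p,
                 mc_se = sqrt(p * (1 - p) / max(sum(keep), 1L)))
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Simulate longitudinal series with planted winner turnovers
#'
#' Each subject gets `timepoints_per_subject` samples. Within lottery and
#' fixed-winner groups the winner persists across a subject's time points,
#' except that in lottery groups each step switches to a different,
#' uniformly chosen member with probability `turnover_rate` (the planted
#' turnover events). Coexistence groups are redrawn independently per time
#' point.
#'
#' @param spec a [community_spec()]; `n_samples` is ignored here.
#' @param n_subjects number of subjects.
#' @param timepoints_per_subject time points per subject (>= 2).
#' @param turnover_rate per-step switch probability in lottery groups.
#' @param seed integer seed.
#' @return list with `table`, `lineage`, `groups`, `metadata` (sample_id,
#'   subject_id, time_point) and `planted` — one row per (subject, lottery
#'   group): the winner sequence, number of planted switches and a
#'   `turnover` flag.
#' @export
simulate_longitudinal <- function(spec, n_subjects = 10L,
                                  timepoints_per_subject = 3L,
                                  turnover_rate = 0.3, seed = NULL) {
  if (timepoints_per_subject < 2L)
    stop("timepoints_per_subject must be >= 2")
  if (turnover_rate < 0 || turnover_rate > 1)
    stop("turnover_rate must lie in [0, 1]")
  feats <- spec_feature_frame(spec)
  groups <- split(feats$feature_id, feats$group)
  groups <- structure(groups[names(spec$schemas)], rank = "genus")
  n_groups <- length(spec$schemas)
  with_seed_if(seed, function() {
    sids <- as.vector(t(outer(seq_len(n_subjects),
                              seq_len(timepoints_per_subject),
                              function(i, t) sprintf("subj%02d_t%02d", i, t))))
    rel <- matrix(0, nrow = nrow(feats), ncol = length(sids),
                  dimnames = list(feats$feature_id, sids))
    metadata <- data.frame(
      sample_id = sids,
      subject_id = rep(sprintf("subj%02d", seq_len(n_subjects)),
                       each = timepoints_per_subject),
      time_point = rep(seq_len(timepoints_per_subject), n_subjects),
      stringsAsFactors = FALSE)
    planted <- list()
    col <- 0L
    for (i in seq_len(n_subjects)) {
      winner_state <- lapply(spec$schemas, function(sc) {
        if (sc$schema == "coexistence") NA_integer_
        else sample.int(sc$n_members, 1L, prob = sc$winner_distribution)
      })
      switches <- stats::setNames(integer(n_groups), names(spec$schemas))
      winner_seq <- lapply(spec$schemas, function(sc) character(0L))
      for (t in seq_len(timepoints_per_subject)) {
        col <- col + 1L
        alloc <- rdirichlet1(rep(spec$group_concentration, n_groups))
        for (gi in seq_len(n_groups)) {
          g <- names(spec$schemas)[gi]
          sc <- spec$schemas[[gi]]
          if (sc$schema == "coexistence") {
            fr <- rdirichlet1(rep(sc$coexistence_concentration,
                                  sc$n_members))
          } else {
            if (sc$schema == "lottery" && t > 1L && sc$n_members > 1L &&
                stats::runif(1L) < turnover_rate) {
              others <- setdiff(seq_len(sc$n_members), winner_state[[g]])
              winner_state[[g]] <- others[sample.int(length(others), 1L)]
              switches[g] <- switches[g] + 1L
            }
            w <- winner_state[[g]]
            wf <- stats::runif(1L, sc$winner_fraction_min,
                               sc$winner_fraction_max)
            fr <- numeric(sc$n_members)
            fr[w] <- wf
            if (sc$n_members > 1L)
              fr[-w] <- (1 - wf) *
                (if (sc$loser_allocation == "stick_breaking")
                  stick_breaking_abundances(sc$n_members - 1L,
                                            sc$stick_theta)
                 else rdirichlet1(rep(1, sc$n_members - 1L)))
            else fr[w] <- 1
            winner_seq[[g]] <- c(winner_seq[[g]], groups[[g]][w])
          }
          rel[groups[[g]], col] <- alloc[gi] * fr
        }
      }
      for (g in names(spec$schemas)) {
        if (spec$schemas[[g]]$schema == "coexistence") next
        planted[[length(planted) + 1L]] <- data.frame(
          subject_id = sprintf("subj%02d", i), group = g,
          winner_sequence = paste(winner_seq[[g]], collapse = ","),
          n_switches = switches[[g]],
          turnover = switches[[g]] > 0L,
          stringsAsFactors = FALSE)
      }
    }
    tab <- if (is.infinite(spec$read_depth)) {
      abundance_table(rel, "relative")
    } else {
      counts <- matrix(stats::rpois(length(rel), rel * spec$read_depth),
                       nrow = nrow(rel), dimnames = dimnames(rel))
      abundance_table(counts, "counts")
    }
    list(table = tab,
         lineage = parse_lineage_strings(
           stats::setNames(feats$lineage, feats$feature_id)),
         groups = groups, metadata = metadata,
         planted = do.call(rbind, c(planted, list(make.row.names = FALSE))))
  })
}

#' Simulate per-species genome gene counts by assembly class
#'
#' Draws species gene counts around class-specific means, emulating the
#' streamlined-genome signal expected in lottery-like genera. Totals are
#' normal around the class mean (truncated at 1); KO-annotated counts are
#' binomial within the total.
#'
#' @param group_classes named character vector genus -> `"lottery_like"` or
#'   `"non_lottery"`.
#' @param n_species_per_genus species simulated per genus.
#' @param lottery_mean,non_lottery_mean class mean total gene counts
#'   (defaults 2000 and 4000).
#' @param sd within-class standard deviation (default 300).
#' @param ko_fraction expected fraction of genes with a KO annotation.
#' @param seed integer seed.
#' @return data.frame matching the genome-table contract: `species_id`,
#'   `genus`, `n_genes_total`, `n_genes_ko`, `n_genes_no_ko`.
#' @export
simulate_gene_counts <- function(group_classes, n_species_per_genus = 5L,
                                 lottery_mean = 2000, non_lottery_mean = 4000,
                                 sd = 300, ko_fraction = 0.55, seed = NULL) {
  if (!length(group_classes) || is.null(names(group_classes)))
    stop("group_classes must be a named vector")
  bad <- setdiff(unique(group_classes), c("lottery_like", "non_lottery"))
  if (length(bad)) stop("unknown class label: ", bad[1L])
  with_seed_if(seed, function() {
    rows <- lapply(names(group_classes), function(g) {
      mu <- if (group_classes[[g]] == "lottery_like") lottery_mean else
        non_lottery_mean
      total <- pmax(1L, round(stats::rnorm(n_species_per_genus, mu, sd)))
      ko <- stats::rbinom(n_species_per_genus, total, ko_fraction)
      data.frame(species_id = sprintf("%s_sp%02d", g,
                                      seq_len(n_species_per_genus)),
                 genus = g,
                 n_genes_total = as.integer(total),
                 n_genes_ko = as.integer(ko),
                 n_genes_no_ko = as.integer(total - ko),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
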