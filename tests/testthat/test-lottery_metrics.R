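test_that("within-group fractions normalize by the group's abundance", {
  tab <- make_table(matrix(c(0.04, 0.01, 0.5), ncol = 1,
                           dimnames = list(c("a", "b", "c"), "S1")))
  expect_equal(within_group_fractions(tab, c("a", "b"), "S1"),
               c(a = 0.8, b = 0.2))
  expect_equal(within_group_fractions(tab, "c", "S1"), c(c = 1))
  tiny <- make_table(matrix(c(1e-9, 1e-9), ncol = 1,
                            dimnames = list(c("a", "b"), "S1")))
  expect_equal(within_group_fractions(tiny, c("a", "b"), "S1"),
               c(a = 0.5, b = 0.5))
  zero <- make_table(matrix(c(0, 0, 1), ncol = 1,
                            dimnames = list(c("a", "b", "c"), "S1")))
  expect_null(within_group_fractions(zero, c("a", "b"), "S1"))
})

test_that("winner calls require strictly more than the cutoff", {
  cfg <- metric_config()
  expect_equal(call_winner(c(a = 0.95, b = 0.03, c = 0.02), cfg)$winner, "a")
  expect_equal(call_winner(c(a = 0.95, b = 0.03, c = 0.02),
                           cfg)$winner_fraction, 0.95)
  expect_true(is.na(call_winner(c(a = 0.90, b = 0.10), cfg)$winner))
  expect_true(is.na(call_winner(c(a = 0.5, b = 0.5), cfg)$winner))
  expect_error(metric_config(winner_cutoff = 0.5))
})

test_that("per-sample entropy follows the base-2 Shannon formula", {
  expect_equal(per_sample_entropy(rep(0.25, 4)), 2)
  expect_equal(per_sample_entropy(c(1, 0, 0)), 0)
  expect_equal(per_sample_entropy(c(0.5, 0.25, 0.25)), 1.5)
})

# a deterministic 8-sample fixture: group {A,B,C}; 4 samples have winners
# (A three times, B once), 4 have even splits, and 2 sit below the 0.5%
# group-abundance floor
winner_count_fixture <- function() {
  cols <- list(
    S01 = c(0.95, 0.03, 0.02), S02 = c(0.96, 0.02, 0.02),
    S03 = c(0.92, 0.04, 0.04), S04 = c(0.05, 0.93, 0.02),
    S05 = c(0.4, 0.3, 0.3),    S06 = c(0.5, 0.3, 0.2),
    S07 = c(0.34, 0.33, 0.33), S08 = c(0.6, 0.2, 0.2),
    S09 = c(0.001, 0.001, 0.001), S10 = c(0.002, 0.001, 0.001))
  vals <- do.call(cbind, cols) * 0.9  # keep included columns above the floor
  rownames(vals) <- c("A", "B", "C")
  make_table(vals)
}

test_that("group statistics match hand-computed prevalence and diversity", {
  res <- group_lottery_stats(winner_count_fixture(), c("A", "B", "C"),
                             group_name = "G")
  expect_equal(res$n_included_samples, 8L)
  expect_equal(res$winner_prevalence, 0.5)
  expect_equal(res$winner_counts, c(A = 3L, B = 1L))
  # H(3/4, 1/4) / log2(2), computed by the direct formula
  expect_equal(res$winner_diversity_normalized,
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  expect_equal(round(res$winner_diversity_normalized, 4), 0.8113)
})

test_that("diversity conventions: equal winners give 1, one winner 0, none NA", {
  # 100 included samples, 4 winners at 25 apiece -> prevalence 1, diversity 1
  vals <- matrix(0.002, nrow = 4, ncol = 100,
                 dimnames = list(LETTERS[1:4], sprintf("S%03d", 1:100)))
  for (s in 1:100) vals[((s - 1) %% 4) + 1, s] <- 0.9
  res <- group_lottery_stats(make_table(vals), LETTERS[1:4])
  expect_identical(res$winner_prevalence, 1)
  expect_identical(res$winner_diversity_normalized, 1)

  single <- matrix(c(rep(0.95, 5), rep(0.01, 5)), nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), paste0("S", 1:5)))
  res1 <- group_lottery_stats(make_table(single / 2), c("A", "B"))
  expect_identical(res1$winner_prevalence, 1)
  expect_identical(res1$winner_diversity_normalized, 0)

  even <- matrix(0.3, nrow = 3, ncol = 5,
                 dimnames = list(c("A", "B", "C"), paste0("S", 1:5)))
  res0 <- group_lottery_stats(make_table(even), c("A", "B", "C"))
  expect_identical(res0$winner_prevalence, 0)
  expect_true(is.na(res0$winner_diversity_normalized))
  expect_equal(classify_group(res0), "non_lottery")

  all_below <- make_table(matrix(1e-4, nrow = 2, ncol = 3,
                                 dimnames = list(c("A", "B"), paste0("S", 1:3))))
  expect_error(group_lottery_stats(all_below, c("A", "B")),
               "below inclusion threshold")
})

test_that("classification uses strict thresholds on both axes", {
  mk <- function(prev, div) structure(
    list(winner_prevalence = prev, winner_diversity_normalized = div),
    class = "group_lottery_result")
  expect_equal(classify_group(mk(0.99, 0.6)), "lottery_like")
  expect_equal(classify_group(mk(0.95, 0.05)), "fixed_winner")
  expect_equal(classify_group(mk(0.75, 0.9)), "non_lottery")  # boundary
  expect_equal(classify_group(mk(0.8, 0.25)), "fixed_winner") # boundary
  expect_equal(classify_group(mk(0.2, 0.9)), "non_lottery")
})

test_that("pipeline statistics equal the naive triple-loop oracle", {
  withr::with_seed(2024, {
    for (rep in 1:40) {
      tab <- random_relative_table(10, 50)
      members <- sample(rownames(tab$values), sample(3:8, 1))
      res <- tryCatch(group_lottery_stats(tab, members),
                      error = function(e) NULL)
      oracle <- naive_group_stats(tab$values, members)
      if (is.null(oracle)) {
        expect_null(res)
      } else {
        expect_equal(res$n_included_samples, oracle$n_included)
        expect_identical(res$winner_prevalence, oracle$prevalence)
        ocounts <- c(unclass(oracle$counts))
        expect_length(res$winner_counts, length(ocounts))
        if (length(ocounts))
          expect_identical(res$winner_counts[sort(names(res$winner_counts))],
                           ocounts[sort(names(ocounts))])
        expect_equal(res$winner_diversity_normalized, oracle$diversity)
      }
    }
  })
})

test_that("prevalence is monotone in the cutoff and under top-k restriction", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      tab <- random_relative_table(8, 40)
      members <- rownames(tab$values)[1:6]
      sweep_df <- sensitivity_sweep(tab, members,
                                    winner_cutoffs = c(0.8, 0.9, 0.99))
      expect_true(all(diff(sweep_df$winner_prevalence) <= 1e-12))
      # top-3 renormalization can only raise the maximum fraction
      full <- group_lottery_stats(tab, members)
      top3 <- group_lottery_stats(tab, members, metric_config(top_k = 3))
      expect_gte(top3$winner_prevalence, full$winner_prevalence)
      # top_k covering the whole group changes nothing
      all_k <- group_lottery_stats(tab, members,
                                   metric_config(top_k = length(members)))
      expect_identical(all_k$winner_prevalence, full$winner_prevalence)
      expect_identical(all_k$winner_diversity_normalized,
                       full$winner_diversity_normalized)
    }
  })
})

test_that("at most one winner exists per sample whenever the cutoff > 0.5", {
  withr::with_seed(5150, {
    for (rep in 1:20) {
      tab <- random_relative_table(6, 30)
      members <- rownames(tab$values)
      cutoff <- runif(1, 0.5001, 0.99)
      for (s in sample_ids(tab)) {
        fr <- within_group_fractions(tab, members, s)
        if (is.null(fr)) next
        expect_lte(sum(fr > cutoff), 1L)
      }
    }
  })
})

test_that("display ordering sorts blocks by size then fraction, deterministically", {
  vals <- matrix(c(0.7, 0.3, 0.99, 0.01, 0.2, 0.8) * 0.5, nrow = 2,
                 dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  ord <- order_samples_for_display(make_table(vals), c("A", "B"))
  expect_equal(ord$sample_id, c("S2", "S1", "S3"))
  expect_equal(ord$dominant_member, c("A", "A", "B"))
  expect_equal(ord$dominant_fraction, c(0.99, 0.7, 0.8))
  # single sample maps to itself; one dominant member gives one sorted block
  one <- make_table(matrix(c(0.4, 0.1), ncol = 1,
                           dimnames = list(c("A", "B"), "S1")))
  expect_equal(order_samples_for_display(one, c("A", "B"))$sample_id, "S1")
  mono <- matrix(c(0.6, 0.1, 0.9, 0.05, 0.7, 0.1) * 0.5, nrow = 2,
                 dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  ordm <- order_samples_for_display(make_table(mono), c("A", "B"))
  expect_equal(ordm$sample_id, c("S2", "S3", "S1"))
})

test_that("OTU-inclusion axis of the sweep re-filters the member set", {
  # member C only ever at 0.002: dropped when the inclusion threshold rises
  vals <- matrix(c(0.90, 0.004, 0.002,
                   0.91, 0.004, 0.002,
                   0.89, 0.004, 0.002) / 3, nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  tab <- make_table(vals)
  fcfg <- filter_config(otu_min_samples_floor = 1,
                        otu_min_sample_fraction = 0.01)
  sw <- sensitivity_sweep(tab, c("A", "B", "C"),
                          otu_min_abundances = c(0.0005, 0.0009),
                          cfg = metric_config(
                            sample_inclusion_min_group_abundance = 0.05),
                          filter_cfg = fcfg)
  # dropping C renormalizes A upward: prevalence cannot decrease
  expect_gte(sw$winner_prevalence[2], sw$winner_prevalence[1])
})
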