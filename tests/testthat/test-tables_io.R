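test_that("lineage strings parse with rank prefixes and unannotated cascade", {
  lin <- parse_lineage_strings(c(
    f1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Ruminococcaceae; g__Faecalibacterium",
    f2 = "k__Bacteria; p__Firmicutes; c__; o__; f__; g__",
    f3 = "",
    f4 = "k__Bacteria; p__Proteobacteria; c__Gammaproteobacteria; o__; f__; g__unclassified"))
  expect_equal(lin["f1", "genus"], "g__Faecalibacterium")
  # empty suffixes leave class..genus unannotated
  expect_true(all(is.na(lin["f2", c("class", "order", "family", "genus")])))
  expect_equal(lin["f2", "phylum"], "p__Firmicutes")
  # empty taxonomy string: everything unannotated
  expect_true(all(is.na(lin["f3", ])))
  # "unclassified" maps to unannotated
  expect_true(is.na(lin["f4", "genus"]))
  # cascade: a gap at one rank blanks all deeper ranks
  gap <- parse_lineage_strings(c(x = "k__B; p__P; c__; o__O; f__F; g__G"))
  expect_true(all(is.na(gap["x", c("class", "order", "family", "genus")])))
})

test_that("TSV round trip preserves values and lineages", {
  vals <- matrix(c(120.5, 3, 0, 7, 42.25, 9999.125), nrow = 3,
                 dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                                 c("S1", "S2")))
  tab <- abundance_table(vals, "counts")
  lin <- parse_lineage_strings(c(
    OTU_a = "k__B; p__P1; c__C; o__O; f__F; g__G1",
    OTU_b = "k__B; p__P1; c__C; o__O; f__F; g__G2",
    OTU_c = "k__B; p__P2; c__; o__; f__; g__"), rownames(vals))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path, lineage = lin)
  back <- read_otu_table(path)
  expect_equal(feature_ids(back$table), rownames(vals))
  expect_equal(sample_ids(back$table), colnames(vals))
  expect_lt(max(abs(back$table$values - vals)), 1e-12)
  expect_identical(back$lineage, lin)
})

test_that("malformed tables and duplicate features are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS2", "a\t1\t2", "a\t3\t4"), path)
  expect_error(read_otu_table(path), "duplicate feature id")
  writeLines(c("#OTU ID\tS1\tS2", "a\t1\t2", "b\t3"), path)
  expect_error(read_otu_table(path), "malformed record")
  writeLines(c("#OTU ID\tS1", "a\tnot_a_number"), path)
  expect_error(read_otu_table(path), "non-numeric")
})

test_that("BIOM files read through biomformat with taxonomy metadata", {
  skip_if_not_installed("biomformat")
  vals <- matrix(c(5, 0, 3, 8, 2, 1), nrow = 3,
                 dimnames = list(paste0("F", 1:3), c("S1", "S2")))
  md <- data.frame(taxonomy1 = c("k__B", "k__B", "k__B"),
                   taxonomy2 = c("p__X", "p__Y", "p__Y"),
                   row.names = rownames(vals))
  b <- biomformat::make_biom(vals, observation_metadata = md)
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  got <- read_otu_table(path)
  expect_equal(got$table$values[rownames(vals), colnames(vals)], vals)
  expect_equal(got$table$value_kind, "counts")
  expect_equal(unname(got$lineage[c("F1", "F2"), "phylum"]),
               c("p__X", "p__Y"))
})

test_that("metaphlan tables keep only deepest-rank rows, in fractions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "clade_name\tS1\tS2",
    "k__A\t100\t100",
    "k__A|p__B\t100\t100",
    "k__A|p__B|c__C|o__O|f__F|g__G\t60\t100",
    "k__A|p__B|c__C|o__O|f__F|g__G|s__X\t12.5\t80",
    "k__A|p__B|c__C|o__O|f__F|g__G|s__Y\t47.5\t20"), path)
  got <- read_metaphlan_table(path)
  # intermediate-rank summary rows excluded; percent converted to fraction
  expect_setequal(feature_ids(got$table), c("s__X", "s__Y"))
  expect_equal(got$table$values["s__X", "S1"], 0.125)
  expect_equal(got$table$value_kind, "relative")
  expect_equal(unname(got$lineage["s__X", "species"]), "s__X")
  expect_equal(unname(got$lineage["s__Y", "genus"]), "g__G")

  writeLines(c("clade_name\tS1", "k__A\t100"), path)
  expect_error(read_metaphlan_table(path), "no base features")
  writeLines(c("clade_name\tS1", "k__A|p__B|c__C\t-5"), path)
  expect_error(read_metaphlan_table(path), "negative abundance")
})

test_that("sample depth filter removes strictly-below-threshold samples", {
  vals <- matrix(c(4999, 0, 2500, 2500, 8000, 0), nrow = 2,
                 dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  tab <- abundance_table(vals, "counts")
  kept <- filter_samples(tab, filter_config())
  expect_equal(sample_ids(kept), c("S2", "S3"))  # 4999 < 5000 removed
  expect_equal(sample_ids(filter_samples(kept, filter_config())),
               c("S2", "S3"))  # idempotent
  tiny <- filter_config(min_reads_per_sample = 1)
  expect_identical(filter_samples(tab, tiny)$values, vals)
  expect_error(filter_samples(tab, filter_config(min_reads_per_sample = 1e6)),
               "no sample")
})

test_that("relative conversion normalizes per column and rejects misuse", {
  tab <- make_table(matrix(c(10, 30, 5, 0), nrow = 2), kind = "counts")
  rel <- to_relative(tab)
  expect_equal(unname(rel$values[, 1L]), c(0.25, 0.75))
  expect_equal(unname(rel$values[, 2L]), c(1, 0))  # single nonzero feature
  expect_error(to_relative(rel), "already relative")
  zero <- make_table(matrix(c(1, 1, 0, 0), nrow = 2), kind = "counts")
  expect_error(to_relative(zero), "zero-sum")
})

test_that("feature filter applies the max(floor, ceil(fraction*n)) rule strictly", {
  # 2000 samples: need max(10, ceil(0.005*2000)) = 10 qualifying samples
  n <- 2000
  base <- matrix(1e-6, nrow = 3, ncol = n)
  base[1, 1:9] <- 0.01    # 9 qualifying -> removed
  base[2, 1:10] <- 0.01   # 10 qualifying -> kept
  base[3, ] <- 0.0005     # exactly at threshold everywhere -> removed
  tab <- make_table(base)
  kept <- filter_features(tab, filter_config())
  expect_equal(feature_ids(kept), "OTU2")
  # 10000 samples: ceil(0.005*10000) = 50 dominates the floor
  n <- 10000
  base <- matrix(1e-6, nrow = 2, ncol = n)
  base[1, 1:49] <- 0.01
  base[2, 1:50] <- 0.01
  kept <- filter_features(make_table(base), filter_config())
  expect_equal(feature_ids(kept), "OTU2")
})

test_that("feature filter matches a brute-force recount on random tables", {
  withr::with_seed(404, {
    for (rep in 1:20) {
      tab <- random_relative_table(12, sample(20:80, 1))
      cfg <- filter_config(otu_min_abundance = runif(1, 0.001, 0.1),
                           otu_min_sample_fraction = runif(1, 0.01, 0.3),
                           otu_min_samples_floor = sample(1:8, 1))
      kept <- feature_ids(suppressWarnings(filter_features(tab, cfg)))
      need <- max(cfg$otu_min_samples_floor,
                  ceiling(cfg$otu_min_sample_fraction * ncol(tab$values)))
      manual <- rownames(tab$values)[
        apply(tab$values, 1L, function(r) sum(r > cfg$otu_min_abundance)) >=
          need]
      expect_identical(kept, manual)
      # idempotent
      expect_identical(
        feature_ids(suppressWarnings(filter_features(
          suppressWarnings(filter_features(tab, cfg)), cfg))), kept)
    }
  })
})

test_that("groups partition exactly the features annotated at the rank", {
  lin <- parse_lineage_strings(c(
    a = "k__B; p__P; c__C; o__O; f__F; g__A",
    b = "k__B; p__P; c__C; o__O; f__F; g__A",
    c = "k__B; p__P; c__C; o__O; f__F; g__B",
    d = "k__B; p__P; c__C; o__O; f__F; g__"))
  groups <- build_groups(lin, "genus")
  expect_equal(lengths(groups), c(g__A = 2L, g__B = 1L))
  members <- unlist(groups, use.names = FALSE)
  expect_setequal(members, c("a", "b", "c"))   # unannotated 'd' in no group
  expect_false(anyDuplicated(members) > 0)
  expect_length(build_groups(lin[4, , drop = FALSE], "genus"), 0L)
})

test_that("group filter uses strict abundance and the override rule", {
  n <- 1000
  vals <- matrix(1e-6, nrow = 2, ncol = n)
  vals[1, 1:9] <- 0.01   # group g1 qualifies in 9 < 10 samples -> removed
  vals[2, 1:10] <- 0.01  # g2 qualifies in exactly 10 -> kept
  tab <- make_table(vals)
  groups <- structure(list(g1 = "OTU1", g2 = "OTU2"), rank = "genus")
  kept <- filter_groups(tab, groups, filter_config())
  expect_equal(names(kept), "g2")
  # override 200: qualifying in exactly 200 samples fails the strict ">"
  vals <- matrix(1e-6, nrow = 2, ncol = n)
  vals[1, 1:200] <- 0.01
  vals[2, 1:201] <- 0.01
  kept <- filter_groups(make_table(vals), groups,
                        filter_config(group_min_samples_override = 200))
  expect_equal(names(kept), "g2")
  # a single group spanning the whole table survives
  whole <- make_table(matrix(0.5, nrow = 2, ncol = 20))
  expect_equal(
    names(filter_groups(whole,
                        structure(list(g = c("OTU1", "OTU2")), rank = "genus"),
                        filter_config(group_min_samples_floor = 1))), "g")
})

test_that("taxonomy TSV and sample metadata readers enforce their contracts", {
  tax <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tk__B; p__P; c__C; o__O; f__F; g__X", "b\t"), tax)
  lin <- read_taxonomy_tsv(tax, c("a", "b", "c"))
  expect_equal(unname(lin["a", "genus"]), "g__X")
  expect_true(all(is.na(lin["c", ])))  # absent feature -> all NA
  md <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsubject_id\ttime_point", "S1\tp1\t1"), md)
  expect_equal(read_sample_metadata(md)$subject_id, "p1")
  writeLines(c("sample\tsubject_id", "S1\tp1"), md)
  expect_error(read_sample_metadata(md), "sample_id")
})
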