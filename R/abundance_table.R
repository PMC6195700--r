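#' Taxonomic ranks recognized by the package, deepest last
#'
#' Ordered from kingdom down to species. 16S OTU tables are typically
#' annotated down to genus; shotgun (MetaPhlAn-style) tables down to species.
#'
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

RANK_PREFIXES <- c(kingdom = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Construct a feature-by-sample abundance table
#'
#' The central container of the pipeline: a non-negative numeric matrix with
#' features as rows and samples as columns, tagged as raw counts or relative
#' abundances. Relative columns may sum to less than 1 (feature filtering
#' removes rows without renormalizing) but never to more than 1.
#'
#' @param values numeric matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param value_kind `"counts"` or `"relative"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, value_kind = c("counts", "relative")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(is.na(values)) || any(values < 0))
    stop("abundance values must be non-negative and non-missing")
  if (value_kind == "relative") {
    cs <- colSums(values)
    if (any(cs > 1 + 1e-6))
      stop("relative-abundance columns must sum to <= 1 (max sum ",
           format(max(cs)), ")")
  }
  structure(list(values = values, value_kind = value_kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (%s): %d features x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @rdname abundance_table
#' @param x an `abundance_table`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname abundance_table
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname abundance_table
#' @export
n_samples <- function(x) ncol(x$values)

is_counts <- function(x) x$value_kind == "counts"

#' Parse GreenGenes-style lineage strings
#'
#' Accepts semicolon-separated, rank-prefixed strings
#' (`"k__Bacteria; p__Firmicutes; ...; g__Blautia"`). A rank whose prefix has
#' an empty suffix, reads "unclassified", or is absent altogether is treated
#' as unannotated (`NA`); once a rank is unannotated, all deeper ranks are
#' forced to `NA` so no pseudo-groups are built from unknown lineages.
#'
#' @param strings character vector of lineage strings (may contain `NA` or
#'   empty strings, which yield all-`NA` lineages).
#' @param feature_ids ids used as rownames of the result.
#' @return data.frame with one row per feature and one column per rank in
#'   [TAXONOMIC_RANKS].
#' @export
parse_lineage_strings <- function(strings, feature_ids = names(strings)) {
  if (is.null(feature_ids)) feature_ids <- as.character(seq_along(strings))
  out <- matrix(NA_character_, nrow = length(strings),
                ncol = length(TAXONOMIC_RANKS),
                dimnames = list(feature_ids, TAXONOMIC_RANKS))
  for (i in seq_along(strings)) {
    s <- strings[[i]]
    if (is.na(s) || !nzchar(trimws(s))) next
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
    for (part in parts) {
      if (!nzchar(part)) next
      hit <- which(startsWith(part, RANK_PREFIXES))
      if (length(hit) != 1L)
        stop("unrecognized lineage segment '", part, "' in record '",
             feature_ids[i], "'")
      name <- substring(part, 4L)
      if (nzchar(name) && tolower(name) != "unclassified")
        out[i, names(RANK_PREFIXES)[hit]] <- part
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  enforce_lineage_cascade(df)
}

# once a rank is NA every deeper rank is NA
enforce_lineage_cascade <- function(lineage) {
  for (j in 2:length(TAXONOMIC_RANKS)) {
    lineage[is.na(lineage[[j - 1L]]), j] <- NA_character_
  }
  lineage
}

format_lineage_strings <- function(lineage, depth = "genus") {
  ranks <- TAXONOMIC_RANKS[seq_len(match(depth, TAXONOMIC_RANKS))]
  apply(lineage[, ranks, drop = FALSE], 1L, function(row) {
    row[is.na(row)] <- RANK_PREFIXES[ranks][is.na(row)]
    paste(row, collapse = "; ")
  })
}

#' Deepest rank with any annotation
#'
#' @param lineage lineage data.frame as produced by [parse_lineage_strings()].
#' @return rank name, e.g. `"genus"` for typical 16S tables.
#' @export
base_rank <- function(lineage) {
  annotated <- vapply(lineage, function(col) any(!is.na(col)), logical(1L))
  if (!any(annotated)) stop("no annotated rank in lineage table")
  TAXONOMIC_RANKS[max(which(annotated))]
}

#' Read an OTU table with taxonomy (BIOM or tab-separated)
#'
#' Files ending in `.biom` are read with the biomformat package (BIOM 1.0
#' JSON or 2.x HDF5, taxonomy taken from the observation metadata). Anything
#' else is parsed as the QIIME-classic tab-separated dialect: features as
#' rows, first column `#OTU ID`, optional trailing `taxonomy` column with
#' GreenGenes lineage strings; leading `#`-comment lines other than the
#' header are skipped. A separate 2-column taxonomy TSV
#' (feature id, lineage string) can be supplied instead via `taxonomy_path`.
#'
#' @param path path to the table.
#' @param taxonomy_path optional 2-column TSV overriding embedded taxonomy.
#' @return list with `table` (an `abundance_table` of counts) and `lineage`
#'   (data.frame per [parse_lineage_strings()]); features lacking taxonomy
#'   get an all-`NA` lineage.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    res <- read_biom_file(path)
  } else {
    res <- read_otu_tsv(path)
  }
  if (!is.null(taxonomy_path)) {
    res$lineage <- read_taxonomy_tsv(taxonomy_path, feature_ids(res$table))
  }
  res
}

read_biom_file <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading .biom files requires the biomformat package")
  b <- biomformat::read_biom(path)
  values <- as.matrix(biomformat::biom_data(b))
  storage.mode(values) <- "double"
  md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  tax <- rep(NA_character_, nrow(values))
  names(tax) <- rownames(values)
  if (!is.null(md)) {
    if (is.data.frame(md)) {
      tax_cols <- grep("taxonomy", colnames(md), ignore.case = TRUE)
      if (!length(tax_cols))  # column names are not preserved by all writers
        tax_cols <- which(vapply(md, function(col)
          any(grepl("^[kpcofgs]__", col)), logical(1L)))
      if (length(tax_cols))
        tax[rownames(md)] <- apply(md[, tax_cols, drop = FALSE], 1L,
                                   function(r) paste(r[!is.na(r)], collapse = "; "))
    } else if (is.list(md)) {
      for (id in names(md)) {
        v <- unlist(md[[id]])
        if (length(v)) tax[id] <- paste(v, collapse = "; ")
      }
    }
  }
  list(table = abundance_table(values, "counts"),
       lineage = parse_lineage_strings(tax, rownames(values)))
}

read_otu_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") | startsWith(lines, "#OTU ID")
  lines <- lines[keep]
  if (!length(lines)) stop("no table content in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "#OTU ID")
    stop("malformed table: first header field must be '#OTU ID', got '",
         header[1L], "'")
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  ncols <- length(header)
  body <- fields[-1L]
  bad <- which(lengths(body) != ncols)
  if (length(bad))
    stop("malformed record at data line ", bad[1L], ": expected ", ncols,
         " fields, found ", lengths(body)[bad[1L]])
  ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  val_cols <- 2:(ncols - if (has_tax) 1L else 0L)
  values <- t(vapply(body, function(f) {
    v <- suppressWarnings(as.numeric(f[val_cols]))
    if (any(is.na(v)))
      stop("malformed record '", f[[1L]], "': non-numeric abundance value")
    v
  }, numeric(length(val_cols))))
  dimnames(values) <- list(ids, header[val_cols])
  tax <- if (has_tax) vapply(body, `[[`, character(1L), ncols) else
    rep(NA_character_, length(ids))
  list(table = abundance_table(values, "counts"),
       lineage = parse_lineage_strings(stats::setNames(tax, ids)))
}

#' Write an OTU table in the tab-separated dialect
#'
#' Counterpart of [read_otu_table()]'s TSV branch; values are written at full
#' double precision so a write/read round trip reproduces them to 1e-12.
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @param lineage optional lineage data.frame; when given, a trailing
#'   `taxonomy` column with GreenGenes strings is emitted.
#' @param depth deepest rank to serialize in the taxonomy strings.
#' @export
write_otu_table <- function(table, path, lineage = NULL, depth = "genus") {
  header <- c("#OTU ID", sample_ids(table))
  if (!is.null(lineage)) header <- c(header, "taxonomy")
  rows <- vapply(seq_len(nrow(table$values)), function(i) {
    cells <- c(feature_ids(table)[i],
               format(table$values[i, ], digits = 17, trim = TRUE,
                      scientific = FALSE))
    if (!is.null(lineage))
      cells <- c(cells,
                 format_lineage_strings(lineage[feature_ids(table)[i], ,
                                                drop = FALSE], depth))
    paste(cells, collapse = "\t")
  }, character(1L))
  writeLines(c(paste(header, collapse = "\t"), rows), path)
}

#' Read a 2-column taxonomy TSV (feature id, lineage string)
#'
#' @param path path to the TSV (no header, or a header line starting `#`).
#' @param expected_ids feature ids the taxonomy must be aligned to; features
#'   absent from the file get all-`NA` lineages.
#' @return lineage data.frame aligned to `expected_ids`.
#' @export
read_taxonomy_tsv <- function(path, expected_ids) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("feature_id", "lineage"))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature id in taxonomy file: ",
         df$feature_id[duplicated(df$feature_id)][1L])
  strings <- stats::setNames(rep(NA_character_, length(expected_ids)),
                             expected_ids)
  hit <- intersect(df$feature_id, expected_ids)
  strings[hit] <- df$lineage[match(hit, df$feature_id)]
  parse_lineage_strings(strings, expected_ids)
}

#' Read a MetaPhlAn-style merged relative-abundance table
#'
#' First column holds clade paths with `|` rank separators
#' (`k__...|p__...|...|s__...`); remaining columns are per-sample relative
#' abundances in percent. Only rows at the deepest rank present (species, for
#' standard output) are retained as base features; intermediate-rank summary
#' rows are dropped. Percentages are converted to fractions.
#'
#' @param path path to the merged table (TSV, header row with sample ids).
#' @return list with `table` (an `abundance_table`, `value_kind = "relative"`)
#'   and `lineage`; feature ids are the terminal clade-path segments.
#' @export
read_metaphlan_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("metaphlan table needs a clade column plus samples")
  clade <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(is.na(vals))) stop("non-numeric abundance value in metaphlan table")
  if (any(vals < 0)) stop("negative abundance in metaphlan table")
  depth <- lengths(strsplit(clade, "|", fixed = TRUE))
  keep <- depth == max(depth)
  if (max(depth) < 2L || !any(keep)) stop("no base features in metaphlan table")
  clade <- clade[keep]
  vals <- vals[keep, , drop = FALSE]
  segs <- strsplit(clade, "|", fixed = TRUE)
  strings <- vapply(segs, paste, character(1L), collapse = "; ")
  ids <- vapply(segs, function(s) s[length(s)], character(1L))
  if (anyDuplicated(ids)) ids <- clade  # fall back to full path for uniqueness
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  lineage <- parse_lineage_strings(stats::setNames(strings, ids))
  # a clade path must not skip ranks: depth in the path = depth in the lineage
  parsed_depth <- rowSums(!is.na(lineage))
  if (any(parsed_depth != max(depth)))
    stop("inconsistent clade-path depth at record '",
         ids[which(parsed_depth != max(depth))[1L]], "'")
  dimnames(vals) <- list(ids, colnames(df)[-1L])
  list(table = abundance_table(vals / 100, "relative"), lineage = lineage)
}

#' Read a sample-metadata TSV
#'
#' @param path TSV with a header; required column `sample_id`, optional
#'   `subject_id`, `time_point`, `dataset`.
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(md))
    stop("sample metadata must contain a sample_id column")
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  md
}
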