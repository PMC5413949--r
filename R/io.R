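# Tabular input dialects (clonotype TSV, spectratype peak CSV) and result
# serialization (TSV matrices, annotated Newick trees).

clonotype_columns <- c("sample_id", "population", "v_gene", "j_gene",
                       "cdr3_nt", "cdr3_aa", "count")
spectratype_columns <- c("sample_id", "population", "trbv", "cdr3_length",
                         "area")

#' Read a clonotype count table
#'
#' Reads a TSV with one row per sample x clonotype and columns
#' \code{sample_id}, \code{population}, \code{v_gene}, \code{j_gene},
#' \code{cdr3_nt}, \code{cdr3_aa}, \code{count} (the dialect emitted by
#' V/J annotation pipelines and by \code{\link{simulate_repertoires}}).
#' Lines starting with \code{#} are comments. Duplicate
#' (sample, clonotype key) rows are merged by summing their counts, since
#' upstream annotators may emit per-read rows; the merge is reported.
#'
#' @param path TSV file path.
#' @param key_mode how a clonotype is keyed: \code{"v_cdr3_j"} (default;
#'   V gene + CDR3 nucleotide string + J gene), \code{"nt"} (CDR3 nucleotide
#'   string alone) or \code{"aa"} (CDR3 amino-acid string alone).
#' @return named list of \code{\link{repertoire}} objects, one per sample in
#'   order of first appearance, with the validated (merged) record table
#'   attached as attribute \code{"records"}.
#' @export
read_clonotype_table <- function(path, key_mode = c("v_cdr3_j", "nt", "aa")) {
  key_mode <- match.arg(key_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE)
  missing <- setdiff(clonotype_columns, names(df))
  if (length(missing) > 0L) {
    stop("format error: clonotype table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    stop("validation error: clonotype table has no data rows: ", path)
  }
  count <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(count) | count != round(count) | count <= 0)
  if (length(bad) > 0L) {
    stop("validation error: counts must be positive integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df$count <- count
  bad_nt <- which(df$cdr3_nt == "" | !grepl("^[ACGTacgt]+$", df$cdr3_nt))
  if (length(bad_nt) > 0L) {
    stop("validation error: cdr3_nt must be a non-empty A/C/G/T string; row(s): ",
         paste(utils::head(bad_nt, 5), collapse = ", "))
  }
  if (any(df$cdr3_aa == "")) {
    stop("validation error: cdr3_aa must be non-empty")
  }
  df$key <- switch(key_mode,
                   v_cdr3_j = paste(df$v_gene, df$cdr3_nt, df$j_gene, sep = "|"),
                   nt = df$cdr3_nt,
                   aa = df$cdr3_aa)
  dup <- duplicated(df[, c("sample_id", "key")])
  if (any(dup)) {
    message(sum(dup), " duplicate (sample, clonotype) row(s) merged by summing counts")
    agg <- stats::aggregate(count ~ sample_id + key, data = df, FUN = sum)
    meta <- df[!dup, c("sample_id", "population", "v_gene", "j_gene",
                       "cdr3_nt", "cdr3_aa", "key")]
    df <- merge(meta, agg, by = c("sample_id", "key"), sort = FALSE)
    df <- df[, c(clonotype_columns, "key")]
  }
  sample_order <- unique(df$sample_id)
  reps <- lapply(sample_order, function(sid) {
    sub <- df[df$sample_id == sid, , drop = FALSE]
    pop <- unique(sub$population)
    if (length(pop) > 1L) {
      stop("validation error: sample '", sid,
           "' is assigned to multiple populations: ",
           paste(pop, collapse = ", "))
    }
    repertoire(stats::setNames(sub$count, sub$key),
               sample_id = sid, population = pop)
  })
  names(reps) <- sample_order
  attr(reps, "records") <- df
  attr(reps, "key_mode") <- key_mode
  reps
}

#' Write a clonotype count table
#'
#' Writes the TSV dialect \code{\link{read_clonotype_table}} reads.
#'
#' @param records data frame with the clonotype table columns.
#' @param path output path.
#' @param header_comment optional character vector written as leading
#'   \code{#} comment lines (e.g. simulation provenance).
#' @export
write_clonotype_table <- function(records, path, header_comment = NULL) {
  missing <- setdiff(clonotype_columns, names(records))
  if (length(missing) > 0L) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(records[, clonotype_columns], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Read a spectratype peak table
#'
#' Reads a CSV of fluorescence peak areas with columns \code{sample_id},
#' \code{population}, \code{trbv}, \code{cdr3_length} (nucleotides) and
#' \code{area}. Rows for excluded segments are retained here: filtering is a
#' downstream, explicit step (\code{\link{apply_segment_exclusions}}).
#'
#' @param path CSV file path.
#' @param known_segments optional whitelist of TRBV labels; rows with other
#'   labels raise a warning but are kept.
#' @return data frame of peaks.
#' @export
read_spectratype_peaks <- function(path, known_segments = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing <- setdiff(spectratype_columns, names(df))
  if (length(missing) > 0L) {
    stop("format error: spectratype table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    stop("validation error: spectratype table has no data rows: ", path)
  }
  area <- suppressWarnings(as.numeric(df$area))
  bad <- which(is.na(area) | area < 0)
  if (length(bad) > 0L) {
    stop("validation error: peak areas must be non-negative numbers; row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  df$area <- area
  len <- suppressWarnings(as.numeric(df$cdr3_length))
  if (any(is.na(len) | len <= 0 | len != round(len))) {
    stop("validation error: cdr3_length must be a positive integer")
  }
  df$cdr3_length <- as.integer(len)
  dup <- duplicated(df[, c("sample_id", "trbv", "cdr3_length")])
  if (any(dup)) {
    stop("validation error: duplicate (sample, trbv, cdr3_length) row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  if (!is.null(known_segments)) {
    unknown <- setdiff(unique(df$trbv), known_segments)
    if (length(unknown) > 0L) {
      warning("unknown TRBV label(s) kept: ", paste(unknown, collapse = ", "))
    }
  }
  df
}

#' Write a spectratype peak table
#'
#' @param peaks data frame with the spectratype peak columns.
#' @param path output CSV path.
#' @param header_comment optional \code{#} comment lines.
#' @export
write_spectratype_peaks <- function(peaks, path, header_comment = NULL) {
  missing <- setdiff(spectratype_columns, names(peaks))
  if (length(missing) > 0L) {
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(peaks[, spectratype_columns], con, sep = ",",
                     quote = FALSE, row.names = FALSE)
}

fmt_num <- function(x, digits = 10) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf(paste0("%.", digits, "g"), v)
  }, character(1))
}

#' Newick string of a dendrogram
#'
#' Serializes an average-linkage merge tree to Newick using the ultrametric
#' convention: the branch length of a node equals half its parent's merge
#' height minus half its own (leaves sit at height 0), so all root-to-leaf
#' path lengths are equal. With \code{annotate = TRUE}, internal nodes carry
#' labels \code{"AU=..|BP=.."} with the cluster support values, when present.
#'
#' @param tree an \code{\link{average_linkage}} /
#'   \code{\link{multiscale_bootstrap_au}} dendrogram.
#' @param annotate write AU/BP internal node labels.
#' @return single Newick string (terminated by \code{";"}).
#' @export
newick_string <- function(tree, annotate = FALSE) {
  stopifnot(inherits(tree, "annotated_dendrogram"))
  merge <- tree$merge
  h <- tree$height
  if (any(h < 0)) stop("validation error: negative merge heights")
  labels <- tree$labels
  min_leaf <- function(m) {
    if (m < 0) labels[-m] else min(vapply(merge[m, ], min_leaf, character(1)))
  }
  build <- function(i) {
    parts <- character(2)
    firsts <- character(2)
    for (j in 1:2) {
      m <- merge[i, j]
      firsts[j] <- min_leaf(m)
      if (m < 0) {
        parts[j] <- paste0(labels[-m], ":", fmt_num(h[i] / 2))
      } else {
        parts[j] <- paste0(build(m), ":", fmt_num(h[i] / 2 - h[m] / 2))
      }
    }
    # children ordered by smallest leaf label for a canonical serialization
    parts <- parts[order(firsts, method = "radix")]
    lab <- ""
    if (annotate && !is.null(tree$au)) {
      lab <- paste0("AU=", fmt_num(tree$au[i], 4),
                    "|BP=", fmt_num(tree$bp[i], 4))
    }
    paste0("(", parts[1], ",", parts[2], ")", lab)
  }
  paste0(build(nrow(merge)), ";")
}

#' Write a dendrogram as Newick
#'
#' @inheritParams newick_string
#' @param path output file path.
#' @return the written string, invisibly.
#' @export
write_newick <- function(tree, path, annotate = FALSE) {
  s <- newick_string(tree, annotate = annotate)
  writeLines(s, path)
  invisible(s)
}

write_tsv_matrix <- function(m, path, rowname_header = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
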