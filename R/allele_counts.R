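#' Read a per-position allele-count table
#'
#' Allele-count tables are the assay's working currency: for every panel
#' position and sample, the number of reads supporting each nucleotide.
#' The TSV must have a header with columns `sample_id`, `gene`,
#' `coding_pos`, `ref`, `A`, `C`, `G`, `T`; depth is the sum of the four
#' counts, and an explicit `depth` column, if present, must equal that sum.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to a tab-separated file.
#' @param panel Optional [hotspot_panel()]; when given, every sample must
#'   cover every panel position exactly once and reference bases must
#'   match the panel.
#' @return A data frame of class `"allele_counts"` with columns
#'   `sample_id`, `gene`, `coding_pos`, `ref`, `A`, `C`, `G`, `T`, `depth`.
#' @export
read_allele_counts <- function(path, panel = NULL) {
  x <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("sample_id", "gene", "coding_pos", "ref", "A", "C", "G", "T")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("allele-count file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_depth <- "depth" %in% names(x)
  x <- x[, c(needed, if (has_depth) "depth")]
  x$coding_pos <- as.integer(x$coding_pos)
  as_allele_counts(x, panel = panel, check_depth = has_depth)
}

#' Validate a data frame of allele counts
#'
#' @param x Data frame with the columns described in
#'   [read_allele_counts()]; `depth` is derived when absent.
#' @param panel Optional panel for completeness checking.
#' @param check_depth If `TRUE` and a `depth` column is present, verify it
#'   equals the sum of the four nucleotide counts.
#' @return The validated table, classed `"allele_counts"`.
#' @export
as_allele_counts <- function(x, panel = NULL, check_depth = TRUE) {
  counts <- as.matrix(x[, c("A", "C", "G", "T")])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("nucleotide counts must be non-negative integers", call. = FALSE)
  }
  sums <- rowSums(counts)
  if ("depth" %in% names(x)) {
    if (check_depth && any(x$depth != sums)) {
      bad <- which(x$depth != sums)[1]
      stop("depth does not equal the sum of nucleotide counts at ",
           x$gene[bad], " position ", x$coding_pos[bad],
           " (depth ", x$depth[bad], ", sum ", sums[bad], ")",
           call. = FALSE)
    }
  }
  x$depth <- sums
  if (!is.null(panel)) {
    for (s in unique(x$sample_id)) {
      xs <- x[x$sample_id == s, ]
      key <- site_key(xs$gene, xs$coding_pos)
      pkey <- site_key(panel$gene, panel$coding_pos)
      absent <- setdiff(pkey, key)
      if (length(absent)) {
        stop("sample ", s, " is missing panel position(s): ",
             paste(absent, collapse = ", "), call. = FALSE)
      }
      if (anyDuplicated(key)) {
        stop("sample ", s, " has duplicated position(s): ",
             paste(unique(key[duplicated(key)]), collapse = ", "),
             call. = FALSE)
      }
      ref <- panel$ref[match(key, pkey)]
      if (any(xs$ref != ref)) {
        stop("sample ", s, " reference base disagrees with the panel at ",
             paste(key[xs$ref != ref], collapse = ", "), call. = FALSE)
      }
    }
  }
  rownames(x) <- NULL
  class(x) <- c("allele_counts", "data.frame")
  x
}

#' Write an allele-count table to TSV
#'
#' Inverse of [read_allele_counts()]: the written file reads back to an
#' identical table.
#'
#' @param x An `"allele_counts"` data frame.
#' @param path Output path.
#' @export
write_allele_counts <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("Allele counts:", length(unique(x$sample_id)), "sample(s),",
      nrow(x), "rows; median depth", stats::median(x$depth), "\n")
  print(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Split a multi-sample allele-count table into per-sample tables
#'
#' @param x An `"allele_counts"` data frame.
#' @return Named list of single-sample tables.
#' @export
split_samples <- function(x) {
  lapply(split(as.data.frame(x), x$sample_id),
         function(d) as_allele_counts(d, check_depth = FALSE))
}
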