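#' 2x2 inter-assay contingency table
#'
#' Cross-classification of per-sample binary calls from a test assay
#' against a comparator: `a` both positive, `b` test-positive only,
#' `c` comparator-positive only, `d` both negative.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return An object of class `"contingency_2x2"`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  m <- matrix(as.integer(cells), 2, 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              comparator = c("positive", "negative")))
  structure(m, class = c("contingency_2x2", class(m)))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(unclass(x), ...)
  if (sum(x) > 0) {
    cat(sprintf("agreement %.1f%%, kappa %.3f\n",
                percent_agreement(x), round(cohen_kappa(x), 3)))
  }
  invisible(x)
}

cells_2x2 <- function(t) {
  list(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2], n = sum(t))
}

#' Build a contingency table from per-sample calls
#'
#' @param test_calls,comparator_calls Logical vectors named by sample id;
#'   the two sample sets must be identical.
#' @return A [contingency_2x2()].
#' @export
build_contingency <- function(test_calls, comparator_calls) {
  if (is.null(names(test_calls)) || is.null(names(comparator_calls)) ||
      !setequal(names(test_calls), names(comparator_calls)) ||
      length(test_calls) == 0L ||
      length(test_calls) != length(comparator_calls)) {
    stop("test and comparator calls must cover the same non-empty sample set",
         call. = FALSE)
  }
  comp <- comparator_calls[names(test_calls)]
  contingency_2x2(sum(test_calls & comp), sum(test_calls & !comp),
                  sum(!test_calls & comp), sum(!test_calls & !comp))
}

#' Overall percent agreement
#'
#' @param t A [contingency_2x2()].
#' @return `100 * (a + d) / n`.
#' @export
percent_agreement <- function(t) {
  x <- cells_2x2(t)
  if (x$n == 0) stop("empty contingency table", call. = FALSE)
  100 * (x$a + x$d) / x$n
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o = (a + d)/n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. Degenerate margins
#' (`p_e = 1`) give `NA` with a warning.
#'
#' @param t A [contingency_2x2()].
#' @return Kappa at full precision (display rounding is the caller's job).
#' @export
cohen_kappa <- function(t) {
  x <- cells_2x2(t)
  if (x$n == 0) stop("empty contingency table", call. = FALSE)
  p_o <- (x$a + x$d) / x$n
  p_e <- ((x$a + x$b) * (x$a + x$c) + (x$c + x$d) * (x$b + x$d)) / x$n^2
  if (p_e >= 1) {
    warning("degenerate margins: chance agreement is 1, kappa undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' False-positive and false-negative rates against a comparator
#'
#' Treating the comparator as reference: the false-positive rate is the
#' share of comparator-negative samples the test calls positive,
#' `100 * b / (b + d)`; the false-negative rate is the share of
#' comparator-positive samples the test misses, `100 * c / (a + c)`.
#' A zero comparator margin yields `NA` for that rate with a warning.
#'
#' @param t A [contingency_2x2()].
#' @return Named numeric vector `c(fp = , fn = )`, in percent.
#' @export
discordance_rates <- function(t) {
  x <- cells_2x2(t)
  fp <- if (x$b + x$d > 0) 100 * x$b / (x$b + x$d) else {
    warning("no comparator-negative samples; FP rate undefined",
            call. = FALSE)
    NA_real_
  }
  fn <- if (x$a + x$c > 0) 100 * x$c / (x$a + x$c) else {
    warning("no comparator-positive samples; FN rate undefined",
            call. = FALSE)
    NA_real_
  }
  c(fp = fp, fn = fn)
}

#' Paired tumor/plasma concordance summary
#'
#' Compares the variant sets found in matched tumor-tissue and plasma
#' samples, per sample and gene. Each pair is categorised as
#' `both_empty`, `identical`, `overlapping` (shared and unshared
#' variants), `one_sided` (variants in only one material) or `disjoint`
#' (variants in both, none shared).
#'
#' @param pairs Data frame with columns `sample_id`, `gene`, `tumor`,
#'   `plasma`; the last two are comma-separated variant labels (empty
#'   string for none), e.g. from [read_paired_manifest()].
#' @return Data frame of class `"paired_concordance"` with a `category`
#'   column; the per-category count table is in `attr(, "summary")`.
#' @export
paired_concordance <- function(pairs) {
  stopifnot(all(c("sample_id", "gene", "tumor", "plasma") %in% names(pairs)))
  split_set <- function(s) {
    s <- trimws(strsplit(ifelse(is.na(s), "", s), ",")[[1]])
    s[nzchar(s)]
  }
  cat_one <- function(tu, pl) {
    if (!length(tu) && !length(pl)) return("both_empty")
    if (!length(tu) || !length(pl)) return("one_sided")
    shared <- intersect(tu, pl)
    if (setequal(tu, pl)) "identical"
    else if (length(shared)) "overlapping"
    else "disjoint"
  }
  pairs$category <- vapply(seq_len(nrow(pairs)), function(i) {
    cat_one(split_set(pairs$tumor[i]), split_set(pairs$plasma[i]))
  }, character(1))
  tab <- table(factor(pairs$category,
                      levels = c("both_empty", "identical", "overlapping",
                                 "one_sided", "disjoint")))
  structure(pairs, summary = tab,
            class = c("paired_concordance", "data.frame"))
}

#' @export
print.paired_concordance <- function(x, ...) {
  cat("Paired tumor/plasma concordance,", nrow(x), "sample-gene pairs\n")
  print(attr(x, "summary"))
  inform <- x[x$category != "both_empty", ]
  if (nrow(inform)) {
    print(as.data.frame(inform[, c("sample_id", "gene", "tumor", "plasma",
                                   "category")]),
          row.names = FALSE, ...)
  }
  invisible(x)
}

#' Pair tumor and plasma call sets into a manifest
#'
#' Builds the [paired_concordance()] input from two lists of `"call_set"`
#' results (see [call_sample()]); variants are the protein labels of
#' positive calls. Samples present in only one material are excluded with
#' a warning.
#'
#' @param tumor_calls,plasma_calls Named lists of call sets (names are
#'   sample ids), e.g. from [predict.error_model()].
#' @return Data frame with columns `sample_id`, `gene`, `tumor`, `plasma`.
#' @export
pair_call_sets <- function(tumor_calls, plasma_calls) {
  common <- intersect(names(tumor_calls), names(plasma_calls))
  dropped <- setdiff(union(names(tumor_calls), names(plasma_calls)), common)
  if (length(dropped)) {
    warning("unpaired sample(s) excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(common)) stop("no paired samples", call. = FALSE)
  genes <- unique(unlist(lapply(tumor_calls[common],
                                function(x) unique(x$gene))))
  variants <- function(calls, g) {
    p <- calls[calls$status == "positive" & calls$gene == g, ]
    paste(p$protein, collapse = ",")
  }
  do.call(rbind, lapply(common, function(s) {
    data.frame(
      sample_id = s, gene = genes,
      tumor = vapply(genes, function(g) variants(tumor_calls[[s]], g), ""),
      plasma = vapply(genes, function(g) variants(plasma_calls[[s]], g), ""),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}

#' Read a paired tumor/plasma variant manifest
#'
#' TSV with columns `sample_id`, `gene`, `tumor`, `plasma` (comma-separated
#' protein-level variant labels, empty for none); each row is one
#' sample-gene pair with both materials.
#'
#' @param path Path to the TSV.
#' @return A data frame suitable for [paired_concordance()].
#' @export
read_paired_manifest <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("sample_id", "gene", "tumor", "plasma")
  if (length(setdiff(needed, names(x)))) {
    stop("manifest needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  x[, needed]
}
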