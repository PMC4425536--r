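#' A labelled sample for threshold tuning
#'
#' Pairs an allele-count table with its known mutation content: the set of
#' (position, alternate) channels truly mutated (empty for a known
#' negative). An optional `ignore` set lists channels whose calls should
#' not count either way (e.g. a bona fide variant outside the labelled
#' target region found in a "negative" sample).
#'
#' @param table A single-sample `"allele_counts"` table.
#' @param truth Data frame with columns `gene`, `coding_pos`, `alt`
#'   (zero rows for a known negative).
#' @param ignore Optional data frame with the same columns.
#' @return A list of class `"labeled_sample"`.
#' @export
labeled_sample <- function(table, truth = empty_truth(), ignore = empty_truth()) {
  stopifnot(all(c("gene", "coding_pos", "alt") %in% names(truth)),
            all(c("gene", "coding_pos", "alt") %in% names(ignore)))
  if (anyDuplicated(truth[, c("gene", "coding_pos", "alt")])) {
    stop("duplicated (position, alt) in truth", call. = FALSE)
  }
  structure(list(table = as_allele_counts(table, check_depth = FALSE),
                 truth = truth, ignore = ignore),
            class = "labeled_sample")
}

#' @rdname labeled_sample
#' @export
empty_truth <- function() {
  data.frame(gene = character(), coding_pos = integer(), alt = character(),
             stringsAsFactors = FALSE)
}

channel_id <- function(d) paste(d$gene, d$coding_pos, d$alt)

#' Sweep the SD multiplier on labelled samples
#'
#' Recreates the assay's cut-off calibration: call every labelled sample
#' at each SD multiplier `k` (null error rate `mean + k * SD`) and
#' cross-classify calls against the labels. A truth channel called
#' positive is a true positive; a truth channel not called is a false
#' negative; any other positive call at an evaluable channel is a false
#' positive (channels in a sample's `ignore` set are skipped). A sample is
#' "correct" when all its truth channels are recovered and it has no
#' false positive.
#'
#' @param labeled List of [labeled_sample()] objects.
#' @param model An [error_model()] fit.
#' @param alpha Significance level (default `2e-5`).
#' @param k_values SD multipliers to try (default `0:7`).
#' @param min_depth Passed to [caller_config()].
#' @return Data frame of class `"k_sweep"`: one row per `k` with `tp`,
#'   `fn`, `fp`, `n_correct_samples`, `n_samples`, `n_truth`.
#' @export
sweep_k <- function(labeled, model, alpha = 2e-5, k_values = 0:7,
                    min_depth = 1000) {
  stopifnot(length(k_values) >= 1, length(labeled) >= 1)
  n_truth <- sum(vapply(labeled, function(l) nrow(l$truth), integer(1)))
  rows <- lapply(k_values, function(k) {
    cfg <- caller_config(alpha = alpha, k_sd = k, min_depth = min_depth)
    per_sample <- vapply(labeled, function(l) {
      calls <- call_sample(l$table, model, cfg)
      pos <- calls[calls$status == "positive", ]
      pos_id <- channel_id(pos)
      truth_id <- channel_id(l$truth)
      ignore_id <- channel_id(l$ignore)
      tp <- sum(truth_id %in% pos_id)
      fn <- length(truth_id) - tp
      fp <- sum(!pos_id %in% c(truth_id, ignore_id))
      c(tp = tp, fn = fn, fp = fp, correct = as.integer(fn == 0 && fp == 0))
    }, numeric(4))
    data.frame(k = k, tp = sum(per_sample["tp", ]),
               fn = sum(per_sample["fn", ]), fp = sum(per_sample["fp", ]),
               n_correct_samples = sum(per_sample["correct", ]),
               n_samples = length(labeled), n_truth = n_truth)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("k_sweep", "data.frame")
  out
}

#' @export
print.k_sweep <- function(x, ...) {
  cat("SD-multiplier sweep over", nrow(x), "values of k;",
      x$n_samples[1], "labelled samples,", x$n_truth[1],
      "truth channels\n")
  print(as.data.frame(x[, c("k", "tp", "fn", "fp", "n_correct_samples")]),
        row.names = FALSE, ...)
  invisible(x)
}

#' @method plot k_sweep
#' @export
plot.k_sweep <- function(x, ...) {
  graphics::matplot(x$k, cbind(x$tp, x$fp), type = "b", pch = c(19, 17),
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "SD multiplier k", ylab = "channel calls", ...)
  graphics::legend("topright", legend = c("true positives", "false positives"),
                   col = c("steelblue", "firebrick"), pch = c(19, 17), lty = 1)
  invisible(x)
}

#' Select the SD multiplier from a sweep
#'
#' The chosen `k` is the smallest value with zero false positives and
#' full truth recovery. If no swept value qualifies, the fall-back is the
#' `k` maximising truth recovery, ties broken by fewer false positives
#' then smaller `k`, and the result carries a warning flag.
#'
#' @param summary A [sweep_k()] result.
#' @return A list of class `"k_selection"`: `k`, `fully_correct` (logical),
#'   and the selected summary `row`.
#' @export
select_k <- function(summary) {
  if (!nrow(summary)) stop("empty sweep summary", call. = FALSE)
  ok <- summary$fp == 0 & summary$fn == 0
  if (any(ok)) {
    row <- summary[which(ok)[which.min(summary$k[ok])], ]
    fully <- TRUE
  } else {
    o <- order(-summary$tp, summary$fp, summary$k)
    row <- summary[o[1], ]
    fully <- FALSE
    warning("no swept k classifies every labelled sample correctly; ",
            "falling back to k = ", row$k, call. = FALSE)
  }
  structure(list(k = row$k, fully_correct = fully, row = row),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Selected SD multiplier k =", x$k,
      if (x$fully_correct) "(all labelled samples classified correctly)"
      else "(FALLBACK: no k was fully correct)", "\n")
  invisible(x)
}
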