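#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lam)`; the tail probability of observing
#' at least `k` non-reference reads when the background error process
#' alone would produce `lam` on average. `P(X >= 0)` is 1 by convention.
#'
#' @param k Non-negative integer count(s).
#' @param lam Non-negative Poisson mean(s).
#' @return Tail probabilities in `[0, 1]`, recycled to the common length.
#' @export
poisson_upper_tail <- function(k, lam) {
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  if (any(lam < 0)) stop("lam must be non-negative", call. = FALSE)
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' Minimum count declared mutation-positive
#'
#' The smallest integer `k` whose upper-tail Poisson probability under the
#' null expectation `lam` falls below `alpha` — the mutant detection limit
#' in reads: any observed non-reference count at or above it is called
#' positive.
#'
#' @param lam Non-negative Poisson mean(s).
#' @param alpha Significance level in (0, 1); default `2e-5`.
#' @return Integer count(s), always `>= 1`.
#' @examples
#' min_positive_count(0)    # 1: any mutant read is impossible under the null
#' min_positive_count(1)    # 8
#' @export
min_positive_count <- function(lam, alpha = 2e-5) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(lam < 0)) stop("lam must be non-negative", call. = FALSE)
  vapply(lam, function(l) {
    k <- stats::qpois(alpha, l, lower.tail = FALSE)
    while (poisson_upper_tail(k, l) >= alpha) k <- k + 1
    while (k > 1 && poisson_upper_tail(k - 1, l) < alpha) k <- k - 1
    as.integer(k)
  }, integer(1))
}

#' Caller configuration
#'
#' @param alpha Per-position significance level for the Poisson tail test
#'   (default `2e-5`).
#' @param k_sd Standard-deviation multiplier: the null error rate is
#'   `mean_rate + k_sd * sd` (default 7, the value selected by the
#'   labelled-sample sweep; see [sweep_k()]).
#' @param min_depth Minimum depth for a position to be evaluable
#'   (default 1000).
#' @param adjust Optional multiple-testing adjustment across the panel's
#'   evaluable channels: `"none"` (default, alpha is per position) or
#'   `"bonferroni"`.
#' @return A list of class `"caller_config"`.
#' @export
caller_config <- function(alpha = 2e-5, k_sd = 7, min_depth = 1000,
                          adjust = c("none", "bonferroni")) {
  stopifnot(alpha > 0, alpha < 1, k_sd >= 0, min_depth >= 1)
  adjust <- match.arg(adjust)
  structure(list(alpha = alpha, k_sd = k_sd, min_depth = min_depth,
                 adjust = adjust),
            class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat(sprintf(
    "Caller config: alpha = %g, lambda rate = mean ER + %g SD, min depth = %d%s\n",
    x$alpha, x$k_sd, x$min_depth,
    if (x$adjust != "none") paste0(", adjust = ", x$adjust) else ""))
  invisible(x)
}

effective_alpha <- function(config, model) {
  if (config$adjust == "bonferroni") {
    n_channels <- 3L * sum(model$site_rates$evaluable)
    config$alpha / max(n_channels, 1L)
  } else {
    config$alpha
  }
}

#' Call mutations in one sample against a fitted error model
#'
#' For every evaluable panel position and alternate nucleotide, the null
#' expectation is `lambda = (mean_rate + k_sd * sd) * depth`, using the
#' channel-specific error rate and the sample's own depth at that
#' position. The channel is called positive when the upper-tail Poisson
#' probability of the observed count is below `alpha`. Positions excluded
#' by the model or with depth below `min_depth` are `not_evaluable`.
#'
#' @param table A single-sample `"allele_counts"` table covering the
#'   model's panel.
#' @param model An [error_model()] fit.
#' @param config A [caller_config()].
#' @return A data frame of class `"call_set"`, one row per position and
#'   alternate: observed count, depth, `vaf`, `lambda`, `tail_prob`,
#'   `status` (`positive` / `negative` / `not_evaluable`) and the coding
#'   and protein annotations.
#' @export
call_sample <- function(table, model, config = caller_config()) {
  table <- as_allele_counts(table, panel = model$panel)
  if (length(unique(table$sample_id)) != 1L) {
    stop("call_sample expects a single-sample table; see split_samples()",
         call. = FALSE)
  }
  a <- model$alt_rates
  s <- model$site_rates
  skey <- site_key(s$gene, s$coding_pos)
  akey <- site_key(a$gene, a$coding_pos)
  tkey <- site_key(table$gene, table$coding_pos)
  ti <- match(akey, tkey)
  if (anyNA(ti)) {
    stop("sample does not cover model position(s): ",
         paste(unique(akey[is.na(ti)]), collapse = ", "), call. = FALSE)
  }
  depth <- table$depth[ti]
  count <- as.matrix(table[, c("A", "C", "G", "T")])[cbind(ti, match(a$alt, c("A", "C", "G", "T")))]
  rate0 <- pmin(a$mean_rate + config$k_sd * a$sd, 1)
  lambda <- rate0 * depth
  tail_prob <- poisson_upper_tail(count, lambda)
  evaluable <- s$evaluable[match(akey, skey)] & depth >= config$min_depth
  alpha <- effective_alpha(config, model)
  status <- ifelse(!evaluable, "not_evaluable",
                   ifelse(tail_prob < alpha, "positive", "negative"))

  panel_i <- match(akey, site_key(model$panel$gene, model$panel$coding_pos))
  ann <- annotate_variant(model$panel[panel_i, ], a$alt)
  out <- data.frame(
    sample_id = table$sample_id[1], gene = a$gene,
    coding_pos = a$coding_pos, ref = a$ref, alt = a$alt,
    count = count, depth = depth, vaf = ifelse(depth > 0, count / depth, 0),
    null_rate = rate0, lambda = lambda, tail_prob = tail_prob,
    status = status, cdna = ann$cdna, protein = ann$protein,
    stringsAsFactors = FALSE
  )
  class(out) <- c("call_set", "data.frame")
  out
}

#' @rdname call_sample
#' @param gene,coding_pos Position to call (single position); `table` must
#'   contain it.
#' @export
call_site <- function(table, gene, coding_pos, model,
                      config = caller_config()) {
  calls <- call_sample(table, model, config)
  out <- calls[calls$gene == gene & calls$coding_pos == coding_pos, ]
  if (!nrow(out)) {
    stop("position ", gene, " ", coding_pos, " is not in the model",
         call. = FALSE)
  }
  out
}

#' Positive calls from a call set
#'
#' @param calls A `"call_set"` (or a list of them).
#' @return The subset with `status == "positive"`.
#' @export
positive_calls <- function(calls) {
  if (!is.data.frame(calls)) calls <- do.call(rbind, calls)
  calls[calls$status == "positive", ]
}

#' @export
print.call_set <- function(x, ...) {
  pos <- x[x$status == "positive", ]
  cat("Calls for sample", x$sample_id[1], "-",
      sum(x$status == "positive"), "positive,",
      sum(x$status == "negative"), "negative,",
      sum(x$status == "not_evaluable"), "not evaluable channels\n")
  if (nrow(pos)) {
    print(as.data.frame(pos[, c("gene", "cdna", "protein", "count", "depth",
                                "vaf", "lambda", "tail_prob")]),
          digits = 4, row.names = FALSE)
  } else {
    cat("No mutation detected\n")
  }
  invisible(x)
}

#' Run the caller on new data
#'
#' `predict()` on a fitted error model applies the Poisson caller to one
#' or more samples.
#'
#' @param object An [error_model()] fit.
#' @param newdata An `"allele_counts"` table (one or more samples) or a
#'   list of single-sample tables.
#' @param config A [caller_config()].
#' @param ... Unused.
#' @return A single `"call_set"` for one sample; otherwise a named list of
#'   call sets.
#' @export
predict.error_model <- function(object, newdata, config = caller_config(),
                                ...) {
  if (is.data.frame(newdata)) {
    samples <- split_samples(as_allele_counts(newdata, check_depth = FALSE))
  } else {
    samples <- newdata
  }
  out <- lapply(samples, call_sample, model = object, config = config)
  if (length(out) == 1L) out[[1]] else out
}

#' Write a call report to TSV
#'
#' @param calls A `"call_set"` or list of call sets.
#' @param path Output path.
#' @param positives_only Write only positive calls (default `FALSE`).
#' @export
write_call_report <- function(calls, path, positives_only = FALSE) {
  if (!is.data.frame(calls)) calls <- do.call(rbind, calls)
  if (positives_only) calls <- calls[calls$status == "positive", ]
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
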