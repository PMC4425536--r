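#' Fit a per-position background error model from normal samples
#'
#' Sequencing and PCR introduce a small, position-specific background of
#' non-reference reads even in mutation-free DNA. This function estimates
#' that background from a cohort of normal samples: for every panel
#' position and alternate nucleotide, the per-sample error rate is the
#' alternate count divided by depth; the model records the across-sample
#' mean and standard deviation (n - 1 denominator) of that rate. The
#' per-position aggregate error rate (total non-reference count divided by
#' depth, averaged across samples) drives exclusion of systematically
#' noisy positions: any position whose aggregate mean exceeds
#' `exclude_threshold` is marked non-evaluable, in addition to positions
#' already excluded in the panel.
#'
#' The fitted object is the package's central model: [predict.error_model()]
#' runs the Poisson caller on new allele-count tables and
#' [simulate.error_model()] draws synthetic cohorts from the fitted rates.
#'
#' @param normals A list of single-sample `"allele_counts"` tables, or one
#'   multi-sample table; at least two samples (the standard deviation is
#'   undefined otherwise).
#' @param panel A [hotspot_panel()].
#' @param exclude_threshold Aggregate error rate above which a position is
#'   excluded from evaluation (default 0.01).
#' @return An object of class `"error_model"`: a list with `alt_rates`
#'   (per position and alternate: `mean_rate`, `sd`), `site_rates` (per
#'   position: `aggregate_rate`, `aggregate_sd`, `evaluable`), `panel`,
#'   `n_samples`, `exclude_threshold`.
#' @examples
#' panel <- hotspot_panel()
#' prof <- simulation_profile(panel, seed = 1)
#' normals <- generate_normal_cohort(10, prof)
#' fit <- error_model(normals, panel)
#' fit
#' coef(fit)[1:5, ]
#' @export
error_model <- function(normals, panel = hotspot_panel(),
                        exclude_threshold = 0.01) {
  if (is.data.frame(normals)) normals <- split_samples(normals)
  normals <- lapply(normals, as_allele_counts, panel = panel)
  n <- length(normals)
  if (n < 2L) {
    stop("at least 2 normal samples are required (SD is undefined for n < 2)",
         call. = FALSE)
  }
  pkey <- site_key(panel$gene, panel$coding_pos)

  # site x sample matrices of depth and per-alt counts, panel order
  depth <- sapply(normals, function(s) {
    s$depth[match(pkey, site_key(s$gene, s$coding_pos))]
  })
  cnt <- lapply(c("A", "C", "G", "T"), function(b) {
    sapply(normals, function(s) {
      s[[b]][match(pkey, site_key(s$gene, s$coding_pos))]
    })
  })
  names(cnt) <- c("A", "C", "G", "T")

  zero_depth <- rowSums(depth == 0) > 0
  if (any(zero_depth)) {
    warning("position(s) with zero depth in at least one normal sample ",
            "marked non-evaluable: ",
            paste(panel$label[zero_depth], collapse = ", "), call. = FALSE)
  }
  safe_depth <- ifelse(depth == 0, NA_real_, depth)

  alt_rows <- lapply(seq_len(nrow(panel)), function(i) {
    alts <- setdiff(c("A", "C", "G", "T"), panel$ref[i])
    rates <- vapply(alts, function(b) cnt[[b]][i, ] / safe_depth[i, ],
                    numeric(n))
    data.frame(
      gene = panel$gene[i], coding_pos = panel$coding_pos[i],
      ref = panel$ref[i], alt = alts,
      mean_rate = colMeans(rates, na.rm = TRUE),
      sd = apply(rates, 2, stats::sd, na.rm = TRUE),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  alt_rates <- do.call(rbind, alt_rows)
  alt_rates$mean_rate[is.nan(alt_rates$mean_rate)] <- NA_real_

  ref_cnt <- t(vapply(seq_len(nrow(panel)), function(i) {
    cnt[[panel$ref[i]]][i, ]
  }, numeric(n)))
  agg <- (depth - ref_cnt) / safe_depth
  site_rates <- data.frame(
    gene = panel$gene, coding_pos = panel$coding_pos, ref = panel$ref,
    label = panel$label,
    aggregate_rate = rowMeans(agg, na.rm = TRUE),
    aggregate_sd = apply(agg, 1, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  site_rates$aggregate_rate[is.nan(site_rates$aggregate_rate)] <- NA_real_
  site_rates$evaluable <- panel$evaluable & !zero_depth &
    !is.na(site_rates$aggregate_rate) &
    site_rates$aggregate_rate <= exclude_threshold

  structure(
    list(alt_rates = alt_rates, site_rates = site_rates, panel = panel,
         n_samples = n, exclude_threshold = exclude_threshold,
         call = match.call()),
    class = "error_model"
  )
}

#' Positions whose aggregate error rate exceeds a threshold
#'
#' @param model An [error_model()] fit.
#' @param threshold Aggregate error rate cut-off in (0, 1); defaults to
#'   the model's `exclude_threshold`.
#' @return The flagged subset of `model$site_rates`, sorted by aggregate
#'   rate, highest first.
#' @export
flag_high_error_sites <- function(model, threshold = model$exclude_threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  s <- model$site_rates
  flagged <- s[!is.na(s$aggregate_rate) & s$aggregate_rate > threshold, ]
  flagged[order(-flagged$aggregate_rate), ]
}

#' @export
print.error_model <- function(x, ...) {
  cat("Per-position background error model\n")
  cat("  normal samples:", x$n_samples, "\n")
  cat("  positions:", nrow(x$site_rates),
      sprintf("(evaluable: %d)", sum(x$site_rates$evaluable)), "\n")
  ev <- x$site_rates$aggregate_rate[x$site_rates$evaluable]
  if (length(ev)) {
    cat(sprintf("  aggregate error rate over evaluable positions: %.4g-%.4g\n",
                min(ev), max(ev)))
  }
  excl <- x$site_rates[!x$site_rates$evaluable, ]
  if (nrow(excl)) {
    cat("  non-evaluable:",
        paste(sprintf("%s (%.4f)", excl$label, excl$aggregate_rate),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @method summary error_model
#' @export
summary.error_model <- function(object, ...) {
  out <- object$site_rates
  out$n_samples <- object$n_samples
  class(out) <- c("summary.error_model", "data.frame")
  out
}

#' @export
print.summary.error_model <- function(x, ...) {
  cat("Aggregate per-position error rates from", x$n_samples[1],
      "normal samples\n")
  print(as.data.frame(x[, c("label", "aggregate_rate", "aggregate_sd",
                            "evaluable")]),
        digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Extract mean per-channel error rates
#'
#' @param object An [error_model()] fit.
#' @param ... Unused.
#' @return The `alt_rates` data frame (position, alternate, mean rate, SD).
#' @method coef error_model
#' @export
coef.error_model <- function(object, ...) object$alt_rates

#' Plot the per-position aggregate error profile
#'
#' Bar chart of aggregate error rate per position (log scale), with
#' across-sample SD whiskers; non-evaluable positions in red, the
#' exclusion threshold as a dashed line.
#'
#' @param x An [error_model()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @method plot error_model
#' @export
plot.error_model <- function(x, ...) {
  s <- x$site_rates
  rate <- pmax(s$aggregate_rate, 1e-6)
  bp <- graphics::barplot(rate, names.arg = s$label, las = 2, log = "y",
                          col = ifelse(s$evaluable, "grey70", "firebrick"),
                          ylab = "aggregate error rate",
                          cex.names = 0.55, ...)
  graphics::segments(bp, rate, bp, pmax(rate + s$aggregate_sd, 1e-6))
  graphics::abline(h = x$exclude_threshold, lty = 2)
  invisible(x)
}

#' Write / read an error model as TSV
#'
#' One row per position and alternate nucleotide; aggregate columns are
#' repeated within a position. `read_error_model()` restores a fitted
#' object usable by the caller.
#'
#' @param model An [error_model()] fit.
#' @param path File path.
#' @export
write_error_model <- function(model, path) {
  a <- model$alt_rates
  s <- model$site_rates
  i <- match(site_key(a$gene, a$coding_pos), site_key(s$gene, s$coding_pos))
  out <- cbind(a, s[i, c("aggregate_rate", "aggregate_sd", "evaluable")])
  out$n_samples <- model$n_samples
  out$exclude_threshold <- model$exclude_threshold
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_model
#' @param panel Panel to attach; defaults to [hotspot_panel()].
#' @export
read_error_model <- function(path, panel = hotspot_panel()) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  keep <- c("gene", "coding_pos", "ref", "alt", "mean_rate", "sd")
  if (length(setdiff(keep, names(x)))) {
    stop("not an error-model file: ", path, call. = FALSE)
  }
  first <- !duplicated(site_key(x$gene, x$coding_pos))
  site_rates <- data.frame(
    gene = x$gene[first], coding_pos = x$coding_pos[first],
    ref = x$ref[first],
    label = sprintf("%s %d%s", x$gene[first], x$coding_pos[first],
                    x$ref[first]),
    aggregate_rate = x$aggregate_rate[first],
    aggregate_sd = x$aggregate_sd[first],
    evaluable = as.logical(x$evaluable[first]),
    stringsAsFactors = FALSE
  )
  structure(
    list(alt_rates = x[, keep], site_rates = site_rates, panel = panel,
         n_samples = x$n_samples[1],
         exclude_threshold = x$exclude_threshold[1],
         call = match.call()),
    class = "error_model"
  )
}
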