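#' Simulated positive-call frequency at a given mutant fraction
#'
#' In-silico analogue of a dilution experiment: replicate samples carry a
#' true mutant fraction `vaf` on top of the channel's background error, so
#' the observed non-reference count is `Binomial(depth, vaf + mean_rate)`
#' (rates additive, capped at 1). Each replicate is judged by the Poisson
#' caller and the fraction judged positive is returned.
#'
#' @param vaf Mutant allele fraction in `[0, 1]`.
#' @param depth Read depth per replicate.
#' @param gene,coding_pos,alt Channel to simulate.
#' @param model An [error_model()] fit.
#' @param config A [caller_config()].
#' @param n_reps Number of replicates (default 1000).
#' @param seed RNG seed.
#' @return Fraction of replicates called positive.
#' @export
simulate_dilution_call <- function(vaf, depth, gene, coding_pos, alt, model,
                                   config = caller_config(), n_reps = 1000,
                                   seed = NULL) {
  stopifnot(vaf >= 0, vaf <= 1, n_reps >= 1, depth >= 1)
  ch <- model$alt_rates[model$alt_rates$gene == gene &
                        model$alt_rates$coding_pos == coding_pos &
                        model$alt_rates$alt == alt, ]
  if (nrow(ch) != 1L) {
    stop("channel ", gene, " ", coding_pos, ">", alt,
         " is not in the model", call. = FALSE)
  }
  site <- model$site_rates[model$site_rates$gene == gene &
                           model$site_rates$coding_pos == coding_pos, ]
  p <- vaf + ch$mean_rate
  if (p > 1) {
    warning("vaf + error rate exceeds 1; capped", call. = FALSE)
    p <- 1
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rbinom(n_reps, depth, p)
  lambda <- pmin(ch$mean_rate + config$k_sd * ch$sd, 1) * depth
  alpha <- effective_alpha(config, model)
  positive <- site$evaluable & depth >= config$min_depth &
    poisson_upper_tail(counts, lambda) < alpha
  mean(positive)
}

#' Estimate the limit of detection by simulation
#'
#' Finds the smallest mutant allele fraction whose simulated
#' positive-call frequency reaches `target_rate` at the given depth.
#' Candidate fractions start at `vaf_max` and descend by two-fold
#' dilutions (mirroring a serial-dilution experiment); the bracket between
#' the last detectable and first undetectable fraction is then refined by
#' bisection to a relative precision of 0.1.
#'
#' @inheritParams simulate_dilution_call
#' @param target_rate Required positive-call frequency (default 0.95).
#' @param vaf_max Largest fraction tried (default 0.5).
#' @param n_reps Replicates per evaluated fraction (default 400).
#' @param seed RNG seed; each evaluated fraction uses a sub-seed derived
#'   from it, so results are reproducible.
#' @return A list of class `"lod_estimate"`: `lod` (fraction, `NA` when
#'   even `vaf_max` is not detectable), `call_rate` at the LoD,
#'   `detectable`, `depth`, and the evaluation `trace`.
#' @export
estimate_lod <- function(gene, coding_pos, alt, depth, model,
                         config = caller_config(), target_rate = 0.95,
                         vaf_max = 0.5, n_reps = 400, seed = 1) {
  stopifnot(target_rate > 0, target_rate <= 1)
  counter <- 0L
  trace <- list()
  eval_vaf <- function(v) {
    counter <<- counter + 1L
    r <- simulate_dilution_call(v, depth, gene, coding_pos, alt, model,
                                config, n_reps = n_reps,
                                seed = (seed + counter) %% .Machine$integer.max)
    trace[[counter]] <<- data.frame(vaf = v, call_rate = r)
    r
  }
  # descending two-fold dilution ladder
  lo <- NA_real_
  hi <- NA_real_
  hi_rate <- NA_real_
  v <- vaf_max
  repeat {
    r <- eval_vaf(v)
    if (r >= target_rate) {
      hi <- v
      hi_rate <- r
      v <- v / 2
      if (v < 1 / depth) break   # below one expected mutant read
    } else {
      lo <- v
      break
    }
  }
  if (is.na(hi)) {
    out <- list(lod = NA_real_, call_rate = NA_real_, detectable = FALSE,
                depth = depth, target_rate = target_rate,
                trace = do.call(rbind, trace))
    class(out) <- "lod_estimate"
    return(out)
  }
  if (!is.na(lo)) {
    # bisect (lo undetectable, hi detectable) to relative precision 0.1
    while ((hi - lo) / hi > 0.1) {
      mid <- (hi + lo) / 2
      r <- eval_vaf(mid)
      if (r >= target_rate) {
        hi <- mid
        hi_rate <- r
      } else {
        lo <- mid
      }
    }
  }
  out <- list(lod = hi, call_rate = hi_rate, detectable = TRUE,
              depth = depth, target_rate = target_rate,
              trace = do.call(rbind, trace))
  class(out) <- "lod_estimate"
  out
}

#' @export
print.lod_estimate <- function(x, ...) {
  if (x$detectable) {
    cat(sprintf(
      "Limit of detection: VAF %.3g%% (call rate %.3f at target %.2f, depth %d)\n",
      100 * x$lod, x$call_rate, x$target_rate, as.integer(x$depth)))
  } else {
    cat("Not detectable at this depth (no tried fraction reached the target rate)\n")
  }
  invisible(x)
}
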