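#' Simulation profile for synthetic allele counts
#'
#' Describes the statistical structure the caller assumes so that every
#' module can be exercised without sequencing data: a background error
#' rate per panel position (drawn uniformly from `base_rate_range`, the
#' band observed on clean positions of real amplicon data), optional
#' systematically noisy positions whose artifact loads onto the ref>A
#' channel (FFPE/PCR-style G>A damage), across-sample rate dispersion,
#' and a log-uniform depth distribution.
#'
#' The per-position rate is split equally across the three alternate
#' channels; at a high-error position the listed artifact rate is added
#' to the ref>A channel on top of its share.
#'
#' @param panel A [hotspot_panel()].
#' @param base_rate_range Range of per-position aggregate background
#'   error rates (default `c(0.0007, 0.0071)`).
#' @param high_error_rates Named numeric vector mapping site labels to
#'   artifact rates; defaults to the three default-panel exclusions at
#'   their characteristic rates. Use `NULL` for none.
#' @param dispersion Standard deviation (log scale) of the mean-one
#'   multiplicative log-normal jitter applied to each sample's rates
#'   (default 0.2).
#' @param depth_range Depth range, sampled log-uniformly per sample and
#'   position (default `c(2e4, 8e4)`).
#' @param seed RNG seed (required): fixes the per-position rates drawn
#'   here and the default stream for the generators.
#' @return A list of class `"simulation_profile"` with a per-channel
#'   `rates` table.
#' @export
simulation_profile <- function(panel = hotspot_panel(),
                               base_rate_range = c(0.0007, 0.0071),
                               high_error_rates = c("KRAS 37G" = 0.1755,
                                                    "KRAS 175G" = 0.3016,
                                                    "NRAS 351G" = 0.0233),
                               dispersion = 0.2,
                               depth_range = c(2e4, 8e4),
                               seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for a reproducible profile", call. = FALSE)
  }
  stopifnot(all(base_rate_range >= 0), all(base_rate_range <= 1),
            dispersion >= 0, all(depth_range >= 1))
  if (!is.null(high_error_rates)) {
    unknown <- setdiff(names(high_error_rates), panel$label)
    if (length(unknown)) {
      stop("high_error_rates name(s) not in panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(seed)
  site_rate <- stats::runif(nrow(panel), base_rate_range[1],
                            base_rate_range[2])
  rates <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    alts <- setdiff(c("A", "C", "G", "T"), panel$ref[i])
    rate <- rep(site_rate[i] / 3, 3)
    extra <- high_error_rates[panel$label[i]]
    if (length(extra) == 1L && !is.na(extra)) {
      rate[alts == "A"] <- rate[alts == "A"] + unname(extra)
    }
    data.frame(gene = panel$gene[i], coding_pos = panel$coding_pos[i],
               ref = panel$ref[i], alt = alts, rate = rate,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(panel = panel, rates = rates, dispersion = dispersion,
                 depth_range = depth_range, seed = seed),
            class = "simulation_profile")
}

#' @export
print.simulation_profile <- function(x, ...) {
  agg <- tapply(x$rates$rate, site_key(x$rates$gene, x$rates$coding_pos), sum)
  cat("Simulation profile:", nrow(x$panel), "positions; aggregate rates",
      sprintf("%.2g-%.2g;", min(agg), max(agg)),
      "dispersion", x$dispersion, "; depths",
      sprintf("%g-%g", x$depth_range[1], x$depth_range[2]),
      "; seed", x$seed, "\n")
  invisible(x)
}

# One synthetic sample: depths log-uniform, channel counts binomial at
# jittered rates, reference count = depth minus alternates.
draw_sample <- function(profile, sample_id, extra_rate = NULL) {
  panel <- profile$panel
  n_sites <- nrow(panel)
  depth <- as.integer(round(exp(stats::runif(
    n_sites, log(profile$depth_range[1]), log(profile$depth_range[2])))))
  r <- profile$rates
  jitter <- if (profile$dispersion > 0) {
    stats::rlnorm(nrow(r), meanlog = -profile$dispersion^2 / 2,
                  sdlog = profile$dispersion)
  } else rep(1, nrow(r))
  rate <- r$rate * jitter
  if (!is.null(extra_rate)) rate <- rate + extra_rate
  if (any(rate > 1)) {
    warning("channel rate(s) above 1 capped", call. = FALSE)
    rate <- pmin(rate, 1)
  }
  skey <- site_key(panel$gene, panel$coding_pos)
  site_i <- match(site_key(r$gene, r$coding_pos), skey)
  counts <- stats::rbinom(nrow(r), depth[site_i], rate)
  m <- matrix(0L, n_sites, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(site_i, match(r$alt, colnames(m)))] <- counts
  alt_sum <- rowSums(m)
  over <- alt_sum > depth
  if (any(over)) {
    # pathological high-rate draw; trim the largest channel
    for (i in which(over)) {
      j <- which.max(m[i, ])
      m[i, j] <- m[i, j] - (alt_sum[i] - depth[i])
    }
  }
  m[cbind(seq_len(n_sites), match(panel$ref, colnames(m)))] <-
    depth - rowSums(m)
  out <- data.frame(sample_id = sample_id, gene = panel$gene,
                    coding_pos = panel$coding_pos, ref = panel$ref,
                    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                    depth = depth, stringsAsFactors = FALSE)
  as_allele_counts(out)
}

#' Generate a cohort of mutation-free samples
#'
#' Emulates the normal-DNA cohort used to calibrate the error model: each
#' sample draws per-position depths and binomial non-reference counts at
#' the profile's (jittered) background rates.
#'
#' @param n_samples Number of samples (>= 1).
#' @param profile A [simulation_profile()].
#' @param seed RNG seed; defaults to the profile's seed.
#' @param prefix Sample-id prefix (default `"N"`).
#' @return A list of `"allele_counts"` tables.
#' @export
generate_normal_cohort <- function(n_samples, profile,
                                   seed = profile$seed, prefix = "N") {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  ids <- sprintf("%s%02d", prefix, seq_len(n_samples))
  out <- lapply(ids, function(id) draw_sample(profile, id))
  names(out) <- ids
  out
}

#' Generate a tumor sample with known spiked variants
#'
#' As [generate_normal_cohort()], but the listed truth channels carry an
#' additional mutant fraction on top of the background error, and the
#' result is a [labeled_sample()] ready for [sweep_k()].
#'
#' @param truth Data frame with columns `gene`, `coding_pos`, `alt`,
#'   `vaf` (fractions in (0, 1]); zero rows give a known negative.
#' @param profile A [simulation_profile()].
#' @param seed RNG seed; defaults to the profile's seed.
#' @param sample_id Sample label.
#' @return A [labeled_sample()].
#' @export
generate_tumor_sample <- function(truth, profile, seed = profile$seed,
                                  sample_id = "T01") {
  stopifnot(all(c("gene", "coding_pos", "alt") %in% names(truth)))
  if (nrow(truth)) {
    if (is.null(truth$vaf)) stop("truth needs a vaf column", call. = FALSE)
    stopifnot(all(truth$vaf > 0), all(truth$vaf <= 1))
    if (anyDuplicated(truth[, c("gene", "coding_pos", "alt")])) {
      stop("duplicated (position, alt) in truth", call. = FALSE)
    }
    r <- profile$rates
    i <- match(channel_id(truth), channel_id(r))
    if (anyNA(i)) {
      stop("truth channel(s) not in panel: ",
           paste(channel_id(truth)[is.na(i)], collapse = ", "),
           call. = FALSE)
    }
    extra <- numeric(nrow(r))
    extra[i] <- truth$vaf
  } else {
    extra <- NULL
  }
  set.seed(seed)
  table <- draw_sample(profile, sample_id, extra_rate = extra)
  labeled_sample(table, truth = truth[, c("gene", "coding_pos", "alt"),
                                      drop = FALSE])
}

#' Simulate cohorts from a fitted error model
#'
#' Draws synthetic normal cohorts whose per-channel rates are the fitted
#' mean rates, a parametric-bootstrap companion to [error_model()].
#'
#' @param object An [error_model()] fit.
#' @param nsim Number of cohorts.
#' @param seed RNG seed.
#' @param n_samples Samples per cohort; defaults to the fitted cohort size.
#' @param dispersion,depth_range Passed to the underlying profile.
#' @param ... Unused.
#' @return A list of `nsim` cohorts (each a list of allele-count tables).
#' @export
simulate.error_model <- function(object, nsim = 1, seed = 1,
                                 n_samples = object$n_samples,
                                 dispersion = 0.2,
                                 depth_range = c(2e4, 8e4), ...) {
  profile <- structure(
    list(panel = object$panel,
         rates = data.frame(object$alt_rates[, c("gene", "coding_pos",
                                                 "ref", "alt")],
                            rate = pmax(object$alt_rates$mean_rate, 0)),
         dispersion = dispersion, depth_range = depth_range, seed = seed),
    class = "simulation_profile")
  lapply(seq_len(nsim), function(i) {
    generate_normal_cohort(n_samples, profile,
                           seed = (seed + i) %% .Machine$integer.max,
                           prefix = sprintf("S%d_", i))
  })
}
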