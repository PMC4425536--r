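# Hand-built model and count-table constructors used across test files.

# An error model with constant per-channel mean rate and SD at every
# panel position (aggregate = 3x the channel rate).
toy_model <- function(panel = hotspot_panel(), mean_rate = 0.001,
                      sd = 0.0002, exclude_threshold = 0.01) {
  alt_rates <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    data.frame(gene = panel$gene[i], coding_pos = panel$coding_pos[i],
               ref = panel$ref[i],
               alt = setdiff(c("A", "C", "G", "T"), panel$ref[i]),
               mean_rate = mean_rate, sd = sd,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  site_rates <- data.frame(
    gene = panel$gene, coding_pos = panel$coding_pos, ref = panel$ref,
    label = panel$label, aggregate_rate = 3 * mean_rate,
    aggregate_sd = sd * sqrt(3), evaluable = panel$evaluable,
    stringsAsFactors = FALSE
  )
  structure(list(alt_rates = alt_rates, site_rates = site_rates,
                 panel = panel, n_samples = 10,
                 exclude_threshold = exclude_threshold),
            class = "error_model")
}

# Allele-count table with uniform depth; alt_counts is an optional data
# frame (gene, coding_pos, alt, count) of non-reference reads to place.
make_counts <- function(panel = hotspot_panel(), sample_id = "S1",
                        depth = 50000, alt_counts = NULL) {
  m <- matrix(0L, nrow(panel), 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  if (!is.null(alt_counts)) {
    i <- match(paste(alt_counts$gene, alt_counts$coding_pos),
               paste(panel$gene, panel$coding_pos))
    stopifnot(!anyNA(i))
    m[cbind(i, match(alt_counts$alt, colnames(m)))] <-
      as.integer(alt_counts$count)
  }
  m[cbind(seq_len(nrow(panel)), match(panel$ref, colnames(m)))] <-
    as.integer(depth - rowSums(m))
  as_allele_counts(data.frame(
    sample_id = sample_id, gene = panel$gene, coding_pos = panel$coding_pos,
    ref = panel$ref, A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
    stringsAsFactors = FALSE
  ))
}

# Independent brute-force Poisson upper tail: direct pmf summation.
tail_oracle <- function(k, lam, upto = 10000) {
  if (k == 0) return(1)
  j <- k:max(k, ceiling(lam + 40 * sqrt(lam + 1)))
  sum(exp(-lam + j * log(lam) - lfactorial(j)))
}
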