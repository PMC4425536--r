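two_sample_cohort <- function(alt1, alt2, depth = 10000) {
  panel <- hotspot_panel()
  list(
    make_counts(panel, "S1", depth,
                data.frame(gene = "KRAS", coding_pos = 34, alt = "A",
                           count = alt1)),
    make_counts(panel, "S2", depth,
                data.frame(gene = "KRAS", coding_pos = 34, alt = "A",
                           count = alt2))
  )
}

test_that("mean and SD of per-sample rates use the n-1 estimator", {
  fit <- error_model(two_sample_cohort(10, 30))
  ch <- fit$alt_rates[fit$alt_rates$gene == "KRAS" &
                      fit$alt_rates$coding_pos == 34 &
                      fit$alt_rates$alt == "A", ]
  expect_equal(ch$mean_rate, 0.002)
  expect_equal(ch$sd, sd(c(0.001, 0.003)))    # ~0.001414
  # aggregate mean equals the mean of per-sample summed non-ref fractions
  site <- fit$site_rates[fit$site_rates$label == "KRAS 34G", ]
  expect_equal(site$aggregate_rate, 0.002)
  # untouched channels are exactly zero
  zero <- fit$alt_rates[fit$alt_rates$coding_pos != 34 |
                        fit$alt_rates$gene != "KRAS", ]
  expect_true(all(zero$mean_rate == 0) && all(zero$sd == 0))
})

test_that("degenerate cohorts are rejected or flagged", {
  panel <- hotspot_panel()
  expect_error(error_model(list(make_counts(panel)), panel),
               "at least 2")
  # zero-depth position: warned and excluded, not fatal
  s1 <- as.data.frame(make_counts(panel, "S1", depth = 1000))
  s1[s1$gene == "BRAF" & s1$coding_pos == 1798, c("A", "C", "G", "T", "depth")] <- 0
  s2 <- make_counts(panel, "S2", depth = 1000)
  expect_warning(fit <- error_model(list(as_allele_counts(s1), s2), panel),
                 "zero depth")
  expect_false(fit$site_rates$evaluable[fit$site_rates$label == "BRAF 1798G"])
})

test_that("estimation is permutation- and scale-invariant", {
  panel <- hotspot_panel()
  prof <- simulation_profile(panel, seed = 5)
  cohort <- generate_normal_cohort(6, prof)
  f1 <- error_model(cohort, panel)
  f2 <- error_model(rev(cohort), panel)
  expect_equal(f1$alt_rates[c("mean_rate", "sd")],
               f2$alt_rates[c("mean_rate", "sd")])
  expect_equal(f1$site_rates$aggregate_rate, f2$site_rates$aggregate_rate)

  scaled <- lapply(two_sample_cohort(10, 30), function(s) {
    s[c("A", "C", "G", "T", "depth")] <- s[c("A", "C", "G", "T", "depth")] * 5L
    as_allele_counts(as.data.frame(s))
  })
  expect_equal(error_model(scaled)$alt_rates$mean_rate,
               error_model(two_sample_cohort(10, 30))$alt_rates$mean_rate)
})

test_that("estimated rates converge to the generating rates", {
  panel <- hotspot_panel()
  # dispersion 0: pure binomial noise around the profile rates
  prof <- simulation_profile(panel, dispersion = 0, seed = 31,
                             depth_range = c(5e4, 5e4))
  fit <- error_model(generate_normal_cohort(100, prof), panel)
  key <- paste(fit$alt_rates$gene, fit$alt_rates$coding_pos,
               fit$alt_rates$alt)
  truth <- prof$rates$rate[match(key, paste(prof$rates$gene,
                                            prof$rates$coding_pos,
                                            prof$rates$alt))]
  se <- sqrt(truth * (1 - truth) / 5e4 / 100)
  dev <- abs(fit$alt_rates$mean_rate - truth)
  # recovery: nearly all of the 108 channels inside 3 SE, none outside 5 SE
  expect_gte(mean(dev <= 3 * se), 0.95)
  expect_true(all(dev <= 5 * se))
})

test_that("high-error flagging reproduces the published exclusions", {
  panel <- hotspot_panel(list(genes = yaml::read_yaml(
    default_panel_config())$genes))   # no pre-excluded sites
  fit <- toy_model(panel)
  set.seed(2)
  fit$site_rates$aggregate_rate <- runif(39, 0.0007, 0.0071)
  fit$site_rates$aggregate_rate[fit$site_rates$label == "KRAS 37G"] <- 0.1755
  fit$site_rates$aggregate_rate[fit$site_rates$label == "KRAS 175G"] <- 0.3016
  fit$site_rates$aggregate_rate[fit$site_rates$label == "NRAS 351G"] <- 0.0233

  flagged <- flag_high_error_sites(fit, 0.01)
  expect_equal(flagged$label, c("KRAS 175G", "KRAS 37G", "NRAS 351G"))
  expect_equal(nrow(flag_high_error_sites(fit, 0.5)), 0)
  expect_equal(flag_high_error_sites(fit, 0.0005)$label,
               fit$site_rates$label[order(-fit$site_rates$aggregate_rate)])
  expect_error(flag_high_error_sites(fit, 0), "threshold")
})

test_that("an error model survives a TSV round trip", {
  fit <- error_model(two_sample_cohort(10, 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_error_model(fit, path)
  back <- read_error_model(path)
  expect_equal(back$alt_rates$mean_rate, fit$alt_rates$mean_rate)
  expect_equal(back$site_rates$evaluable, fit$site_rates$evaluable)
  expect_equal(back$n_samples, fit$n_samples)
  # calls made with the restored model are identical
  tab <- make_counts(hotspot_panel(), "Q1", 40000,
                     data.frame(gene = "NRAS", coding_pos = 181, alt = "A",
                                count = 400))
  expect_equal(call_sample(tab, back)$status, call_sample(tab, fit)$status)
})
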