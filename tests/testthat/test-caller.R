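test_that("the Poisson upper tail matches direct pmf summation", {
  expect_equal(poisson_upper_tail(0, 0), 1)
  expect_equal(poisson_upper_tail(0, 123), 1)
  expect_equal(poisson_upper_tail(1, 0), 0)
  expect_equal(poisson_upper_tail(8, 1), tail_oracle(8, 1),
               tolerance = 1e-12)
  for (lam in c(0.01, 0.5, 1, 5, 20, 100)) {
    for (k in c(0, 1, 2, 5, 20, 50, 200)) {
      expect_equal(poisson_upper_tail(k, lam), tail_oracle(k, lam),
                   tolerance = 1e-12, info = paste("k", k, "lam", lam))
    }
  }
  expect_error(poisson_upper_tail(-1, 1), "non-negative")
  expect_error(poisson_upper_tail(1, -1), "non-negative")
})

test_that("the minimum positive count is the smallest k past the alpha tail", {
  expect_identical(min_positive_count(0), 1L)
  expect_identical(min_positive_count(1), 8L)    # P(X>=8|1) ~ 1.02e-5 < 2e-5
  expect_gte(poisson_upper_tail(7, 1), 2e-5)
  # exhaustive agreement with a brute-force scan
  for (lam in c(0, 0.1, 1, 3, 10, 60)) {
    for (alpha in c(2e-5, 1e-3, 0.05)) {
      k <- min_positive_count(lam, alpha)
      expect_lt(poisson_upper_tail(k, lam), alpha)
      if (k > 1) expect_gte(poisson_upper_tail(k - 1, lam), alpha)
      expect_gte(k, 1)
    }
  }
  # monotone: non-decreasing in lambda, non-increasing in alpha
  lams <- c(0, 0.5, 1, 5, 50)
  expect_true(!is.unsorted(min_positive_count(lams)))
  expect_true(!is.unsorted(rev(
    sapply(c(1e-6, 2e-5, 1e-3, 0.05), function(a) min_positive_count(5, a)))))
})

test_that("per-channel lambda scales with depth and drives the decision", {
  panel <- hotspot_panel()
  model <- toy_model(panel, mean_rate = 0.001, sd = 0.0002)
  # lambda = (0.001 + 7*0.0002) * 50000 = 120
  tab <- make_counts(panel, "S1", 50000,
                     data.frame(gene = "KRAS", coding_pos = 34, alt = "A",
                                count = 600))
  row <- call_site(tab, "KRAS", 34, model)
  row <- row[row$alt == "A", ]
  expect_equal(row$lambda, 120)
  expect_equal(row$status, "positive")
  expect_equal(row$vaf, 600 / 50000)
  expect_equal(row$protein, "G12S")

  at_mean <- make_counts(panel, "S1", 50000,
                         data.frame(gene = "KRAS", coding_pos = 34,
                                    alt = "A", count = 120))
  expect_equal(call_site(at_mean, "KRAS", 34, model)$status[
    call_site(at_mean, "KRAS", 34, model)$alt == "A"], "negative")

  # zero observed count: negative with tail probability 1
  clean <- make_counts(panel, "S1", 50000)
  r0 <- call_site(clean, "NRAS", 182, model)
  expect_true(all(r0$status == "negative"))
  expect_true(all(r0$tail_prob == 1))
})

test_that("excluded positions and low depth are not evaluable", {
  panel <- hotspot_panel()
  model <- toy_model(panel)
  tab <- make_counts(panel, "S1", 50000,
                     data.frame(gene = "KRAS", coding_pos = 37, alt = "A",
                                count = 20000))
  r <- call_site(tab, "KRAS", 37, model)
  expect_true(all(r$status == "not_evaluable"))

  shallow <- make_counts(panel, "S1", 500,
                         data.frame(gene = "KRAS", coding_pos = 34,
                                    alt = "A", count = 400))
  r2 <- call_sample(shallow, model)
  expect_true(all(r2$status == "not_evaluable"))
})

test_that("tail-test and count-threshold decision paths agree", {
  panel <- hotspot_panel()
  model <- toy_model(panel, mean_rate = 0.002, sd = 0.0005)
  cfg <- caller_config()
  set.seed(91)
  for (rep in 1:50) {
    depth <- sample(2000:80000, 1)
    count <- sample(0:300, 1)
    tab <- make_counts(panel, "S1", depth,
                       data.frame(gene = "NRAS", coding_pos = 35, alt = "T",
                                  count = count))
    r <- call_site(tab, "NRAS", 35, model, cfg)
    r <- r[r$alt == "T", ]
    expected <- count >= min_positive_count(r$lambda, cfg$alpha)
    expect_equal(r$status == "positive", expected,
                 info = paste("depth", depth, "count", count))
  }
})

test_that("calls are monotone in observed count and in the SD multiplier", {
  panel <- hotspot_panel()
  model <- toy_model(panel, mean_rate = 0.001, sd = 0.0005)
  status_at <- function(count, k_sd) {
    tab <- make_counts(panel, "S1", 40000,
                       data.frame(gene = "BRAF", coding_pos = 1799,
                                  alt = "A", count = count))
    r <- call_site(tab, "BRAF", 1799, model, caller_config(k_sd = k_sd))
    r$status[r$alt == "A"]
  }
  counts <- c(0, 40, 80, 120, 200, 400, 1000)
  s <- vapply(counts, status_at, "", k_sd = 7)
  expect_true(!is.unsorted(match(s, c("negative", "positive"))))
  # larger k never flips a channel negative -> positive
  for (cnt in c(60, 120, 240)) {
    by_k <- vapply(0:7, function(k) status_at(cnt, k), "")
    expect_true(!is.unsorted(rev(match(by_k, c("negative", "positive")))))
  }
})

test_that("a spiked sample yields exactly its expected positive call", {
  panel <- hotspot_panel()
  prof <- simulation_profile(panel, seed = 17)
  fit <- error_model(generate_normal_cohort(10, prof), panel)
  lab <- generate_tumor_sample(
    data.frame(gene = "KRAS", coding_pos = 34, alt = "A", vaf = 0.10),
    prof, seed = 23)
  pos <- positive_calls(call_sample(lab$table, fit))
  expect_equal(nrow(pos), 1)
  expect_equal(pos$protein, "G12S")

  # double mutant in codon 12
  lab2 <- generate_tumor_sample(
    data.frame(gene = "KRAS", coding_pos = c(34, 35), alt = c("A", "A"),
               vaf = c(0.10, 0.15)),
    prof, seed = 24)
  pos2 <- positive_calls(call_sample(lab2$table, fit))
  expect_setequal(pos2$protein, c("G12S", "G12D"))
})

test_that("baseline samples are almost never called positive at 7 SD", {
  panel <- hotspot_panel()
  prof <- simulation_profile(panel, seed = 29)
  fit <- error_model(generate_normal_cohort(10, prof), panel)
  set.seed(77)
  nulls <- generate_normal_cohort(100, prof, seed = 78, prefix = "Z")
  n_pos7 <- sum(vapply(nulls, function(s) {
    nrow(positive_calls(call_sample(s, fit)))
  }, numeric(1)))
  expect_lte(n_pos7, 1)
  # and strictly fewer than with no SD padding
  n_pos0 <- sum(vapply(nulls[1:20], function(s) {
    nrow(positive_calls(call_sample(s, fit, caller_config(k_sd = 0))))
  }, numeric(1)))
  n_pos7_sub <- sum(vapply(nulls[1:20], function(s) {
    nrow(positive_calls(call_sample(s, fit)))
  }, numeric(1)))
  expect_lte(n_pos7_sub, n_pos0)
})
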