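# Power simulation, prior bookkeeping, outcome/consciousness statistics,
# forward model selection.

test_that("power simulation matches the closed form 1-(1-p)^N", {
  pc <- power_simulation(p = 0.21, n_sims = 5000, seed = 7)
  expect_true(all(abs(pc$power - pc$power_closed_form) <=
                    3 * pmax(pc$power_se, sqrt(pc$power_closed_form *
                                                 (1 - pc$power_closed_form) / 5000))))
  expect_true(all(abs(pc$mean_k - pc$n * 0.21) <= 3 * pc$mean_k_se))
  # closed form at the protocol's operating point
  expect_equal(pc$power_closed_form[pc$n == 13], 1 - 0.79^13, tolerance = 1e-12)

  expect_equal(unique(power_simulation(1, n_sims = 500, seed = 1)$power), 1)
  expect_equal(unique(power_simulation(0, n_sims = 500, seed = 1)$power), 0)
})

test_that("minimal sample size finds the power crossing", {
  # noise-free curve: plug the closed form in as the estimate
  pc <- power_simulation(0.21, n_sims = 1000, seed = 3)
  exact <- pc
  exact$power <- exact$power_closed_form
  expect_equal(minimal_sample_size(exact, 0.95), 13)

  all_one <- power_simulation(1, n_sims = 200, seed = 1)
  expect_equal(minimal_sample_size(all_one, 0.95), 4)

  low <- power_simulation(0.01, n_range = 4:10, n_sims = 200, seed = 1)
  expect_error(minimal_sample_size(low, 0.95), "maximum power")
})

test_that("prior probabilities are two-decimal bookkeeping", {
  expect_equal(prior_success_probability(5, 24), 0.21)
  expect_equal(prior_success_probability(2, 10), 0.20)
  expect_equal(prior_success_probability(4, 11), 0.36)
  expect_error(prior_success_probability(5, 0))
})

fake_cohort <- function(sig, outcome, auc = NULL, four = NULL) {
  n <- length(sig)
  tibble::tibble(
    id = sprintf("P%02d", 1:n), day = 1L,
    auc = auc %||% runif(n, 0.4, 0.9),
    significant = sig,
    four = four %||% sample(0:16, n, TRUE),
    cpc = ifelse(outcome == "favourable", 1L, 4L),
    outcome = outcome,
    propofol = rgamma(n, 2), fentanyl = rgamma(n, 2), midazolam = rgamma(n, 2),
    temperature = rnorm(n, 36.5, 0.3), age = 55L, sex = "F")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Fisher exact test on decoding x outcome matches enumeration", {
  set.seed(110)
  perfect <- fake_cohort(rep(c(TRUE, FALSE), each = 5),
                         rep(c("favourable", "unfavourable"), each = 5))
  ft <- outcome_fisher(perfect)
  expect_equal(ft$p, 2 / choose(10, 5))  # only the two extreme tables qualify
  expect_equal(c(ft$sig_fav, ft$sig_unfav, ft$nonsig_fav, ft$nonsig_unfav),
               c(5, 0, 0, 5))

  flat <- fake_cohort(c(TRUE, TRUE, FALSE, FALSE),
                      rep(c("favourable", "unfavourable"), 2))
  expect_equal(outcome_fisher(flat)$p, 1)

  expect_error(outcome_fisher(fake_cohort(rep(TRUE, 4),
                                          rep("favourable", 4))),
               "both")

  # enumeration oracle for arbitrary margins (totals <= 40)
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    kk <- max(0, k - n):min(k, m)
    pr <- dhyper(kk, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  for (i in 1:20) {
    cnt <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    if (any(cnt[1:2] + cnt[3:4] == 0) || any(cnt[c(1, 3)] + cnt[c(2, 4)] == 0))
      next
    co <- fake_cohort(
      rep(c(TRUE, TRUE, FALSE, FALSE), cnt),
      rep(rep(c("favourable", "unfavourable"), 2), cnt))
    expect_equal(outcome_fisher(co)$p,
                 enum_fisher(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-9)
  }
})

test_that("Pearson correlation matches hand computation and brute force", {
  expect_equal(correlate(1:10, 1:10)$r, 1)
  h <- correlate(c(1, 2, 3), c(1, 2, 4))
  expect_equal(h$r, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_error(correlate(c(1, 1, 1), 1:3), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")

  set.seed(111)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    out <- correlate(x, y)
    r_ref <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r, r_ref, tolerance = 1e-12)
    t_stat <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
    expect_equal(out$p, 2 * pt(abs(t_stat), n - 2, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis matches the rank-sum formula and is rank-invariant", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$h, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(kw$df, 1)

  same <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))
  expect_equal(same$h, 0); expect_equal(same$p, 1)

  set.seed(112)
  v <- rexp(12); g <- rep(c("a", "b", "c"), 4)
  expect_equal(kruskal_wallis(v, g)$h, kruskal_wallis(log(v), g)$h)

  # brute-force reference with tie correction on small samples
  for (i in 1:15) {
    n <- sample(6:10, 1)
    v <- sample(1:4, n, replace = TRUE)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(v)) == 1) next
    r <- rank(v)
    ns <- table(g)
    h_ref <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / ns) - 3 * (n + 1)
    ties <- table(v)
    h_ref <- h_ref / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(kruskal_wallis(v, g)$h, h_ref, tolerance = 1e-9)
  }
})

test_that("forward selection recovers the active sedative and stops on null cohorts", {
  picks <- sapply(1:20, function(s) {
    co <- simulate_cohort(n_patients = 30, base_amplitude = 2.5,
                          sedation_effects = c(propofol = -0.8),
                          auc_noise_sd = 0.03, seed = 500 + s)
    paste(sort(sedation_model_selection(co$table)$selected), collapse = "+")
  })
  expect_gt(mean(picks == "propofol"), 0.5)

  null_picks <- sapply(1:60, function(s) {
    co <- simulate_cohort(n_patients = 30, seed = 600 + s)
    length(sedation_model_selection(co$table)$selected)
  })
  expect_gt(mean(null_picks == 0), 0.5)

  expect_error(sedation_model_selection(fake_cohort(rep(TRUE, 5),
                                                    rep("favourable", 5))),
               "at least 10")
})

test_that("the selection ledger reflects nested-model improvements", {
  co <- simulate_cohort(n_patients = 30, base_amplitude = 2.5,
                        sedation_effects = c(propofol = -0.8),
                        auc_noise_sd = 0.03, seed = 510)
  ms <- sedation_model_selection(co$table)
  expect_s3_class(ms$ledger, "tbl_df")
  expect_true(all(c("step", "term", "adj_r2", "aic", "added") %in%
                    names(ms$ledger)))
  # adding any term never increases RSS (nested least squares)
  dat <- co$table
  rss0 <- sum(resid(lm(auc ~ 1, dat))^2)
  for (term in c("propofol", "fentanyl", "midazolam"))
    expect_lte(sum(resid(lm(reformulate(term, "auc"), dat))^2), rss0 + 1e-10)
  # glance/tidy methods expose the selected model
  g <- glance(ms)
  expect_true(is.finite(g$aic))
  expect_true("term" %in% names(tidy(ms)))
})
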