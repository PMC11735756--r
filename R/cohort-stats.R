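# Cohort-level statistics: binomial power simulation for the sampling plan,
# outcome and consciousness-level tests, and forward model selection over
# sedative infusion rates.

#' Binomial power simulation for a count-of-successes design
#'
#' The design declares the experiment positive when at least one recording
#' shows significant decoding. For each candidate cohort size N, `n_sims`
#' success counts K' are drawn from Binomial(N, p). Under the null of a zero
#' success probability, the probability of observing at least K' successes is
#' 1 when K' = 0 and 0 otherwise, so a draw is significant iff K' >= 1 (this
#' "at least K'" reading is the only one under which the test has any power;
#' the protocol's "up to K'" phrasing would make it identically 1).
#' Power(N) is the fraction of significant draws; the closed form is
#' `1 - (1 - p)^N`.
#'
#' @param p A-priori per-recording success probability.
#' @param n_range Candidate cohort sizes (default 4:30).
#' @param n_sims Simulations per N (default 5000; >= 1000 recommended).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A tibble of class `power_curve`: `n`, `power`, `power_se`
#'   (Monte-Carlo SE), `mean_k` (mean success count), `mean_k_se`,
#'   `power_closed_form`.
#' @examples
#' pc <- power_simulation(p = 0.21, n_sims = 2000, seed = 1)
#' minimal_sample_size(pc)  # 13
#' @export
power_simulation <- function(p, n_range = 4:30, n_sims = 5000L,
                             alpha = 0.05, seed = 1L) {
  stopifnot(p >= 0, p <= 1, n_sims >= 1L, alpha > 0, alpha < 1)
  rows <- withr_seed(seed, {
    purrr::map(n_range, function(N) {
      k <- stats::rbinom(n_sims, N, p)
      p_h0 <- ifelse(k == 0, 1, 0)       # P(>= K' successes | p = 0)
      sig <- p_h0 < alpha
      pw <- mean(sig)
      tibble::tibble(
        n = N, power = pw,
        power_se = sqrt(pw * (1 - pw) / n_sims),
        mean_k = mean(k),
        mean_k_se = stats::sd(k) / sqrt(n_sims),
        power_closed_form = 1 - (1 - p)^N
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "p") <- p; attr(out, "alpha") <- alpha; attr(out, "n_sims") <- n_sims
  class(out) <- c("power_curve", class(out))
  out
}

#' Smallest cohort size reaching a target power
#'
#' @param curve A `power_curve` from [power_simulation()].
#' @param target Target power (default 0.95).
#' @return The smallest `n` whose estimated power is >= `target`.
#' @export
minimal_sample_size <- function(curve, target = 0.95) {
  ok <- which(curve$power >= target)
  if (length(ok) == 0L)
    stop("target power ", target, " not reached in range; maximum power = ",
         signif(max(curve$power), 3), " at n = ", curve$n[which.max(curve$power)])
  curve$n[min(ok)]
}

#' A-priori success probability from prior counts
#'
#' Bookkeeping helper: successes/total rounded to two decimals, the way prior
#' prevalences parametrize the power simulation (5/24 -> 0.21, 2/10 -> 0.20).
#'
#' @param successes,total Prior counts.
#' @return Rounded probability.
#' @export
prior_success_probability <- function(successes, total) {
  stopifnot(total > 0, successes >= 0, successes <= total)
  round(successes / total, 2)
}

#' Fisher's exact test of decoding significance against outcome
#'
#' Crosses the per-recording `significant` flag with the dichotomized outcome
#' and runs the two-sided exact hypergeometric test.
#'
#' @param table A `cohort_table` with `significant` and `outcome` columns.
#' @param day Optional recording day filter (1 or 2).
#' @return A tibble: `p`, plus the four cell counts
#'   (`sig_fav`, `sig_unfav`, `nonsig_fav`, `nonsig_unfav`).
#' @export
outcome_fisher <- function(table, day = NULL) {
  if (!is.null(day)) table <- dplyr::filter(table, .data$day == !!day)
  out <- factor(table$outcome, levels = c("favourable", "unfavourable"))
  sig <- factor(ifelse(table$significant, "yes", "no"), levels = c("yes", "no"))
  tab <- base::table(sig, out)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("Fisher test needs both decoding groups and both outcome groups")
  ft <- stats::fisher.test(tab)
  tibble::tibble(p = ft$p.value,
                 sig_fav = tab["yes", "favourable"],
                 sig_unfav = tab["yes", "unfavourable"],
                 nonsig_fav = tab["no", "favourable"],
                 nonsig_unfav = tab["no", "unfavourable"])
}

#' Pearson correlation between decoding performance and a clinical scale
#'
#' @param x Per-recording AUC values.
#' @param y FOUR (0-16) or CPC (1-5) values, same length.
#' @return A tibble: `r`, `p` (two-sided, t distribution with n-2 df), `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis comparison of a clinical feature across decoding groups
#'
#' Rank-based H with tie correction, p from the chi-squared distribution with
#' `groups - 1` degrees of freedom. Returns H = 0, p = 1 when all values are
#' identical.
#'
#' @param values Numeric clinical feature (e.g. infusion rate, temperature).
#' @param groups Grouping vector (e.g. decodable vs non-decodable).
#' @return A tibble: `h`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2L, all(table(groups) > 0))
  if (length(unique(values)) == 1L)
    return(tibble::tibble(h = 0, p = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(h = unname(kt$statistic), p = kt$p.value,
                 df = unname(kt$parameter))
}

#' Forward selection of sedation covariates for decoding performance
#'
#' Response is the per-recording AUC (Gaussian GLM, identity link by default;
#' `family = "logit"` models `qlogis(auc)` instead). Candidate terms are the
#' three sedative infusion rates and their pairwise interactions; an
#' interaction becomes eligible only once both of its main effects are in the
#' model. At each step the eligible term with the largest adjusted-R2 gain is
#' added if it also lowers the information criterion; selection stops
#' otherwise. The criterion is the small-sample corrected AIC (AICc): at
#' cohort sizes around 30 with three candidate covariates, plain AIC admits a
#' spurious term in more than half of null cohorts, so the correction is what
#' makes the stopping rule meaningful at this design's scale (both AIC and
#' AICc are reported in the ledger). Zero-variance covariates are dropped
#' with a warning.
#'
#' @param table A `cohort_table` with `auc`, `propofol`, `fentanyl`,
#'   `midazolam` columns (n >= 10).
#' @param family `"gaussian"` (identity) or `"logit"` (Gaussian on the logit
#'   of AUC).
#' @return A list of class `model_selection`: `selected` (character terms),
#'   `model` (the final `lm`), `ledger` (tibble of every candidate evaluated:
#'   `step`, `term`, `adj_r2`, `aic`, `aicc`, `added`).
#' @export
sedation_model_selection <- function(table, family = c("gaussian", "logit")) {
  family <- match.arg(family)
  if (nrow(table) < 10L) stop("need at least 10 recordings")
  dat <- tibble::tibble(
    auc = if (family == "logit")
      stats::qlogis(pmin(pmax(table$auc, 1e-6), 1 - 1e-6)) else table$auc,
    propofol = table$propofol, fentanyl = table$fentanyl,
    midazolam = table$midazolam
  )
  mains <- c("propofol", "fentanyl", "midazolam")
  keep <- mains[purrr::map_lgl(mains, ~ stats::sd(dat[[.x]]) > 1e-12)]
  if (length(keep) < length(mains))
    warning("dropped zero-variance covariate(s): ",
            paste(setdiff(mains, keep), collapse = ", "))
  interactions <- if (length(keep) >= 2L)
    utils::combn(keep, 2, paste, collapse = ":") else character(0)

  selected <- character(0)
  current <- stats::lm(auc ~ 1, data = dat)
  ledger <- list(); step <- 0L
  repeat {
    step <- step + 1L
    elig_main <- setdiff(keep, selected)
    elig_int <- interactions[
      !interactions %in% selected &
        purrr::map_lgl(strsplit(interactions, ":"),
                       ~ all(.x %in% selected))]
    eligible <- c(elig_main, elig_int)
    if (length(eligible) == 0L) break
    cand <- purrr::map(eligible, function(term) {
      f <- stats::reformulate(c(selected, term), response = "auc")
      m <- stats::lm(f, data = dat)
      list(term = term, adj_r2 = summary(m)$adj.r.squared,
           aic = stats::AIC(m), aicc = aicc(m), model = m)
    })
    adj <- purrr::map_dbl(cand, "adj_r2")
    best <- cand[[which.max(adj)]]
    improves <- best$aicc < aicc(current)
    ledger[[step]] <- tibble::tibble(
      step = step,
      term = purrr::map_chr(cand, "term"),
      adj_r2 = adj,
      aic = purrr::map_dbl(cand, "aic"),
      aicc = purrr::map_dbl(cand, "aicc"),
      added = purrr::map_chr(cand, "term") == best$term & improves
    )
    if (!improves) break
    selected <- c(selected, best$term)
    current <- best$model
  }
  structure(list(selected = selected, model = current,
                 ledger = dplyr::bind_rows(ledger), family = family),
            class = "model_selection")
}

# Small-sample corrected AIC; k counts all estimated parameters incl. sigma.
aicc <- function(model) {
  k <- length(stats::coef(model)) + 1
  n <- stats::nobs(model)
  stats::AIC(model) + 2 * k * (k + 1) / (n - k - 1)
}
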