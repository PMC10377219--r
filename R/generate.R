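# Truncated-normal sampling by inverse-CDF, with the location parameter
# re-solved so the *truncated* mean equals the requested group mean (plain
# truncation of N(mean, sd) would bias variables whose mean sits near a
# bound, e.g. age against the 75-year cap).

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

solve_trunc_location <- function(target, sd, lo, hi) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lo, hi) - target,
                 lower = target - 8 * sd, upper = target + 8 * sd,
                 tol = 1e-10)$root
}

rtruncnorm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

#' Generate a synthetic stress cohort
#'
#' Draws `n_low + n_high` subject records from the group-conditional
#' distributions of a [cohort_spec()]: continuous variables from truncated
#' normal distributions whose truncated means equal the specified group means,
#' binary variables from group-specific Bernoulli distributions. BMI is then
#' recomputed as `weight / (height / 100)^2` so the derived-variable identity
#' holds exactly in every record. The class label is assigned by group
#' membership (two-component mixture); the class signal lives entirely in the
#' between-group distribution shifts.
#'
#' @param spec A [cohort_spec()]; defaults to [default_cohort_spec()].
#' @param seed Integer seed; the same `(spec, seed)` pair yields an identical
#'   cohort. The caller's RNG state is left untouched.
#' @return A tibble with the 11 schema columns plus a `stress` factor
#'   (`low`/`high`); low-stress records first.
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(), seed = 1)
#' table(cohort$stress)
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = 1L) {
  validate_cohort_spec(spec)
  with_seed(as.integer(seed), {
    groups <- lapply(c(low = "low", high = "high"), function(g) {
      n <- if (g == "low") spec$n_low else spec$n_high
      mcol <- if (g == "low") "mean_low" else "mean_high"
      pcol <- if (g == "low") "prob_low" else "prob_high"
      rec <- list()
      for (v in setdiff(continuous_vars(), "bmi")) {
        r <- spec$continuous[v, ]
        mu <- solve_trunc_location(r[[mcol]], r$sd, r$lower, r$upper)
        rec[[v]] <- rtruncnorm(n, mu, r$sd, r$lower, r$upper)
      }
      lv <- binary_levels()
      for (v in binary_vars()) {
        p <- spec$binary[v, pcol]
        rec[[v]] <- factor(lv[[v]][1L + stats::rbinom(n, 1L, p)],
                           levels = lv[[v]])
      }
      rec$bmi <- rec$weight / (rec$height / 100)^2
      rec$stress <- factor(g, levels = c("low", "high"))
      tibble::as_tibble(rec)
    })
    out <- rbind(groups$low, groups$high)
    out[, c(cohort_schema(), "stress")]
  })
}

#' Generate the imbalanced two-group study cohort
#'
#' Emulates the full published study labeling: 651 subjects who reported
#' feeling extremely stressed (high) against 2529 who reported no stress
#' (low), 3180 records in total, drawn from the [default_cohort_spec()]
#' group distributions.
#'
#' @param seed Integer seed.
#' @return A tibble of 3180 subject records.
#' @export
generate_imbalanced_study <- function(seed = 1L) {
  spec <- default_cohort_spec()
  spec$n_low <- 2529L
  spec$n_high <- 651L
  generate_cohort(spec, seed)
}
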