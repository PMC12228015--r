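# Scenario layer: named PAE inputs run through the same risk model, and
# pairwise comparison of the resulting estimates.

#' Define a PAE scenario
#'
#' A scenario is one prenatal-alcohol-exposure input (a summary proportion)
#' paired with a risk model, to be propagated to a FASD prevalence estimate
#' by [run_scenario()].
#'
#' @param label Scenario name, unique within a scenario set.
#' @param pae A [summary_proportion()] for PAE prevalence.
#' @param risk A `risk_model` (see [make_risk_model()]).
#' @param year Optional calendar year.
#' @param pae_range Optional `c(lo, hi)` across-study PAE range, converted
#'   to a prevalence range in the output.
#' @param source Free-text citation for the PAE input.
#' @return An object of class `scenario`.
#' @export
scenario <- function(label, pae, risk, year = NULL, pae_range = NULL,
                     source = "") {
  stopifnot(inherits(pae, "summary_proportion"), inherits(risk, "risk_model"))
  if (!nzchar(label)) stop("`label` must be non-empty", call. = FALSE)
  if (!is.null(pae_range)) {
    stop_if_not_proportion(pae_range, "pae_range")
    stopifnot(length(pae_range) == 2L, pae_range[1] <= pae_range[2])
  }
  structure(
    list(label = as.character(label), year = year, pae = pae, risk = risk,
         pae_range = pae_range, source = as.character(source)),
    class = "scenario"
  )
}

#' Bundle scenarios sharing a risk model
#'
#' @param scenarios List of [scenario()] objects with unique labels.
#' @param risk The shared `risk_model` (informational; each scenario
#'   already carries its own).
#' @return An object of class `scenario_set`.
#' @export
scenario_set <- function(scenarios, risk) {
  stopifnot(is.list(scenarios), length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, logical(1), "scenario")))
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("scenario labels must be unique within a set", call. = FALSE)
  }
  structure(list(scenarios = scenarios, risk = risk), class = "scenario_set")
}

#' Read a scenario set from a YAML config file
#'
#' The schema (see the shipped example at
#' `system.file("extdata", "scenarios.yaml", package = "fasdprev")`):
#'
#' ```yaml
#' risk:
#'   n_per_case: 13
#'   interval: [0.0725, 0.0790]
#'   pooled_n: 158161        # optional
#' scenarios:
#'   - label: NDSHS 2019     # required, unique
#'     year: 2019            # optional
#'     mean: 0.297           # required, proportions in [0, 1]
#'     ci_low: 0.253
#'     ci_high: 0.341
#'     range: [0.142, 0.76]  # optional PAE study range
#'     source: "..."         # optional
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `scenario_set`.
#' @export
read_scenarios <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$risk)) stop("config lacks a `risk` block", call. = FALSE)
  for (f in c("n_per_case", "interval")) {
    if (is.null(cfg$risk[[f]])) {
      stop("risk block lacks required field `", f, "`", call. = FALSE)
    }
  }
  risk <- make_risk_model(cfg$risk$n_per_case, as.numeric(cfg$risk$interval),
                          pooled_n = cfg$risk$pooled_n)
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0L) {
    stop("no scenarios defined in ", path, call. = FALSE)
  }
  sc <- lapply(cfg$scenarios, function(s) {
    for (f in c("label", "mean", "ci_low", "ci_high")) {
      if (is.null(s[[f]])) {
        stop("scenario entry lacks required field `", f, "`", call. = FALSE)
      }
    }
    scenario(
      label = s$label,
      pae = summary_proportion(s$mean, s$ci_low, s$ci_high,
                               label = paste("PAE prevalence,", s$label)),
      risk = risk, year = s$year,
      pae_range = if (!is.null(s$range)) as.numeric(s$range),
      source = if (is.null(s$source)) "" else s$source
    )
  })
  scenario_set(sc, risk)
}

#' Run one scenario
#'
#' Fits a beta distribution to the scenario's PAE summary (point mass if
#' the summary has a zero-width interval) and propagates it with the
#' scenario's risk model via [mc_prevalence()].
#'
#' @param s A [scenario()].
#' @param n_draws,seed,level Passed to [mc_prevalence()].
#' @return A labelled `prevalence_estimate`.
#' @examples
#' est <- run_scenario(default_scenarios()$scenarios[[2]],
#'                     n_draws = 1e5, seed = 1)
#' @export
run_scenario <- function(s, n_draws = 1e6, seed, level = 0.95) {
  stopifnot(inherits(s, "scenario"))
  pae <- if (s$pae$ci_high > s$pae$ci_low) fit_beta_from_summary(s$pae)
         else s$pae$mean
  mc_prevalence(pae, s$risk, n_draws = n_draws, seed = seed, level = level,
                label = s$label, range = s$pae_range)
}

#' Run every scenario in a set
#'
#' Seeds are derived deterministically as `seed + index - 1` in set order.
#'
#' @param set A `scenario_set`.
#' @param n_draws,level Passed to [run_scenario()].
#' @param seed Base integer seed.
#' @return Named list of `prevalence_estimate` objects.
#' @export
run_scenarios <- function(set, n_draws = 1e6, seed, level = 0.95) {
  stopifnot(inherits(set, "scenario_set"))
  ests <- lapply(seq_along(set$scenarios), function(i) {
    run_scenario(set$scenarios[[i]], n_draws = n_draws,
                 seed = seed + i - 1L, level = level)
  })
  names(ests) <- vapply(set$scenarios, `[[`, character(1), "label")
  ests
}

#' Compare two prevalence estimates
#'
#' Two methods are offered. `"ci_overlap"` (default) is the informal check
#' used in descriptive reporting: the difference is called not
#' statistically significant if and only if the two confidence intervals
#' intersect. Overlap checks are conservative — intervals can overlap even
#' when a formal test of the difference would reject — so the returned
#' record always names the method used. `"mc_difference"` re-runs both
#' estimates with fresh paired draws (the risk draws are shared when the
#' two estimates use the same risk model, since that uncertainty is common
#' to both) and reports the empirical `P(a - b > 0)` together with a
#' percentile interval for the difference; significance is then judged by
#' whether that interval excludes zero.
#'
#' @param a,b `prevalence_estimate` objects at the same confidence level.
#' @param method `"ci_overlap"` or `"mc_difference"`.
#' @param n_draws Draws for `"mc_difference"` (default 10^5).
#' @param seed Seed for `"mc_difference"`.
#' @return An object of class `scenario_comparison`: fields `method`,
#'   `labels`, `significant`, and for `"mc_difference"` also `p_a_gt_b`,
#'   `diff_mean`, `diff_ci`.
#' @export
compare_scenarios <- function(a, b, method = c("ci_overlap", "mc_difference"),
                              n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(a, "prevalence_estimate"),
            inherits(b, "prevalence_estimate"))
  if (a$level != b$level) {
    stop("estimates must share a confidence level to be compared",
         call. = FALSE)
  }
  out <- list(method = method, labels = c(a$label, b$label), level = a$level)
  if (method == "ci_overlap") {
    out$significant <- a$ci_low > b$ci_high || b$ci_low > a$ci_high
  } else {
    stop_if_not_count(n_draws, "n_draws", min = 1)
    same_risk <- identical(a$inputs$risk[c("mean_risk", "mc", "mc_spec")],
                           b$inputs$risk[c("mean_risk", "mc", "mc_spec")])
    d <- withr::with_seed(as.integer(seed), {
      pa <- sample_pae(a$inputs$pae, n_draws)
      pb <- sample_pae(b$inputs$pae, n_draws)
      ra <- sample_risk(a$inputs$risk, n_draws)
      rb <- if (same_risk) ra else sample_risk(b$inputs$risk, n_draws)
      pa * ra - pb * rb
    })
    a2 <- (1 - a$level) / 2
    out$p_a_gt_b <- mean(d > 0)
    out$diff_mean <- mean(d)
    out$diff_ci <- unname(stats::quantile(d, c(a2, 1 - a2), type = 7))
    out$risk_draws_shared <- same_risk
    out$n_draws <- n_draws
    out$seed <- as.integer(seed)
    out$significant <- out$diff_ci[1] > 0 || out$diff_ci[2] < 0
  }
  structure(out, class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Comparison (%s): %s vs %s\n", x$method,
              x$labels[1], x$labels[2]))
  cat(sprintf("  difference %s statistically significant\n",
              if (x$significant) "IS" else "is not"))
  if (x$method == "mc_difference") {
    cat(sprintf("  P(a > b) = %.3f; difference %s pp (%d%% CI %s, %s)\n",
                x$p_a_gt_b, format_pct(x$diff_mean), round(100 * x$level),
                format_pct(x$diff_ci[1]), format_pct(x$diff_ci[2])))
  }
  invisible(x)
}
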