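#' Empirical two-tailed 95% confidence interval
#'
#' The 2.5th and 97.5th empirical percentiles of a simulated distribution,
#' with linear interpolation between order statistics (quantile type 7).
#'
#' @param values numeric vector of length >= 40.
#' @return numeric `c(low, high)`.
#' @export
ci95 <- function(values) {
  if (length(values) < 40) stop("ci95 needs >= 40 values")
  quantile(values, c(0.025, 0.975), type = 7, names = FALSE)
}

#' Midrank percentile of an observed value in a simulated distribution
#'
#' `(#\{v < observed\} + 0.5 * #\{v == observed\}) / length(values)`.
#'
#' @param observed a single number.
#' @param values non-empty numeric vector.
#' @return the percentile, in `[0, 1]`.
#' @export
percentile_of <- function(observed, values) {
  if (!length(values)) stop("empty distribution")
  (sum(values < observed) + 0.5 * sum(values == observed)) / length(values)
}

#' Two-tailed probability from a percentile
#'
#' `p = 2 * min(percentile, 1 - percentile)`, capped at 1. A percentile of
#' exactly 0 or 1 would give p = 0, which is floored at `1 / n_runs` when
#' the null-distribution size is supplied (an observed value beyond every
#' simulated one can only be said to be beyond 1/n resolution).
#'
#' @param percentile a value in `[0, 1]`.
#' @param n_runs optional size of the simulated distribution.
#' @return the two-tailed probability, in `(0, 1]` when `n_runs` is given.
#' @export
two_tailed_p <- function(percentile, n_runs = NULL) {
  if (!is.numeric(percentile) || percentile < 0 || percentile > 1) {
    stop("percentile must lie in [0, 1]")
  }
  p <- 2 * min(percentile, 1 - percentile)
  p <- min(p, 1)
  if (p == 0 && !is.null(n_runs)) p <- 1 / n_runs
  p
}

#' Build null distributions of the three statistics under one model
#'
#' Runs `n_runs` independent simulations of the model on the tree with the
#' calibrated pull constant and computes (DSD, SK, DRS) from each run's
#' standardized extant phenotypes. Deterministic given `seed`.
#'
#' @param tree a rooted speciational `phylo` tree.
#' @param model a model name.
#' @param C calibrated pull constant.
#' @param n_runs number of simulation runs (>= 40; default 1000).
#' @param seed integer seed.
#' @return a named list (`DSD`, `SK`, `DRS`) of `null_distribution` objects,
#'   each holding the model, the statistic name, the `n_runs` values and the
#'   95% CI bounds `ci_low`, `ci_high`.
#' @export
build_null <- function(tree, model, C, n_runs = 1000, seed = NULL) {
  model <- match_model(model)
  if (n_runs < 40) stop("n_runs must be >= 40 for a 95% CI")
  sim <- simulate_tips_batch(tree, model, C, n_runs, seed = seed)
  stats <- batch_statistics(sim)
  out <- lapply(STATISTIC_NAMES, function(s) {
    v <- stats[[s]]
    ci <- ci95(v)
    structure(
      list(model = model, statistic = s, values = v,
           ci_low = ci[1L], ci_high = ci[2L]),
      class = "null_distribution"
    )
  })
  names(out) <- STATISTIC_NAMES
  out
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution: %s under %s (%d runs)\n  95%% CI [%.4f, %.4f]\n",
              x$statistic, x$model, length(x$values), x$ci_low, x$ci_high))
  invisible(x)
}

#' Test observed statistics against every model's null distribution
#'
#' For each (model, statistic) pair: the midrank percentile of the observed
#' value in the model's null distribution, the reconstructed two-tailed
#' probability, and the rejection flag. A model is rejected for a statistic
#' when the observed value falls outside the model's two-tailed 95%
#' confidence interval.
#'
#' @param observed a `summary_statistics` object from [compute_statistics()].
#' @param nulls a named list: one [build_null()] result per model, covering
#'   all three models.
#' @return a data frame with columns `model`, `statistic`, `observed`,
#'   `percentile`, `p_two_tailed`, `rejected`.
#' @export
assess_models <- function(observed, nulls) {
  if (!all(MODEL_NAMES %in% names(nulls))) {
    stop("nulls must contain all models: ", paste(MODEL_NAMES, collapse = ", "))
  }
  obs <- c(DSD = observed$dsd, SK = observed$sk, DRS = observed$drs)
  rows <- list()
  for (model in MODEL_NAMES) {
    for (s in STATISTIC_NAMES) {
      nd <- nulls[[model]][[s]]
      if (is.null(nd)) stop("missing null for ", model, " / ", s)
      pct <- percentile_of(obs[[s]], nd$values)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, statistic = s, observed = obs[[s]],
        percentile = pct,
        p_two_tailed = two_tailed_p(pct, n_runs = length(nd$values)),
        rejected = obs[[s]] < nd$ci_low || obs[[s]] > nd$ci_high,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Pairwise model discriminability (type-II error matrix)
#'
#' For every ordered pair of models (A, B) and every statistic: the
#' fraction of A's simulated values that fall inside B's two-tailed 95%
#' confidence interval. This is the probability of type II error when
#' trying to tell the models apart with that statistic; 1 minus it is the
#' discriminating power. For A == B it is about 0.95 by construction.
#'
#' @param nulls a named list: one [build_null()] result per model.
#' @return a data frame with columns `generating`, `reference`, `statistic`,
#'   `type2_probability`.
#' @export
discrimination_matrix <- function(nulls) {
  models <- names(nulls)
  rows <- list()
  for (a in models) {
    for (b in models) {
      for (s in STATISTIC_NAMES) {
        na_ <- nulls[[a]][[s]]; nb <- nulls[[b]][[s]]
        frac <- mean(na_$values >= nb$ci_low & na_$values <= nb$ci_high)
        rows[[length(rows) + 1L]] <- data.frame(
          generating = a, reference = b, statistic = s,
          type2_probability = frac, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
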