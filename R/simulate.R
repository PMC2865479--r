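#' Brownian step for one lineage
#'
#' Adds independent Normal(0, 1) increments to the male and female scores of
#' a lineage. The increment standard deviation is fixed at 1: under a
#' speciational clock the scale is arbitrary because the downstream
#' statistics are computed on standardized phenotypes.
#'
#' @param state numeric vector `c(male, female)`.
#' @param increments optional numeric vector `c(r_male, r_female)` of
#'   pre-drawn increments (used for reproducible hand traces); drawn from
#'   `rnorm(2)` when `NULL`.
#' @return the updated `c(male, female)` state.
#' @export
brownian_step <- function(state, increments = NULL) {
  stopifnot(is.numeric(state), length(state) == 2L, all(is.finite(state)))
  if (is.null(increments)) increments <- rnorm(2L)
  state + increments
}

#' Block reversed dimorphism
#'
#' If the female score exceeds the male score the state is reset so that
#' female <= male, in the model-specific way: under constraint on females
#' the female is set to the male value; under constraint on males the male
#' is raised to the female value; under mutual constraint both are set to
#' their mean. States already satisfying female <= male are untouched.
#'
#' @param model a model name (see [pull_max()]).
#' @param state numeric `c(male, female)`.
#' @return the corrected `c(male, female)` state, with female <= male.
#' @export
block_reversal <- function(model, state) {
  model <- match_model(model)
  m <- state[1L]; f <- state[2L]
  if (f > m) {
    switch(model,
      constraint_on_females = f <- m,
      constraint_on_males   = m <- f,
      mutual_constraint     = { mid <- (m + f) / 2; m <- mid; f <- mid }
    )
  }
  c(m, f)
}

#' Pull the constrained sex towards the other
#'
#' Moves the constrained sex by a proportion `C` of the current between-sex
#' difference: under constraint on females only the female moves (towards
#' the male), under constraint on males only the male moves, and under
#' mutual constraint both move simultaneously from the pre-update values,
#' preserving their mean. `C = 0` is the identity; `C = pull_max(model)`
#' makes the sexes meet exactly.
#'
#' @param model a model name.
#' @param state numeric `c(male, female)` with female <= male.
#' @param C pull constant in `[0, pull_max(model)]`.
#' @return the updated `c(male, female)` state.
#' @export
constraint_pull <- function(model, state, C) {
  model <- match_model(model)
  if (!is.numeric(C) || length(C) != 1L || C < 0 || C > pull_max(model)) {
    stop("pull constant C must lie in [0, ", pull_max(model), "] for ", model)
  }
  m <- state[1L]; f <- state[2L]
  # convex-combination form: exact identity at C = 0 and exact meeting at
  # C = pull_max; a final clamp absorbs any last-ulp rounding overshoot so
  # the female <= male invariant holds exactly
  switch(model,
    constraint_on_females = f <- min((1 - C) * f + C * m, m),
    constraint_on_males   = m <- max((1 - C) * m + C * f, f),
    mutual_constraint     = {
      m2 <- (1 - C) * m + C * f
      f2 <- (1 - C) * f + C * m
      m <- max(m2, f2); f <- min(m2, f2)
    }
  )
  c(m, f)
}

# Vectorized batch simulator: evolves all runs simultaneously, one column
# per run. Returns tip score matrices. `increments` (a list with elements
# `male`, `female`, each n_edges x n_runs) supports common random numbers
# across candidate C values during calibration; when NULL they are drawn
# from `seed`. `pure_brownian = TRUE` disables the block and pull steps (a
# test hook for checking that Brownian motion alone leaves the sexes
# uncorrelated).
simulate_tips_batch <- function(tree, model, C, n_runs, seed = NULL,
                                increments = NULL, pure_brownian = FALSE) {
  model <- match_model(model)
  tree <- validate_tree(tree)
  if (!is_speciational(tree)) {
    stop("tree is not speciational; convert with as_speciational() first")
  }
  if (!pure_brownian && (C < 0 || C > pull_max(model))) {
    stop("pull constant C must lie in [0, ", pull_max(model), "] for ", model)
  }
  edges <- preorder_edges(tree)
  n_edges <- nrow(edges)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode

  if (is.null(increments)) {
    if (!is.null(seed)) set.seed(seed)
    increments <- list(
      male = matrix(rnorm(n_edges * n_runs), n_edges, n_runs),
      female = matrix(rnorm(n_edges * n_runs), n_edges, n_runs)
    )
  }
  stopifnot(nrow(increments$male) == n_edges, ncol(increments$male) >= n_runs)

  M <- matrix(0, n_node, n_runs)
  F_ <- matrix(0, n_node, n_runs)
  for (e in seq_len(n_edges)) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    m <- M[par, ] + increments$male[e, seq_len(n_runs)]
    f <- F_[par, ] + increments$female[e, seq_len(n_runs)]
    if (!pure_brownian) {
      bad <- f > m
      if (any(bad)) {
        switch(model,
          constraint_on_females = f[bad] <- m[bad],
          constraint_on_males   = m[bad] <- f[bad],
          mutual_constraint     = {
            mid <- (m[bad] + f[bad]) / 2
            m[bad] <- mid; f[bad] <- mid
          }
        )
      }
      # convex-combination pull with an exact clamp (see constraint_pull)
      switch(model,
        constraint_on_females = f <- pmin((1 - C) * f + C * m, m),
        constraint_on_males   = m <- pmax((1 - C) * m + C * f, f),
        mutual_constraint     = {
          m2 <- (1 - C) * m + C * f
          f2 <- (1 - C) * f + C * m
          m <- pmax(m2, f2); f <- pmin(m2, f2)
        }
      )
    }
    M[ch, ] <- m
    F_[ch, ] <- f
  }
  list(
    species = tree$tip.label,
    male = M[seq_len(n_tip), , drop = FALSE],
    female = F_[seq_len(n_tip), , drop = FALSE]
  )
}

# Pearson cross-sex correlation of every run (column) of a batch.
tip_correlations <- function(sim) {
  M <- sim$male; F_ <- sim$female
  n <- nrow(M)
  Mc <- sweep(M, 2, colMeans(M))
  Fc <- sweep(F_, 2, colMeans(F_))
  num <- colSums(Mc * Fc)
  den <- sqrt(colSums(Mc^2) * colSums(Fc^2))
  num / den
}

#' Simulate extant phenotypes under a constraint model
#'
#' Evolves a (male, female) score pair from the root state (0, 0) along
#' every branch of a speciational tree in root-to-tip order. Each branch
#' applies three steps in sequence: a Brownian step (independent N(0, 1)
#' increments per sex), the model's block of reversed dimorphism, and the
#' model's pull of magnitude `C`. Only tip values are returned; all tips
#' satisfy female <= male.
#'
#' @param tree a rooted speciational `phylo` tree.
#' @param model a model name.
#' @param C pull constant in `[0, pull_max(model)]`.
#' @param seed integer seed; the run is deterministic given
#'   `(tree, model, C, seed)`.
#' @return a [tip_phenotypes()] data frame (`species`, `male`, `female`).
#' @export
simulate_tips <- function(tree, model, C, seed = NULL) {
  sim <- simulate_tips_batch(tree, model, C, n_runs = 1L, seed = seed)
  tip_phenotypes(sim$species, sim$male[, 1L], sim$female[, 1L])
}

#' Per-species extant phenotypes
#'
#' Light constructor/validator for the package's score table: one row per
#' species with that species' male and female ornament scores.
#'
#' @param species character vector of unique species labels.
#' @param male,female numeric score vectors aligned with `species`.
#' @return a `data.frame` of class `tip_phenotypes`.
#' @export
tip_phenotypes <- function(species, male, female) {
  species <- as.character(species)
  if (length(species) != length(male) || length(male) != length(female)) {
    stop("species, male and female must have equal length")
  }
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (!all(is.finite(male)) || !all(is.finite(female))) {
    stop("scores must be finite")
  }
  structure(
    data.frame(species = species, male = as.numeric(male),
               female = as.numeric(female), stringsAsFactors = FALSE),
    class = c("tip_phenotypes", "data.frame")
  )
}

#' Read / write a tip score table
#'
#' Tab-separated with header `species	male	female`.
#'
#' @param file path to a TSV file.
#' @return a [tip_phenotypes()] data frame.
#' @export
read_tip_scores <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("species", "male", "female")
  if (!all(need %in% names(d))) {
    stop("score table must have columns: ", paste(need, collapse = ", "))
  }
  tip_phenotypes(d$species, d$male, d$female)
}

#' @rdname read_tip_scores
#' @param tips a [tip_phenotypes()] data frame.
#' @export
write_tip_scores <- function(tips, file) {
  write.table(tips, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Calibrate the pull constant to a target cross-sex correlation
#'
#' Finds `C` such that the mean (over replicate simulations) Pearson
#' correlation between male and female tip scores equals `target_r`. The
#' same Brownian increments are reused for every candidate `C` (common
#' random numbers), which makes the mean-correlation curve a deterministic
#' nondecreasing function of `C`; bisection then converges reliably. If
#' `target_r` lies below the baseline correlation at `C = 0` (the block
#' step alone already induces positive correlation) the target is
#' unachievable and an error reports the baseline.
#'
#' @param tree a rooted speciational `phylo` tree.
#' @param model a model name.
#' @param target_r target mean correlation, in `(0, 1]`.
#' @param replicates simulations per candidate `C` (default 500).
#' @param tolerance convergence tolerance on the mean correlation
#'   (default 0.005).
#' @param max_iterations bisection cap (default 60).
#' @param seed integer seed for the shared increments.
#' @return the calibrated `C` in `[0, pull_max(model)]`.
#' @export
calibrate_pull_constant <- function(tree, model, target_r,
                                    replicates = 500, tolerance = 0.005,
                                    max_iterations = 60, seed = 1L) {
  model <- match_model(model)
  tree <- validate_tree(tree)
  if (!is.numeric(target_r) || length(target_r) != 1L ||
      target_r <= 0 || target_r > 1) {
    stop("target_r must lie in (0, 1]")
  }
  edges <- preorder_edges(tree)
  set.seed(seed)
  inc <- list(
    male = matrix(rnorm(nrow(edges) * replicates), nrow(edges), replicates),
    female = matrix(rnorm(nrow(edges) * replicates), nrow(edges), replicates)
  )
  c_max <- pull_max(model)
  mean_r <- function(C) {
    mean(tip_correlations(
      simulate_tips_batch(tree, model, C, replicates, increments = inc)
    ))
  }
  baseline <- mean_r(0)
  if (target_r < baseline - tolerance) {
    stop(sprintf(
      paste0("unachievable target correlation %.3f: the block step alone ",
             "yields a baseline mean correlation of %.3f at C = 0"),
      target_r, baseline))
  }
  if (abs(baseline - target_r) <= tolerance) return(0)
  top <- mean_r(c_max)
  if (target_r >= top - tolerance) return(c_max)

  lo <- 0; hi <- c_max
  mid <- (lo + hi) / 2
  for (i in seq_len(max_iterations)) {
    mid <- (lo + hi) / 2
    r <- mean_r(mid)
    if (abs(r - target_r) <= tolerance) return(mid)
    if (r < target_r) lo <- mid else hi <- mid
  }
  warning("calibration hit the iteration cap; returning last midpoint")
  mid
}
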