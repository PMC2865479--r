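#' Broken-stick component retention
#'
#' Retains the leading principal components whose variance share exceeds
#' the broken-stick expectation: component j is retained (together with all
#' earlier ones) when `eigenvalue_j / sum(eigenvalues) >=
#' (1/p) * sum(1/i for i in j..p)`. Retention is consecutive from the first
#' component; the count stops at the first component that falls below its
#' expectation.
#'
#' @param eigenvalues nonnegative eigenvalues in descending order, from a
#'   correlation-matrix PCA of `p` traits (they sum to `p`).
#' @return the number of retained components (possibly 0).
#' @export
broken_stick_retention <- function(eigenvalues) {
  p <- length(eigenvalues)
  if (!p) stop("empty eigenvalue vector")
  props <- eigenvalues / sum(eigenvalues)
  expected <- vapply(seq_len(p), function(j) sum(1 / (j:p)) / p, numeric(1))
  ok <- props >= expected
  if (!ok[1L]) return(0L)
  # first failure ends the consecutive run
  which.max(c(!ok, TRUE)) - 1L
}

#' Kaiser (eigenvalue > 1) component retention
#'
#' @inheritParams broken_stick_retention
#' @return the number of eigenvalues larger than 1.
#' @export
kaiser_retention <- function(eigenvalues) {
  if (!length(eigenvalues)) stop("empty eigenvalue vector")
  sum(eigenvalues > 1)
}

#' Eigenvalue-weighted composite ornament scores
#'
#' Runs a correlation-matrix PCA on a species x trait measurement matrix
#' (columns are standardized, so per-trait units are irrelevant), retains
#' components by the chosen criterion, orients each retained component so
#' that its loading sum is positive (higher composite score = larger
#' standardized trait values on average), and returns per-species scores
#' `score_s = sum_j eigenvalue_j * component_score_{s,j}` over the retained
#' components.
#'
#' When the broken-stick criterion retains nothing the function stops and
#' suggests the Kaiser fallback: a leading eigenvalue can fail the
#' broken-stick expectation yet still exceed 1 (the typical situation for
#' weakly structured trait sets), and the fallback must be an explicit
#' analyst choice.
#'
#' @param x a numeric species x trait matrix, or a data frame whose first
#'   column `species` labels rows (an optional `sex` column is carried
#'   through; scores are computed jointly across all rows so that male and
#'   female rows share one PCA space).
#' @param criterion `"broken_stick"` (default) or `"kaiser"`.
#' @return a list of class `composite_scores`: `species`, `score`,
#'   `retained`, `criterion`, `variance_explained`, `eigenvalues`.
#' @export
composite_score <- function(x, criterion = c("broken_stick", "kaiser")) {
  criterion <- match.arg(criterion)
  species <- NULL; sex <- NULL
  if (is.data.frame(x)) {
    if ("species" %in% names(x)) { species <- as.character(x$species) }
    if ("sex" %in% names(x)) { sex <- as.character(x$sex) }
    x <- as.matrix(x[setdiff(names(x), c("species", "sex"))])
    storage.mode(x) <- "double"
  }
  if (anyNA(x)) stop("measurement matrix contains missing values")
  if (is.null(species)) species <- rownames(x)
  if (is.null(species)) species <- paste0("row", seq_len(nrow(x)))
  p <- ncol(x)
  if (p < 1) stop("need at least one trait column")
  if (any(apply(x, 2, sd) == 0)) stop("constant trait column: cannot standardize")

  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pca$sdev^2
  k <- switch(criterion,
    broken_stick = broken_stick_retention(eig),
    kaiser = kaiser_retention(eig)
  )
  if (k < 1) {
    stop("no significant components under the '", criterion,
         "' criterion; consider criterion = \"kaiser\"")
  }
  if (k >= nrow(x)) stop("more retained components than species")
  scores <- pca$x[, seq_len(k), drop = FALSE]
  loads <- pca$rotation[, seq_len(k), drop = FALSE]
  flip <- colSums(loads) < 0
  scores[, flip] <- -scores[, flip]
  composite <- as.numeric(scores %*% eig[seq_len(k)])
  structure(
    list(species = species, sex = sex, score = composite, retained = k,
         criterion = criterion,
         variance_explained = sum(eig[seq_len(k)]) / sum(eig),
         eigenvalues = eig),
    class = "composite_scores"
  )
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("composite ornament scores: %d species, %d PC(s) by %s (%.0f%% variance)\n",
              length(x$score), x$retained, x$criterion,
              100 * x$variance_explained))
  invisible(x)
}

#' Read a species x trait measurement matrix
#'
#' CSV with header `species,<trait1>,<trait2>,...` and optionally a `sex`
#' column.
#'
#' @param file path to a CSV file.
#' @return a data frame suitable for [composite_score()].
#' @export
read_measurements <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  if (!"species" %in% names(d)) stop("measurement CSV must have a 'species' column")
  d
}
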