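#' Generate a random speciational tree (Yule topology)
#'
#' Grows a rooted binary topology by uniform-random tip splitting (the Yule
#' pure-birth process restricted to topology), then assigns unit branch
#' lengths. Used as a stand-in clade tree when the real phylogeny is not
#' supplied; any user tree can replace it in every downstream function.
#'
#' @param n_tips number of tips (>= 2). Default 23, a typical single-genus
#'   clade size.
#' @param seed integer seed; the tree is deterministic given `seed`.
#' @return a rooted speciational `phylo` with tips `t1..t<n>`.
#' @export
gen_yule_tree <- function(n_tips = 23, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  set.seed(seed)
  children <- vector("list", 2L * n_tips - 1L)
  children[[1L]] <- c(2L, 3L)
  leaves <- c(2L, 3L)
  n_node <- 3L
  while (length(leaves) < n_tips) {
    k <- sample.int(length(leaves), 1L)
    v <- leaves[k]
    children[[v]] <- c(n_node + 1L, n_node + 2L)
    leaves <- c(leaves[-k], n_node + 1L, n_node + 2L)
    n_node <- n_node + 2L
  }
  label_counter <- 0L
  subtree <- function(v) {
    if (is.null(children[[v]])) {
      label_counter <<- label_counter + 1L
      paste0("t", label_counter)
    } else {
      paste0("(", subtree(children[[v]][1L]), ",",
             subtree(children[[v]][2L]), ")")
    }
  }
  nwk <- paste0(subtree(1L), ";")
  as_speciational(ape::read.tree(text = nwk))
}

#' Generate a pseudo-observed study dataset
#'
#' Produces a score table under a chosen generating model: the pull
#' constant is first calibrated so that tip male/female scores correlate at
#' `target_r` on average, then one simulation run is drawn as the
#' "observed" data. No species shows reversed dimorphism (female <= male
#' everywhere), as in the simulated models.
#'
#' @param tree a rooted speciational `phylo` tree.
#' @param model generating model name.
#' @param target_r target cross-sex correlation in `(0, 1]` (the package's
#'   reference regimes are 0.893, 0.848 and 0.560 — strong, strong and
#'   moderate similarity between the sexes).
#' @param seed master seed (calibration and the draw use derived sub-seeds).
#' @param calibration optional list of overrides passed to
#'   [calibrate_pull_constant()] (`replicates`, `tolerance`,
#'   `max_iterations`).
#' @return a [tip_phenotypes()] data frame with attributes `model`, `C` and
#'   `target_r`.
#' @export
gen_study_dataset <- function(tree, model = "constraint_on_females",
                              target_r = 0.893, seed = 1L,
                              calibration = list()) {
  model <- match_model(model)
  args <- c(list(tree = tree, model = model, target_r = target_r,
                 seed = derive_seed(seed, 1L)), calibration)
  C <- do.call(calibrate_pull_constant, args)
  tips <- simulate_tips(tree, model, C, seed = derive_seed(seed, 2L))
  attr(tips, "model") <- model
  attr(tips, "C") <- C
  attr(tips, "target_r") <- target_r
  tips
}

#' Generate a latent-factor measurement matrix
#'
#' Species x trait values built as `factor scores x loading pattern +
#' Gaussian noise`: each trait loads on exactly one of `n_factors`
#' independent standard-normal latent factors with coefficient `loading`,
#' plus `Normal(0, noise_sd)` noise. With the defaults (loading 0.8, noise
#' SD 0.6) a correlation-matrix PCA of the result typically retains
#' `n_factors` components under the broken-stick criterion, which makes the
#' matrix a controlled fixture for composite scoring.
#'
#' @param n_species number of rows (> `n_traits`).
#' @param n_traits number of measured traits (>= 2).
#' @param n_factors number of latent factors (>= 1, < `n_traits`).
#' @param loading common factor loading.
#' @param noise_sd residual noise standard deviation.
#' @param seed integer seed.
#' @return a data frame: `species` column plus `n_traits` numeric columns.
#' @export
gen_measurement_matrix <- function(n_species, n_traits, n_factors = 1,
                                   loading = 0.8, noise_sd = 0.6, seed = 1L) {
  if (n_traits < 2) stop("n_traits must be >= 2")
  if (n_factors < 1 || n_factors >= n_traits) {
    stop("need 1 <= n_factors < n_traits")
  }
  if (n_species <= n_traits) stop("need n_species > n_traits")
  set.seed(seed)
  fac <- matrix(rnorm(n_species * n_factors), n_species, n_factors)
  L <- matrix(0, n_traits, n_factors)
  L[cbind(seq_len(n_traits), ((seq_len(n_traits) - 1L) %% n_factors) + 1L)] <- loading
  values <- fac %*% t(L) + matrix(rnorm(n_species * n_traits, sd = noise_sd),
                                  n_species, n_traits)
  out <- data.frame(species = paste0("s", seq_len(n_species)), values,
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("trait", seq_len(n_traits))
  attr(out, "factors") <- fac
  out
}
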