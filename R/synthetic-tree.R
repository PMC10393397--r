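# Phylogeny + trait simulation: pure-birth ultrametric trees with Brownian
# trait evolution (lambda-scaled), a habitat fixed effect, and the ground
# truth returned alongside.

#' Simulate an ultrametric tree and habitat-structured species traits
#'
#' Grows a pure-birth tree, assigns a fraction of tips to one habitat, and
#' draws one trait value per species as
#' `intercept + beta_habitat * I(habitat) + e`, where `e` is multivariate
#' normal with covariance `sigma2_bm * C_lambda`: `C` is the Brownian
#' shared-path-length matrix of the tree and its off-diagonals are scaled
#' by `lambda_true` (Pagel's lambda; 0 = star independence, 1 = Brownian).
#'
#' @param n_species number of tips (>= 3; PGLS is undefined below that).
#' @param habitat_split fraction of species assigned to the focal
#'   (`"rocky"`) habitat; the rest are `"mangrove"`.
#' @param beta_habitat habitat effect added to rocky-shore species, trait
#'   units.
#' @param sigma2_bm Brownian rate (trait variance per unit branch length).
#' @param lambda_true Pagel's lambda in `[0, 1]` used to generate the
#'   residual covariance.
#' @param intercept baseline trait value.
#' @param seed optional integer seed.
#' @param tip_prefix prefix for generated species names.
#' @return list with `tree` (an `ape::phylo`), `traits` (data frame
#'   `species`, `habitat`, `value`) and `truth` (the generating parameters).
#' @export
simulate_tree_and_traits <- function(n_species, habitat_split = 0.5,
                                     beta_habitat = 0, sigma2_bm = 1,
                                     lambda_true = 1, intercept = 0,
                                     seed = NULL, tip_prefix = "sp") {
  if (n_species < 3)
    stop("n_species must be >= 3 (PGLS undefined for fewer species)")
  if (lambda_true < 0 || lambda_true > 1)
    stop("lambda_true must be in [0, 1]")
  with_seed(seed, {
    tree <- ape::rphylo(n_species, birth = 1, death = 0)
    tree$tip.label <- sprintf("%s%02d", tip_prefix, seq_len(n_species))
    n_rocky <- round(n_species * habitat_split)
    habitat <- rep("mangrove", n_species)
    habitat[sample.int(n_species, n_rocky)] <- "rocky"
    cl <- phylo_cov(tree, lambda_true)
    e <- if (sigma2_bm > 0) {
      drop(crossprod(chol(sigma2_bm * cl), rnorm(n_species)))
    } else {
      numeric(n_species)
    }
    value <- intercept + beta_habitat * (habitat == "rocky") + e
    traits <- data.frame(species = tree$tip.label, habitat = habitat,
                         value = value, row.names = NULL)
    list(tree = tree, traits = traits,
         truth = list(beta_habitat = beta_habitat, sigma2_bm = sigma2_bm,
                      lambda_true = lambda_true, intercept = intercept))
  })
}
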