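test_that("Newick parsing handles the basic cases", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))
  expect_error(read_newick("(A:1,B:1"), "malformed")
  expect_error(read_newick("(A:1,:1);"), "unlabeled")
  expect_error(read_newick("(A:1,A:1,B:1);"), "duplicate")
})

test_that("Newick round-trip preserves the path-length matrix", {
  set.seed(12)
  tree <- ape::rtree(50)
  back <- read_newick(write_newick(tree))
  d0 <- cophenetic(tree)
  d1 <- cophenetic(back)[rownames(d0), colnames(d0)]
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("three-taxon neighbour joining matches the closed form", {
  d <- matrix(c(0, 3, 5,
                3, 0, 6,
                5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  len <- setNames(tree$edge.length,
                  tree$tip.label[tree$edge[, 2]])
  expect_equal(len[["a"]], (3 + 5 - 6) / 2)
  expect_equal(len[["b"]], (3 + 6 - 5) / 2)
  expect_equal(len[["c"]], (5 + 6 - 3) / 2)
})

test_that("additive matrices are recovered exactly", {
  set.seed(13)
  for (n in c(4, 5, 8)) {
    tree <- ape::rtree(n)
    d <- cophenetic(tree)
    rec <- nj_tree(d)
    expect_equal(cophenetic(rec)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::unroot(tree), rec), 0)
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(runif(9), 3, 3)
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
})

test_that("lambda scales the off-diagonal phylogenetic covariances", {
  set.seed(14)
  tree <- ape::rcoal(8)  # ultrametric
  c0 <- phylo_cov(tree, 0)
  c1 <- phylo_cov(tree, 1)
  ch <- phylo_cov(tree, 0.5)
  expect_true(all(c0[upper.tri(c0)] == 0))
  expect_equal(diag(c0), diag(c1))
  expect_equal(unname(diag(c1)), rep(max(diag(c1)), 8), tolerance = 1e-8)
  expect_equal(ch[upper.tri(ch)], c1[upper.tri(c1)] / 2)
  expect_error(phylo_cov(tree, 1, species = c("nope", tree$tip.label)),
               "nope")
})

test_that("the star model reproduces ordinary least squares", {
  sim <- simulate_tree_and_traits(10, beta_habitat = 2, sigma2_bm = 1,
                                  lambda_true = 0, seed = 15)
  f <- pgls_fit(sim$traits, sim$tree, model = "star")
  ols <- lm(value ~ habitat, data = sim$traits)
  expect_equal(unname(f$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$lambda, 0)
})

test_that("a noise-free habitat effect is estimated exactly", {
  sim <- simulate_tree_and_traits(8, beta_habitat = 3, sigma2_bm = 0,
                                  intercept = 1, seed = 16)
  for (m in c("star", "brownian")) {
    f <- pgls_fit(sim$traits, sim$tree, model = m)
    expect_equal(unname(f$beta), c(1, 3), tolerance = 1e-9)
  }
})

test_that("the Pagel likelihood nests both fixed-lambda endpoints", {
  for (i in 1:25) {
    sim <- simulate_tree_and_traits(12, beta_habitat = 1, sigma2_bm = 1,
                                    lambda_true = runif(1), seed = 600 + i)
    ll <- vapply(c("star", "brownian", "pagel"), function(m)
      pgls_fit(sim$traits, sim$tree, model = m)$log_lik, 1)
    expect_gte(ll[["pagel"]], max(ll[["star"]], ll[["brownian"]]) - 1e-6)
  }
})

test_that("GLS equals OLS on whitened data", {
  sim <- simulate_tree_and_traits(12, beta_habitat = 1.5, sigma2_bm = 1,
                                  lambda_true = 1, seed = 17)
  f <- pgls_fit(sim$traits, sim$tree, model = "brownian")
  cmat <- phylo_cov(sim$tree, 1, species = sim$traits$species)
  l <- chol(cmat)
  xw <- backsolve(l, model.matrix(~habitat, sim$traits), transpose = TRUE)
  yw <- backsolve(l, sim$traits$value, transpose = TRUE)
  expect_equal(unname(f$beta), unname(coef(lm(yw ~ xw - 1))),
               tolerance = 1e-8)
})

test_that("pgls matches the nlme/corPagel maximum-likelihood fit", {
  sim <- simulate_tree_and_traits(12, beta_habitat = 1.5, sigma2_bm = 0.5,
                                  lambda_true = 0.7, seed = 7)
  d <- sim$traits
  rownames(d) <- d$species
  f <- pgls_fit(d, sim$tree, model = "pagel")
  g <- nlme::gls(value ~ habitat, data = d,
                 correlation = ape::corPagel(0.5, sim$tree, form = ~species),
                 method = "ML")
  expect_equal(f$lambda,
               unname(coef(g$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(f$log_lik, as.numeric(logLik(g)), tolerance = 1e-5)
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-5)
})

test_that("AICc weights follow the closed form and sum to one", {
  mk <- function(model, aicc, y) structure(
    list(model = model, lambda = 0, log_lik = 0, aicc = aicc, y = y),
    class = "pgls_fit")
  y <- 1:5
  cmp <- compare_models(list(mk("star", 10, y), mk("brownian", 12, y)))
  expect_equal(sum(cmp$wAICc), 1, tolerance = 1e-12)
  expect_equal(cmp$wAICc, c(0.7310586, 0.2689414), tolerance = 1e-6)
  # equal AICc -> equal weights; invariance to a constant shift
  cmp2 <- compare_models(list(mk("star", 7, y), mk("brownian", 7, y)))
  expect_equal(cmp2$wAICc, c(0.5, 0.5))
  cmp3 <- compare_models(list(mk("star", 110, y), mk("brownian", 112, y)))
  expect_equal(cmp3$wAICc, cmp$wAICc, tolerance = 1e-12)
  # differing data are refused
  expect_error(compare_models(list(mk("star", 10, y),
                                   mk("brownian", 12, y + 1))),
               "same data")
})

test_that("tree/trait simulation honours its degenerate settings", {
  sim0 <- simulate_tree_and_traits(6, beta_habitat = 2, sigma2_bm = 0,
                                   seed = 18)
  expect_equal(sim0$traits$value,
               2 * (sim0$traits$habitat == "rocky"), tolerance = 1e-12)
  expect_true(ape::is.ultrametric(sim0$tree, tol = 1e-8))
  expect_error(simulate_tree_and_traits(2), "n_species")
  expect_error(simulate_tree_and_traits(5, lambda_true = 1.2), "lambda")
})
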