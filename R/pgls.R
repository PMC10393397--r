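# Phylogenetic generalized least squares under star, Brownian and Pagel
# lambda covariance models, compared by AICc weights.

#' Lambda-scaled phylogenetic covariance matrix
#'
#' The Brownian covariance `C[i, j]` is the shared root-to-MRCA path
#' length of tips i and j; Pagel's lambda multiplies the off-diagonal
#' entries.  `lambda = 0` gives a diagonal matrix of root-to-tip depths
#' (the star model), `lambda = 1` the full Brownian matrix.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param lambda scalar in `[0, 1]`.
#' @param species optional character vector; the matrix is restricted and
#'   reordered to these tips, erroring on any that are missing.
#' @return a symmetric covariance matrix with tip labels.
#' @export
phylo_cov <- function(tree, lambda, species = NULL) {
  stopifnot(inherits(tree, "phylo"), lambda >= 0, lambda <= 1)
  cmat <- ape::vcv(tree)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(cmat))
    if (length(missing))
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    cmat <- cmat[species, species, drop = FALSE]
  }
  out <- lambda * cmat
  diag(out) <- diag(cmat)
  out
}

# GLS core for a fixed covariance matrix: ML estimates, profiled sigma^2,
# log-likelihood and conventional t statistics (df = n - rank(X)).
.gls_core <- function(y, x_mat, cmat) {
  n <- length(y)
  cl <- chol(cmat)
  xw <- backsolve(cl, x_mat, transpose = TRUE)
  yw <- backsolve(cl, y, transpose = TRUE)
  qr_x <- qr(xw)
  beta <- qr.coef(qr_x, yw)
  r <- yw - xw %*% beta
  rss <- sum(r^2)
  p_x <- qr_x$rank
  sig2_ml <- rss / n
  log_lik <- -0.5 * (n * log(2 * pi * sig2_ml) +
                       2 * sum(log(diag(cl))) + n)
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * rss / (n - p_x))
  list(beta = drop(beta), se = se, rss = rss, sigma2_ml = sig2_ml,
       log_lik = log_lik, df = n - p_x, n = n)
}

#' Phylogenetic regression of species means on habitat
#'
#' Fits `value ~ habitat` by generalized least squares with residual
#' covariance `sigma^2 * C(lambda)` on the tree: the star model fixes
#' `lambda = 0` (phylogeny ignored), the Brownian model fixes `lambda = 1`,
#' and the Pagel model maximizes the ML likelihood over `lambda` in
#' `[0, 1]` by bounded 1-D search (endpoints included).  The likelihood is
#' ML (not REML) so AICc is comparable across fixed- and estimated-lambda
#' models; AICc counts the residual variance, and lambda for the Pagel
#' model, among the parameters.
#'
#' @param data data frame with one row per species: columns `species`, a
#'   grouping/predictor column and a trait value column.
#' @param tree `ape::phylo` whose tips cover `data$species`.
#' @param model one of `"star"`, `"brownian"`, `"pagel"`.
#' @param trait_col,group_col names of the value and predictor columns.
#' @return an object of class `pgls_fit` with coefficients, standard
#'   errors, t statistics (df = n - rank(X)), two-sided p-values, lambda,
#'   the ML log-likelihood, AICc and bookkeeping fields.
#' @export
pgls_fit <- function(data, tree, model = c("star", "brownian", "pagel"),
                     trait_col = "value", group_col = "habitat") {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), "species" %in% names(data),
            trait_col %in% names(data), group_col %in% names(data))
  if (anyDuplicated(data$species))
    stop("pgls_fit expects one value per species; average first ",
         "(see species_means())")
  n <- nrow(data)
  if (n < 3) stop("need at least 3 species")
  y <- data[[trait_col]]
  grp <- factor(data[[group_col]])
  x_mat <- model.matrix(~grp)
  colnames(x_mat) <- c("(Intercept)",
                       paste0(group_col, levels(grp)[-1]))
  if (qr(x_mat)$rank < ncol(x_mat)) stop("design matrix is rank deficient")

  cov_at <- function(lam) phylo_cov(tree, lam, species = data$species)
  fit_at <- function(lam) .gls_core(y, x_mat, cov_at(lam))

  if (model == "star") {
    lambda <- 0
    core <- fit_at(0)
  } else if (model == "brownian") {
    lambda <- 1
    core <- fit_at(1)
  } else {
    opt <- optimize(function(l) fit_at(l)$log_lik, c(0, 1),
                    maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    ll <- c(fit_at(0)$log_lik, opt$objective, fit_at(1)$log_lik)
    lambda <- cand[which.max(ll)]
    core <- fit_at(lambda)
  }

  p <- ncol(x_mat) + 1L + (model == "pagel")
  aicc_ok <- (core$n - p - 1) > 0
  aicc <- if (aicc_ok) {
    -2 * core$log_lik + 2 * p + 2 * p * (p + 1) / (core$n - p - 1)
  } else {
    NA_real_
  }
  t_stat <- core$beta / core$se
  structure(list(model = model, lambda = lambda,
                 beta = core$beta, se = core$se, t_stat = t_stat,
                 df = core$df,
                 p_value = 2 * pt(abs(t_stat), core$df, lower.tail = FALSE),
                 log_lik = core$log_lik, sigma2_ml = core$sigma2_ml,
                 aicc = aicc, aicc_ok = aicc_ok,
                 n = core$n, n_params = p,
                 trait_col = trait_col, group_col = group_col,
                 y = setNames(y, data$species)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s model, lambda = %.3g): logLik = %.3f, AICc = %.3f\n",
              x$model, x$lambda, x$log_lik, x$aicc))
  tab <- data.frame(beta = x$beta, se = x$se, t = x$t_stat,
                    p = x$p_value)
  print(round(tab, 4))
  cat("residual df:", x$df, "\n")
  invisible(x)
}

#' Rank a set of PGLS fits by small-sample Akaike weights
#'
#' `wAICc_i = exp(-d_i/2) / sum_j exp(-d_j/2)` with
#' `d_i = AICc_i - min AICc`.  All fits must be of the same response data.
#'
#' @param fits a list of [pgls_fit()] objects (>= 2).
#' @return data frame ranked by AICc with columns `model`, `lambda`,
#'   `logLik`, `AICc`, `dAICc`, `wAICc`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  for (f in fits) stopifnot(inherits(f, "pgls_fit"))
  y0 <- fits[[1]]$y
  for (f in fits[-1]) {
    if (length(f$y) != length(y0) ||
        !isTRUE(all.equal(sort(unname(f$y)), sort(unname(y0)))))
      stop("fits being compared are not of the same data")
  }
  aicc <- vapply(fits, `[[`, numeric(1), "aicc")
  if (anyNA(aicc)) stop("AICc undefined for at least one fit (n too small)")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
                    logLik = vapply(fits, `[[`, numeric(1), "log_lik"),
                    AICc = aicc, dAICc = delta, wAICc = w)
  out[order(out$AICc), ]
}

#' Average a long trait table to species means
#'
#' Arithmetic per-species means in the measured units (temperatures stay in
#' degrees Celsius; the Kelvin transform is reserved for CV% summaries).
#'
#' @param trait_table long data frame with columns `species`, `habitat`,
#'   `trait`, `value`.
#' @param trait which trait to average.
#' @return data frame `species`, `habitat`, `value` with one row per
#'   species.
#' @export
species_means <- function(trait_table, trait) {
  d <- trait_table[trait_table$trait == trait & !is.na(trait_table$value), ]
  if (!nrow(d)) stop("no values for trait ", trait)
  agg <- stats::aggregate(value ~ species + habitat, data = d, FUN = mean)
  agg[order(agg$species), c("species", "habitat", "value")]
}

#' Full model-comparison table across traits
#'
#' For each trait: species means, the three PGLS fits and their AICc
#' weights, laid out one row per trait x model.
#'
#' @param trait_table long trait table (`species`, `habitat`, `trait`,
#'   `value`).
#' @param tree `ape::phylo` covering the species.
#' @param traits trait labels to analyse; defaults to all present.
#' @return data frame with columns `trait`, `model`, `lambda`,
#'   `beta_habitat`, `se`, `t`, `df`, `p`, `logLik`, `AICc`, `wAICc`.
#' @export
pgls_table <- function(trait_table, tree,
                       traits = unique(trait_table$trait)) {
  rows <- lapply(traits, function(tr) {
    sm <- species_means(trait_table, tr)
    fits <- lapply(c("star", "brownian", "pagel"), function(m)
      pgls_fit(sm, tree, model = m))
    cmp <- compare_models(fits)
    do.call(rbind, lapply(fits, function(f) {
      i_hab <- 2L  # habitat coefficient
      data.frame(trait = tr, model = f$model, lambda = f$lambda,
                 beta_habitat = unname(f$beta[i_hab]),
                 se = unname(f$se[i_hab]), t = unname(f$t_stat[i_hab]),
                 df = f$df, p = unname(f$p_value[i_hab]),
                 logLik = f$log_lik, AICc = f$aicc,
                 wAICc = cmp$wAICc[match(f$model, cmp$model)])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
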