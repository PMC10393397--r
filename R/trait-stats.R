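# Within-habitat species comparisons (Gaussian linear models, LRT, Tukey
# HSD with compact-letter displays) and Kelvin-based CV% summaries.

#' Gaussian linear model of a trait across groups
#'
#' A Gaussian-error GLM is an ordinary linear model; it is fitted here by
#' least squares, whose estimates coincide with ML, and the ML
#' log-likelihood (residual variance estimated) is retained for
#' likelihood-ratio testing.
#'
#' @param values numeric trait values.
#' @param groups factor (or coercible) of group labels, same length.
#' @param response label of the modelled trait, for reporting.
#' @return object of class `trait_lm` wrapping the `lm` fit.
#' @export
fit_lm <- function(values, groups, response = "trait") {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  counts <- table(groups)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("groups with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  fit <- lm(values ~ groups)
  structure(list(fit = fit, response = response,
                 groups = groups, values = values,
                 log_lik = as.numeric(logLik(fit)),
                 n_params = length(coef(fit)) + 1L),  # + residual variance
            class = "trait_lm")
}

#' @export
print.trait_lm <- function(x, ...) {
  cat(sprintf("Gaussian linear model: %s ~ group (%d groups, n = %d), logLik = %.3f\n",
              x$response, nlevels(x$groups), length(x$values), x$log_lik))
  invisible(x)
}

#' Residuals of a trait model (for external diagnostic plotting)
#' @param object a `trait_lm`.
#' @param ... unused.
#' @export
residuals.trait_lm <- function(object, ...) resid(object$fit)

#' Likelihood-ratio test between nested Gaussian models
#'
#' `chi2 = 2 (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with df equal to the parameter-count difference.
#'
#' @param full,reduced `trait_lm` fits on the same observations, with
#'   `reduced` nested in `full`.
#' @return list of class `lrt_result` with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "trait_lm"), inherits(reduced, "trait_lm"))
  if (length(full$values) != length(reduced$values))
    stop("models fitted to different numbers of observations")
  df <- full$n_params - reduced$n_params
  if (df < 0) stop("'full' has fewer parameters than 'reduced': not nested")
  chi2 <- max(0, 2 * (full$log_lik - reduced$log_lik))
  if (df == 0) {
    if (chi2 > 1e-8) stop("models have equal parameter counts: not nested")
    return(structure(list(chi2 = 0, df = 0L, p = 1), class = "lrt_result"))
  }
  if (2 * (full$log_lik - reduced$log_lik) < -1e-6)
    stop("'reduced' fits better than 'full': models are not nested")
  structure(list(chi2 = chi2, df = as.integer(df),
                 p = pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, P = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

# Compact letter display by insert-and-absorb: start from one group holding
# all levels; each significant pair splits every group containing both;
# groups that become subsets of others are absorbed.
.letter_display <- function(levels_ordered, sig_pairs) {
  groups <- list(levels_ordered)
  if (nrow(sig_pairs)) {
    for (r in seq_len(nrow(sig_pairs))) {
      a <- sig_pairs[r, 1]
      b <- sig_pairs[r, 2]
      new_groups <- list()
      for (g in groups) {
        if (a %in% g && b %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      keep <- rep(TRUE, length(new_groups))
      for (i in seq_along(new_groups)) {
        for (j in seq_along(new_groups)) {
          if (i != j && keep[j] &&
              all(new_groups[[i]] %in% new_groups[[j]]) &&
              (length(new_groups[[i]]) < length(new_groups[[j]]) || i > j))
            keep[i] <- FALSE
        }
      }
      groups <- unique(new_groups[keep])
      groups <- groups[vapply(groups, length, 1L) > 0]
    }
  }
  ord <- order(vapply(groups, function(g)
    min(match(g, levels_ordered)), 1L))
  groups <- groups[ord]
  letters_out <- setNames(rep("", length(levels_ordered)), levels_ordered)
  for (i in seq_along(groups)) {
    for (lv in groups[[i]])
      letters_out[lv] <- paste0(letters_out[lv], letters[i])
  }
  letters_out
}

#' Tukey HSD multiple comparisons with compact letters
#'
#' For every pair of groups the studentized-range statistic
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` is referred to the
#' studentized-range distribution with `k` groups and the model's residual
#' df (the Tukey-Kramer form for unbalanced designs).  Levels are labelled
#' with compact letters: groups sharing a letter are not significantly
#' different at `alpha`.
#'
#' @param fit a [fit_lm()] result.
#' @param alpha significance level for the letter display.
#' @return object of class `tukey_result`: `table` (one row per pair with
#'   `mean_diff`, `q_stat`, `p_adj`), `letters`, `alpha`.
#' @export
tukey_hsd <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "trait_lm"), alpha > 0, alpha < 1)
  g <- fit$groups
  y <- fit$values
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_res <- length(y) - k
  mse <- sum(resid(fit$fit)^2) / df_res
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  zero_var <- mse <= .Machine$double.eps
  if (zero_var)
    warning("zero residual variance: all pairwise differences flagged significant")
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff_ab <- means[[a]] - means[[b]]
    if (zero_var) {
      q <- if (abs(diff_ab) > 0) Inf else 0
      p <- if (abs(diff_ab) > 0) 0 else 1
    } else {
      se <- sqrt(mse / 2 * (1 / ns[[a]] + 1 / ns[[b]]))
      q <- abs(diff_ab) / se
      p <- ptukey(q, nmeans = k, df = df_res, lower.tail = FALSE)
    }
    data.frame(level_i = a, level_j = b, mean_diff = diff_ab,
               q_stat = q, p_adj = p)
  })
  tab <- do.call(rbind, rows)
  sig <- tab[tab$p_adj < alpha, c("level_i", "level_j"), drop = FALSE]
  lv_by_mean <- lv[order(means, decreasing = TRUE)]
  letters_out <- .letter_display(lv_by_mean, as.matrix(sig))
  structure(list(table = tab, letters = letters_out[lv], alpha = alpha,
                 means = means, df_res = df_res, mse = mse),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %g, residual df = %d):\n",
              x$alpha, x$df_res))
  print(transform(x$table, p_adj = signif(p_adj, 4)), row.names = FALSE)
  cat("letters:", paste(names(x$letters), x$letters, sep = ":",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Coefficient-of-variation summary of a trait across species
#'
#' `CV% = 100 * sd / |mean|` per species, then mean and SD of the CVs
#' across species (the absolute mean keeps CV% non-negative for
#' sign-varying traits such as the slope curvature).  Temperature traits
#' (`t_opt_C`, `ult_C`) are converted to Kelvin (+273.15) first, so their
#' relative variability is measured on an absolute scale.
#'
#' @param trait_table long trait table (`species`, `habitat`, `trait`,
#'   `value`).
#' @param trait trait label to summarise.
#' @param kelvin_traits traits treated as Celsius temperatures.
#' @return object of class `cv_summary`: per-species table, `mean_cv`,
#'   `sd_cv`, `kelvin_applied`.
#' @export
cv_summary <- function(trait_table, trait,
                       kelvin_traits = c("t_opt_C", "ult_C")) {
  d <- trait_table[trait_table$trait == trait & !is.na(trait_table$value), ]
  if (!nrow(d)) stop("no values for trait ", trait)
  counts <- table(d$species)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("species with fewer than 2 individuals: ",
         paste(small, collapse = ", "))
  kelvin <- trait %in% kelvin_traits
  if (kelvin) d$value <- d$value + 273.15
  per <- do.call(rbind, lapply(split(d, d$species), function(s) {
    mu <- mean(s$value)
    cv <- if (abs(mu) < .Machine$double.eps) NA_real_ else
      100 * sd(s$value) / abs(mu)
    data.frame(species = s$species[1], habitat = s$habitat[1],
               n = nrow(s), mean = mu, sd = sd(s$value), cv_pct = cv)
  }))
  rownames(per) <- NULL
  if (anyNA(per$cv_pct))
    warning("CV undefined (zero mean) for: ",
            paste(per$species[is.na(per$cv_pct)], collapse = ", "))
  structure(list(trait = trait, per_species = per,
                 mean_cv = mean(per$cv_pct, na.rm = TRUE),
                 sd_cv = sd(per$cv_pct, na.rm = TRUE),
                 kelvin_applied = kelvin),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("CV%% of %s%s: mean %.3g +/- %.3g across %d species\n",
              x$trait, if (x$kelvin_applied) " (Kelvin scale)" else "",
              x$mean_cv, x$sd_cv, nrow(x$per_species)))
  invisible(x)
}
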