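# Cohort-level orchestration: simulate a study cohort of ramped traces with
# known ground truth, run every trace through the trait pipeline, then run
# the comparative analyses (PGLS + AICc weights, habitat models with Tukey
# letters, CV% summaries).

#' Default study cohort design
#'
#' Six species, three per habitat, with species-mean traits spanning the
#' range typical of intertidal neritid snails (HRmax 108-151 bpm, Topt
#' 42-45 degC, ULT 51-52.5 degC) and a habitat effect on the slope
#' gradient (rocky-shore activation energies above mangrove ones).
#' `depression_prob` is the per-individual probability of a
#' metabolic-depression plateau, highest in the species where resting
#' depression is commonly observed.
#'
#' @return data frame with one row per species.
#' @export
default_cohort <- function() {
  data.frame(
    species = c("rocky_A", "rocky_B", "rocky_C",
                "mangrove_A", "mangrove_B", "mangrove_C"),
    habitat = c("rocky", "rocky", "rocky",
                "mangrove", "mangrove", "mangrove"),
    e_act = c(0.95, 0.90, 0.85, 0.70, 0.65, 0.60),
    hr_max = c(151, 130, 108, 135, 128, 112),
    t_opt = c(45, 44, 42.5, 44.5, 44, 42),
    ult = c(52.5, 52, 51.5, 52, 51.5, 51),
    depression_prob = c(1 / 9, 3 / 9, 0, 4 / 9, 3 / 9, 0))
}

#' Pipeline run configuration
#'
#' Bundles the cohort design, ramp protocol, individual-level trait
#' dispersions (as CV%; temperatures on the Kelvin scale), detection
#' thresholds, fitting settings and the significance level.  Individual
#' trait dispersions default to the per-species coefficients of variation
#' characteristic of neritid cTPC traits (ULT 0.955%, Topt 2.19% on
#' Kelvin; HRmax 12.6%, activation energy 19.2%).
#'
#' @param cohort species design, as [default_cohort()].
#' @param n_individuals individuals per species.
#' @param ramp a [ramp_protocol()].
#' @param noise_sd sensor noise SD in mV (pulses are 1 mV tall).
#' @param cv list of individual-level CV% values (`ult`, `t_opt`,
#'   `hr_max`, `e_act`).
#' @param e_deact_mean,e_deact_cv deactivation-energy distribution.
#' @param detection list of detection settings (`smooth_window_s`,
#'   `refractory_s`, `window_s`, `step_s`, `hr_floor`, `sustain_s`).
#' @param fit list of fitting settings (`n_starts`, `tref_C`).
#' @param alpha significance level for the statistics stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = default_cohort(), n_individuals = 9,
                       ramp = ramp_protocol(), noise_sd = 0.2,
                       cv = list(ult = 0.955, t_opt = 2.19,
                                 hr_max = 12.6, e_act = 19.2),
                       e_deact_mean = 4, e_deact_cv = 10,
                       detection = list(smooth_window_s = 0.1,
                                        refractory_s = 0.25,
                                        window_s = 60, step_s = 30,
                                        hr_floor = 5, sustain_s = 120),
                       fit = list(n_starts = 20, tref_C = 30),
                       alpha = 0.05) {
  stopifnot(n_individuals >= 1, noise_sd >= 0,
            all(unlist(cv) > 0), all(unlist(detection) > 0),
            fit$n_starts >= 1, alpha > 0, alpha < 1)
  structure(list(cohort = cohort, n_individuals = n_individuals,
                 ramp = ramp, noise_sd = noise_sd, cv = cv,
                 e_deact_mean = e_deact_mean, e_deact_cv = e_deact_cv,
                 detection = detection, fit = fit, alpha = alpha),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$cohort <- as.list(config$cohort)
  x$ramp <- unclass(config$ramp)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(cohort = as.data.frame(x$cohort),
             n_individuals = x$n_individuals,
             ramp = do.call(ramp_protocol, x$ramp),
             noise_sd = x$noise_sd, cv = x$cv,
             e_deact_mean = x$e_deact_mean, e_deact_cv = x$e_deact_cv,
             detection = x$detection, fit = x$fit, alpha = x$alpha)
}

# Lognormal multiplier with mean 1 and the requested CV (in percent).
.rlnorm_cv <- function(n, cv_pct) {
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Truncated normal by redraw (clamped after 50 attempts).
.rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# Draw one individual's generating traits around its species means.
.draw_individual <- function(sp, config) {
  cv <- config$cv
  e_i <- sp$e_act * .rlnorm_cv(1, cv$e_act)
  e_i <- min(max(e_i, 0.15), 2.5)
  eh_i <- config$e_deact_mean * .rlnorm_cv(1, config$e_deact_cv)
  eh_i <- max(eh_i, e_i + 0.5)
  hr_i <- sp$hr_max * .rlnorm_cv(1, cv$hr_max)
  # draw the two temperature traits jointly, rejecting pairs that violate
  # Topt + 1.5 < ULT, so each keeps as much of its target dispersion as the
  # ordering constraint allows
  sd_topt <- (cv$t_opt / 100) * (sp$t_opt + 273.15)
  sd_ult <- (cv$ult / 100) * (sp$ult + 273.15)
  topt_K <- ult_K <- NA_real_
  for (i in 1:50) {
    to <- .rnorm_trunc(sp$t_opt + 273.15, sd_topt, 34 + 273.15, 51 + 273.15)
    ul <- .rnorm_trunc(sp$ult + 273.15, sd_ult, 46 + 273.15, 60 + 273.15)
    if (ul >= to + 1.5) {
      topt_K <- to
      ult_K <- ul
      break
    }
  }
  if (is.na(topt_K)) {
    ult_K <- sp$ult + 273.15
    topt_K <- min(sp$t_opt + 273.15, ult_K - 1.5)
  }
  th_i <- .ss_th_for_topt(topt_K - 273.15, e_i, eh_i)
  # scale r_tref so the fitted maximum equals the drawn HRmax
  peak_unit <- ss_rate(topt_K - 273.15, 1, e_i, eh_i, th_i,
                       config$fit$tref_C)
  tt <- true_traits(r_tref = hr_i / peak_unit, e_act = e_i, e_deact = eh_i,
                    th_K = th_i, ult_C = ult_K - 273.15,
                    tref_C = config$fit$tref_C)
  if (runif(1) < sp$depression_prob) {
    onset <- .rnorm_trunc(40, 1.5, 36, 44)
    cap <- runif(1, 0.5, 0.8) *
      .ss_rate_p(tt$params, onset)
    tt$depression_cap <- cap
    tt$depression_onset_C <- onset
  }
  tt
}

#' Simulate a full study cohort of cardiac traces
#'
#' Draws per-individual generating traits around the cohort's species
#' means, simulates one ramped trace per individual, and simulates a
#' pure-birth phylogeny over the species.  Deterministic for a given
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @param seed integer seed (required: cohorts are meant to be
#'   reproducible).
#' @param out_dir optional directory; when given, trace CSVs, the manifest
#'   TSV and the tree (Newick) are written there.
#' @param overwrite allow writing into an existing non-empty `out_dir`.
#' @return list of class `ctpc_cohort`: `traces` (list of
#'   [cardiac_trace()]), `manifest` (data frame of individuals with their
#'   true trait values), `tree`, `config`, `seed`.
#' @export
run_simulate <- function(config = run_config(), seed, out_dir = NULL,
                         overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (missing(seed)) stop("run_simulate requires an explicit seed")
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
      stop("output directory exists and is not empty (use overwrite = TRUE)")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  with_seed(seed, {
    cohort <- config$cohort
    traces <- list()
    rows <- list()
    for (s in seq_len(nrow(cohort))) {
      sp <- cohort[s, ]
      for (i in seq_len(config$n_individuals)) {
        id <- sprintf("%s_%02d", sp$species, i)
        tt <- .draw_individual(sp, config)
        tr <- simulate_trace(tt, ramp = config$ramp,
                             noise_sd = config$noise_sd,
                             meta = list(individual = id,
                                         species = sp$species,
                                         habitat = sp$habitat))
        traces[[id]] <- tr
        rows[[id]] <- data.frame(
          individual = id, species = sp$species, habitat = sp$habitat,
          true_e_act = tt$params$e_act, true_e_deact = tt$params$e_deact,
          true_hr_max = .ss_rate_p(tt$params, tt$topt_C),
          true_t_opt = tt$topt_C, true_ult = tt$ult_C,
          depressed = !is.null(tt$depression_cap))
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    tree <- ape::rphylo(nrow(cohort), birth = 1, death = 0)
    tree$tip.label <- sample(cohort$species)
    out <- structure(list(traces = traces, manifest = manifest,
                          tree = tree, config = config, seed = seed),
                     class = "ctpc_cohort")
    if (!is.null(out_dir)) {
      for (id in names(traces))
        write_trace(traces[[id]], file.path(out_dir, paste0(id, ".csv")))
      write.table(manifest, file.path(out_dir, "manifest.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write_newick(tree, file.path(out_dir, "tree.nwk"))
    }
    out
  })
}

#' @export
print.ctpc_cohort <- function(x, ...) {
  cat(sprintf("cTPC cohort: %d traces (%d species x %d individuals), seed %d\n",
              length(x$traces), nrow(x$config$cohort),
              x$config$n_individuals, x$seed))
  invisible(x)
}

#' Run the trait pipeline over a cohort
#'
#' Applies [trace_to_traits()] to every trace.  Individual failures are
#' logged as warnings and yield `fit_ok = FALSE` rows; only a cohort with
#' no readable traces is an error.
#'
#' @param cohort a `ctpc_cohort` from [run_simulate()], or a directory of
#'   trace CSVs with a `manifest.tsv`.
#' @param config a [run_config()]; defaults to the cohort's own.
#' @return data frame (class `trait_table`) with one row per individual:
#'   `species`, `habitat`, `individual`, the five traits, `fit_ok`, `rss`.
#' @export
run_traits <- function(cohort, config = NULL) {
  if (is.character(cohort)) cohort <- .load_cohort_dir(cohort)
  stopifnot(inherits(cohort, "ctpc_cohort"))
  config <- config %||% cohort$config
  if (!length(cohort$traces)) stop("cohort contains no readable traces")
  det <- config$detection
  ids <- names(cohort$traces)
  rows <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    tr <- cohort$traces[[id]]
    # stable per-trace seed so reruns are bit-identical
    fit_seed <- (if (is.na(cohort$seed)) 0L else cohort$seed %% 100000L) +
      1000L * k
    res <- tryCatch(
      trace_to_traits(tr,
                      smooth_window_s = det$smooth_window_s,
                      refractory_s = det$refractory_s,
                      window_s = det$window_s, step_s = det$step_s,
                      hr_floor = det$hr_floor, sustain_s = det$sustain_s,
                      n_starts = config$fit$n_starts,
                      seed = fit_seed,
                      tref_C = config$fit$tref_C),
      error = function(e) {
        warning("trace ", id, " failed: ", conditionMessage(e))
        NULL
      })
    meta <- tr$meta
    base <- data.frame(species = meta$species %||% NA,
                       habitat = meta$habitat %||% NA,
                       individual = meta$individual %||% id)
    if (is.null(res)) {
      cbind(base, data.frame(slope_gradient_eV = NA, slope_curvature = NA,
                             hr_max_bpm = NA, t_opt_C = NA, ult_C = NA,
                             fit_ok = FALSE, rss = NA))
    } else {
      cbind(base, as.data.frame(res))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trait_table", "data.frame"))
}

.load_cohort_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv in ", dir)
  manifest <- read.delim(man_path)
  tree_path <- file.path(dir, "tree.nwk")
  tree <- if (file.exists(tree_path)) read_newick(file = tree_path) else NULL
  traces <- list()
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$individual[r]
    f <- file.path(dir, paste0(id, ".csv"))
    if (!file.exists(f)) next
    traces[[id]] <- read_trace(f, meta = list(individual = id,
                                              species = manifest$species[r],
                                              habitat = manifest$habitat[r]))
  }
  if (!length(traces)) stop("cohort contains no readable traces")
  structure(list(traces = traces, manifest = manifest, tree = tree,
                 config = run_config(), seed = NA_integer_),
            class = "ctpc_cohort")
}

#' Reshape a wide trait table to long format
#'
#' @param trait_table output of [run_traits()].
#' @param traits trait column names to keep.
#' @return long data frame `species`, `habitat`, `individual`, `trait`,
#'   `value` (rows with failed fits dropped).
#' @export
traits_long <- function(trait_table,
                        traits = c("slope_gradient_eV", "slope_curvature",
                                   "hr_max_bpm", "t_opt_C", "ult_C")) {
  d <- trait_table[trait_table$fit_ok %in% TRUE, , drop = FALSE]
  out <- do.call(rbind, lapply(traits, function(tr)
    data.frame(species = d$species, habitat = d$habitat,
               individual = d$individual, trait = tr, value = d[[tr]])))
  out[!is.na(out$value), ]
}

#' Run the comparative stage: PGLS, habitat models and CV summaries
#'
#' @param trait_table wide table from [run_traits()].
#' @param tree `ape::phylo` covering the cohort's species.
#' @param config a [run_config()] (for `alpha`).
#' @return list of class `ctpc_comparison`: `pgls` (trait x model table
#'   with AICc weights), `habitat_stats` (per habitat and trait: LRT
#'   against the null plus Tukey letters) and `cv` (per-trait
#'   [cv_summary()] objects).
#' @export
run_compare <- function(trait_table, tree, config = run_config()) {
  long <- traits_long(trait_table)
  species <- unique(long$species)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "))
  pgls <- pgls_table(long, tree)
  trait_names <- unique(long$trait)
  habitat_stats <- list()
  for (h in unique(long$habitat)) {
    for (tr in trait_names) {
      d <- long[long$habitat == h & long$trait == tr, ]
      if (length(unique(d$species)) < 2) next
      full <- fit_lm(d$value, d$species, response = tr)
      null <- .fit_lm_null(d$value, response = tr)
      habitat_stats[[paste(h, tr, sep = ".")]] <- list(
        habitat = h, trait = tr,
        lrt = lrt(full, null),
        tukey = tukey_hsd(full, alpha = config$alpha))
    }
  }
  cv <- lapply(setNames(trait_names, trait_names), function(tr)
    cv_summary(long, tr))
  structure(list(pgls = pgls, habitat_stats = habitat_stats, cv = cv),
            class = "ctpc_comparison")
}

# Intercept-only Gaussian fit used as the LRT null.
.fit_lm_null <- function(values, response = "trait") {
  values <- values[!is.na(values)]
  fit <- lm(values ~ 1)
  structure(list(fit = fit, response = response,
                 groups = factor(rep("all", length(values))),
                 values = values,
                 log_lik = as.numeric(logLik(fit)),
                 n_params = 2L),
            class = "trait_lm")
}

#' @export
print.ctpc_comparison <- function(x, ...) {
  cat("cTPC comparative analysis\n\nPGLS model comparison:\n")
  print(transform(x$pgls, p = signif(p, 3), wAICc = round(wAICc, 3)),
        row.names = FALSE)
  cat("\nCV% by trait (mean +/- SD across species):\n")
  for (tr in names(x$cv))
    cat(sprintf("  %-18s %7.3f +/- %.3f%s\n", tr, x$cv[[tr]]$mean_cv,
                x$cv[[tr]]$sd_cv,
                if (x$cv[[tr]]$kelvin_applied) "  [Kelvin]" else ""))
  invisible(x)
}
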