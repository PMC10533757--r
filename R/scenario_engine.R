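#' Build a calibration/validation scenario specification
#'
#' Five named designs cover the study's calibration options for predicting
#' the validation sub-population B at generation 4 in the target location
#' (SRO):
#' * `Uni1` — cross-validation within B at SRO: a random 70% of families
#'   trains, the remaining 30% validates; single-environment model.
#' * `Uni2` / `Uni3` — sub-population A phenotyped at SRO at generation 2
#'   (resp. 3) trains; all of B validates; deterministic, so one replicate.
#' * `Multi1` — B at generation 4 in both locations: 100% of PAL records
#'   plus a random 70% of SRO records train; the held-out 30% of SRO
#'   records validate; G-by-E models apply.
#' * `Multi2` — A phenotyped at PAL (generation 2, 100%) and at SRO
#'   (generation 3, a 25/50/75% fraction drawn at random or by CDmean);
#'   all of B validates.
#'
#' @param name scenario name.
#' @param model prediction model; Uni scenarios force `"SM"`, Multi
#'   scenarios accept `"MM"`, `"MDs"`, `"MDe"`.
#' @param fraction Multi2 SRO training fraction (0.25, 0.5 or 0.75 unless
#'   `allow_any_fraction`).
#' @param sampling Multi2 SRO sampling rule, `"random"` or `"cdmean"`.
#' @param n_replicates stochastic replicates (forced to 1 for Uni2/Uni3).
#' @param traits trait labels to run.
#' @param allow_any_fraction override the Multi2 fraction whitelist.
#' @return list of class `scenario_spec`.
#' @export
build_scenario <- function(name = c("Uni1", "Uni2", "Uni3", "Multi1",
                                    "Multi2"),
                           model = NULL, fraction = 0.5,
                           sampling = c("random", "cdmean"),
                           n_replicates = 100,
                           traits = c("FL", "PH", "YLD", "ZN"),
                           allow_any_fraction = FALSE) {
  name <- match.arg(name)
  sampling <- match.arg(sampling)
  comp <- function(pop, gen, loc, frac, samp = "all")
    list(population = pop, generation = gen, location = loc,
         fraction = frac, sampling = samp)
  uni <- name %in% c("Uni1", "Uni2", "Uni3")
  if (uni) {
    if (!is.null(model) && model != "SM")
      stop("Uni scenarios use the single-environment model SM")
    model <- "SM"
  } else {
    if (is.null(model)) model <- "MDs"
    if (!model %in% c("MM", "MDs", "MDe"))
      stop("Multi scenarios require model MM, MDs or MDe")
  }
  spec <- switch(name,
    Uni1 = list(ts = list(comp("B", 4L, "SRO", 0.70, "random")),
                vs = comp("B", 4L, "SRO", 0.30)),
    Uni2 = list(ts = list(comp("A", 2L, "SRO", 1.0)),
                vs = comp("B", 4L, "SRO", 1.0)),
    Uni3 = list(ts = list(comp("A", 3L, "SRO", 1.0)),
                vs = comp("B", 4L, "SRO", 1.0)),
    Multi1 = list(ts = list(comp("B", 4L, "PAL", 1.0),
                            comp("B", 4L, "SRO", 0.70, "random")),
                  vs = comp("B", 4L, "SRO", 0.30)),
    Multi2 = {
      if (!allow_any_fraction && !fraction %in% c(0.25, 0.5, 0.75))
        stop("Multi2 fraction must be 0.25, 0.5 or 0.75 ",
             "(use allow_any_fraction to override)")
      list(ts = list(comp("A", 2L, "PAL", 1.0),
                     comp("A", 3L, "SRO", fraction, sampling)),
           vs = comp("B", 4L, "SRO", 1.0))
    })
  if (name %in% c("Uni2", "Uni3")) n_replicates <- 1L
  structure(list(name = name, ts_components = spec$ts,
                 vs_component = spec$vs, model = model,
                 n_replicates = as.integer(n_replicates), traits = traits),
            class = "scenario_spec")
}

#' @export
#' @method print scenario_spec
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec", x$name, "model", x$model, "replicates",
      x$n_replicates, "\n")
  for (tc in x$ts_components)
    cat("  TS:", tc$population, paste0("S0:", tc$generation), tc$location,
        sprintf("%.0f%%", 100 * tc$fraction), tc$sampling, "\n")
  v <- x$vs_component
  cat("  VS:", v$population, paste0("S0:", v$generation), v$location,
      sprintf("%.0f%%", 100 * v$fraction), "\n")
  invisible(x)
}

component_pool <- function(blues, comp, trait) {
  rows <- blues$population == comp$population &
    blues$generation == comp$generation &
    blues$location == comp$location & blues$trait == trait
  blues[rows, , drop = FALSE]
}

#' Run a scenario over replicated training-set draws
#'
#' For each trait and replicate: draw the training families per component
#' sampling rule, mark the validation families' phenotypes in the
#' prediction environment as missing, fit the scenario's model by Gibbs
#' sampling, and score predictive ability against the validation BLUEs.
#' The record set (and hence the kernel eigendecompositions) is shared
#' across replicates; only the observed-phenotype mask changes. Validation
#' phenotypes never enter the training data in any replicate (hard
#' assertion).
#'
#' @param spec a [build_scenario()] spec.
#' @param bundle list with `G` (a `genomic_rel`) and `blues` (a
#'   [fit_blues_all()] table with a `population` column).
#' @param seed master seed; replicate r uses `seed + r`.
#' @param settings an [mcmc_settings()] (its seed is re-derived per
#'   replicate).
#' @param ga GA settings for `cdmean` sampling components.
#' @return Object of class `scenario_result`: `pa` (data.frame trait,
#'   model, scenario, replicate, pa), `summary` (mean/sd per trait),
#'   `gebv` (per-trait replicate-mean GEBV of validation families).
#' @export
run_scenario <- function(spec, bundle, seed = 1L,
                         settings = mcmc_settings(),
                         ga = ga_settings(n_iterations = 25, pop_size = 40,
                                          n_elites = 4)) {
  blues <- bundle$blues
  G <- bundle$G
  pa_rows <- list()
  gebv_out <- list()
  for (trait in spec$traits) {
    pools <- lapply(spec$ts_components, component_pool, blues = blues,
                    trait = trait)
    for (i in seq_along(pools))
      if (nrow(pools[[i]]) == 0) {
        tc <- spec$ts_components[[i]]
        stop("no BLUEs for TS component ", tc$population, " S0:",
             tc$generation, " ", tc$location, " ", trait)
      }
    vsc <- spec$vs_component
    vs_pool <- component_pool(blues, vsc, trait)
    if (nrow(vs_pool) == 0)
      stop("no BLUEs for VS component ", vsc$population, " S0:",
           vsc$generation, " ", vsc$location, " ", trait)
    n_vs <- max(1L, round(vsc$fraction * nrow(vs_pool)))
    # fixed record set: every pool record plus every VS-pool record
    rec_df <- unique(rbind(
      do.call(rbind, lapply(pools, function(p)
        data.frame(family = p$family, environment = p$location,
                   y = p$blue, stringsAsFactors = FALSE))),
      data.frame(family = vs_pool$family, environment = vs_pool$location,
                 y = vs_pool$blue, stringsAsFactors = FALSE)))
    records <- data.frame(individual = rec_df$family,
                          environment = rec_df$environment,
                          stringsAsFactors = FALSE)
    kern <- build_kernels(G, records, spec$model)
    ecache <- kernel_eigen(kern)
    vs_shares_pool <- vapply(seq_along(pools), function(i) {
      tc <- spec$ts_components[[i]]
      tc$population == vsc$population && tc$generation == vsc$generation &&
        tc$location == vsc$location
    }, logical(1))
    gebv_acc <- NULL
    for (r in seq_len(spec$n_replicates)) {
      rseed <- seed + 7919L * r
      set.seed(rseed)
      # validation draw first (complement-linked components respect it)
      vs_fams <- if (vsc$fraction >= 1) vs_pool$family else
        sample(vs_pool$family, n_vs)
      ts_sel <- vector("list", length(pools))
      for (i in seq_along(pools)) {
        tc <- spec$ts_components[[i]]
        pool_f <- pools[[i]]$family
        avail <- if (vs_shares_pool[i]) setdiff(pool_f, vs_fams) else pool_f
        k <- round(tc$fraction * length(pool_f))
        k <- min(k, length(avail))
        ts_sel[[i]] <- switch(tc$sampling,
          all = avail,
          random = sample(avail, k),
          cdmean = {
            fixed <- unlist(lapply(which(!vs_shares_pool &
                                           seq_along(pools) != i),
                                   function(j) pools[[j]]$family))
            prob <- ts_opt_problem(G, candidate_ids = avail,
                                   target_ids = unique(vs_fams),
                                   n_select = k, lambda = 1,
                                   fixed_ts_ids = unique(fixed))
            ga$seed <- rseed
            ga_select(prob, ga)$selected
          })
      }
      obs_keys <- unique(unlist(lapply(seq_along(pools), function(i)
        paste(ts_sel[[i]], spec$ts_components[[i]]$location))))
      vs_keys <- paste(vs_fams, vsc$location)
      # leakage assertion: validation records never observed in training
      stopifnot(length(intersect(obs_keys, vs_keys)) == 0)
      rec_keys <- paste(rec_df$family, rec_df$environment)
      y <- ifelse(rec_keys %in% obs_keys, rec_df$y, NA_real_)
      st <- settings
      st$seed <- rseed
      fitted <- fit_gibbs(kern, y, st, eigen_cache = ecache)
      vs_idx <- match(vs_keys, rec_keys)
      pa <- predictive_ability(fitted$gebv[vs_idx], rec_df$y[vs_idx])
      pa_rows[[length(pa_rows) + 1]] <- data.frame(
        trait = trait, model = spec$model, scenario = spec$name,
        replicate = r, pa = pa, seed = rseed)
      g <- stats::setNames(fitted$gebv[vs_idx], vs_fams)
      if (is.null(gebv_acc)) {
        gebv_acc <- stats::setNames(numeric(nrow(vs_pool)), vs_pool$family)
        gebv_n <- gebv_acc
      }
      gebv_acc[names(g)] <- gebv_acc[names(g)] + g
      gebv_n[names(g)] <- gebv_n[names(g)] + 1
    }
    gebv_out[[trait]] <- ifelse(gebv_n > 0, gebv_acc / gebv_n, NA_real_)
    names(gebv_out[[trait]]) <- names(gebv_acc)
  }
  pa <- do.call(rbind, pa_rows)
  summ <- do.call(rbind, lapply(split(pa, pa$trait), function(d)
    data.frame(trait = d$trait[1], scenario = spec$name,
               model = spec$model, n = nrow(d), mean_pa = mean(d$pa),
               sd_pa = stats::sd(d$pa))))
  rownames(summ) <- NULL
  structure(list(pa = pa, summary = summ, gebv = gebv_out, spec = spec),
            class = "scenario_result")
}

#' @export
#' @method print scenario_result
print.scenario_result <- function(x, ...) {
  cat("scenario_result", x$spec$name, "(", x$spec$model, ")\n")
  print(x$summary)
  invisible(x)
}

#' Compare scenario predictive abilities with Fisher-Z and Tukey letters
#'
#' Fisher-Z transforms the replicate predictive abilities, fits a one-way
#' fixed-effect linear model on the group labels, and assigns compact
#' letters from all pairwise Tukey comparisons at `alpha`. Groups with
#' zero variance are flagged as degenerate.
#'
#' @param results named list of `scenario_result` objects or numeric PA
#'   vectors (each a group), all for one trait.
#' @param trait trait to extract when results are `scenario_result`s.
#' @param alpha significance level for the letter display.
#' @return data.frame `group`, `n`, `mean_pa`, `mean_z`, `letter`,
#'   `degenerate`.
#' @export
compare_scenarios <- function(results, trait = NULL, alpha = 0.05) {
  vals <- lapply(results, function(r) {
    if (inherits(r, "scenario_result")) {
      pa <- r$pa
      if (!is.null(trait)) pa <- pa[pa$trait == trait, ]
      pa$pa
    } else as.numeric(r)
  })
  if (is.null(names(vals)) || any(names(vals) == ""))
    names(vals) <- paste0("grp", seq_along(vals))
  n_per <- lengths(vals)
  if (length(vals) < 2 || any(n_per < 2)) {
    if (length(vals) == 1)
      return(data.frame(group = names(vals), n = n_per,
                        mean_pa = vapply(vals, mean, 0),
                        mean_z = vapply(vals, function(v) mean(fisher_z(v)), 0),
                        letter = "a", degenerate = FALSE))
    stop("need >= 2 groups with >= 2 replicates each")
  }
  degen <- vapply(vals, function(v) stats::sd(v) == 0, logical(1))
  if (any(degen))
    warning("zero-variance group(s): ",
            paste(names(vals)[degen], collapse = ", "))
  df <- data.frame(
    z = fisher_z(unlist(vals)),
    group = factor(rep(names(vals), n_per), levels = names(vals)))
  fit <- stats::lm(z ~ group, data = df)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  letters <- multcomp::cld(glht, level = alpha)$mcletters$Letters
  data.frame(group = names(vals), n = as.integer(n_per),
             mean_pa = vapply(vals, mean, 0),
             mean_z = vapply(vals, function(v) mean(fisher_z(v)), 0),
             letter = unname(letters[names(vals)]),
             degenerate = unname(degen), row.names = NULL)
}

#' Overlap between the top-k ranked families of two results
#'
#' @param gebv_a,gebv_b named numeric vectors of GEBVs over the same
#'   families (or `scenario_result`s, using the first trait).
#' @param k top-list size.
#' @param trait trait to extract from `scenario_result` inputs.
#' @return Integer overlap count `|top_k(a) intersect top_k(b)|`.
#' @export
top_k_overlap <- function(gebv_a, gebv_b, k, trait = NULL) {
  pull <- function(x) {
    if (inherits(x, "scenario_result")) {
      tr <- if (is.null(trait)) names(x$gebv)[1] else trait
      x$gebv[[tr]]
    } else x
  }
  a <- pull(gebv_a); b <- pull(gebv_b)
  fams <- intersect(names(a), names(b))
  if (k > length(fams)) stop("k exceeds the number of shared families")
  a <- a[fams]; b <- b[fams]
  top <- function(v) names(sort(v, decreasing = TRUE))[seq_len(k)]
  length(intersect(top(a), top(b)))
}
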