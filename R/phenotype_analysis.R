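#' Flag outliers per trial and trait with Tukey fences
#'
#' Values outside `coef` times the interquartile range beyond the Tukey
#' hinges (the boxplot convention) are flagged, per (location, year,
#' trait) group. Flags are informational; nothing is removed.
#'
#' @param records a `trial_records` data.frame.
#' @param coef fence coefficient (default 1.5).
#' @return Logical vector, one flag per row of `records`.
#' @export
flag_outliers <- function(records, coef = 1.5) {
  flags <- logical(nrow(records))
  grp <- interaction(records$location, records$year, records$trait,
                     drop = TRUE)
  for (g in levels(grp)) {
    i <- which(grp == g)
    v <- records$value[i]
    if (sum(!is.na(v)) < 4) {
      warning("group ", g, " has <4 observations; no outlier flags")
      next
    }
    fn <- stats::fivenum(v)          # Tukey hinges, as boxplot.stats
    iqr <- fn[4] - fn[2]
    flags[i] <- !is.na(v) & (v < fn[2] - coef * iqr | v > fn[4] + coef * iqr)
  }
  flags
}

#' REML variance decomposition for a multi-location trial set
#'
#' Fits, per trait, the mixed model with fixed location and
#' replicate-within-location effects, random blocks nested in replicates
#' and locations, random genotype, and random genotype-within-location
#' (the G-by-E term):
#' `y = mu + Loc + Rep(Loc) + Bl(Rep(Loc)) + g + g(Loc) + e`.
#' With a single location the location terms drop and blocks are nested
#' in replicates only. Fitted by REML with \pkg{lme4}; variances are
#' non-negative by construction (boundary fits are returned as 0).
#'
#' @param records `trial_records` rows for one population-generation set
#'   (one or two locations).
#' @param trait trait label to analyse.
#' @return An object of class `variance_components`: `sigma2_g`,
#'   `sigma2_gxloc` (`NA` for single-location fits), `sigma2_block`,
#'   `sigma2_e`, `fixed_estimates`, `proportions` (% of total variance,
#'   summing to 100), `converged`, `n_iter`.
#' @export
fit_variance_model <- function(records, trait) {
  df <- records[records$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no records for trait ", trait)
  df$family <- factor(df$family)
  df$location <- factor(df$location)
  df$rep <- factor(df$rep)
  df$block <- factor(df$block)
  multi <- nlevels(df$location) > 1
  form <- if (multi)
    value ~ location + location:rep + (1 | location:rep:block) +
      (1 | family) + (1 | family:location)
  else
    value ~ rep + (1 | rep:block) + (1 | family)
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(name) {
    i <- match(name, vc$grp)
    if (is.na(i)) NA_real_ else vc$vcov[i]
  }
  s_g <- getv("family")
  s_gl <- if (multi) getv("family:location") else NA_real_
  s_bl <- if (multi) getv("location:rep:block") else getv("rep:block")
  s_e <- vc$vcov[vc$grp == "Residual"]
  comps <- c(genotype = s_g,
             `genotype:location` = if (multi) s_gl else NA,
             block = s_bl, residual = s_e)
  tot <- sum(comps, na.rm = TRUE)
  props <- 100 * comps / tot
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(sigma2_g = s_g, sigma2_gxloc = s_gl, sigma2_block = s_bl,
                 sigma2_e = s_e,
                 fixed_estimates = lme4::fixef(fit),
                 proportions = props, converged = conv,
                 n_iter = as.integer(fit@optinfo$feval),
                 n_locations = nlevels(df$location)),
            class = "variance_components")
}

#' @export
#' @method print variance_components
print.variance_components <- function(x, ...) {
  cat("variance_components: sigma2_g =", signif(x$sigma2_g, 4),
      " sigma2_gxloc =", signif(x$sigma2_gxloc, 4),
      " sigma2_block =", signif(x$sigma2_block, 4),
      " sigma2_e =", signif(x$sigma2_e, 4), "\n")
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = s_g / (s_g + s_gxloc / NE + s_e / NR)` where `NE` and `NR` are
#' harmonic means of the numbers of locations and replicates per genotype.
#' For a within-location estimate the G-by-E term is absent (pass
#' `sigma2_gxloc = NA` or a single-location [fit_variance_model()] result).
#'
#' @param vc a `variance_components` object, or a number (`sigma2_g`).
#' @param NE,NR harmonic-mean numbers of locations and replicates.
#' @param sigma2_gxloc,sigma2_e used when `vc` is numeric.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc, NE, NR, sigma2_gxloc = NA, sigma2_e = NULL) {
  if (inherits(vc, "variance_components")) {
    s_g <- vc$sigma2_g; s_gl <- vc$sigma2_gxloc; s_e <- vc$sigma2_e
  } else {
    s_g <- vc; s_gl <- sigma2_gxloc; s_e <- sigma2_e
  }
  stopifnot(NE > 0, NR > 0)
  gl_term <- if (is.na(s_gl)) 0 else s_gl / NE
  denom <- s_g + gl_term + s_e / NR
  if (denom == 0) stop("all variance components are zero; H2 undefined")
  s_g / denom
}

#' Harmonic means of locations and replicates per genotype
#'
#' @param records a `trial_records` data.frame (one trait is enough; the
#'   design, not the values, matters).
#' @return `c(NE, NR)`: harmonic means over families of the number of
#'   locations and of the total number of replicate plots per family.
#' @export
harmonic_means <- function(records) {
  stopifnot(nrow(records) > 0)
  tr <- records$trait[1]
  df <- records[records$trait == tr, , drop = FALSE]
  ne_f <- tapply(df$location, df$family, function(x) length(unique(x)))
  nr_f <- tapply(df$location, df$family, length)
  c(NE = 1 / mean(1 / ne_f), NR = 1 / mean(1 / nr_f))
}

#' Per-trial BLUEs of genotype means
#'
#' Stage-1 adjustment for a single location-year trial: genotype and
#' replicate fixed, block-within-replicate random
#' (`y = mu + Rep + Bl(Rep) + g + e` with `g` fixed). Estimates are
#' centered so the mean BLUE equals the trial mean. Falls back to ordinary
#' least squares when the block variance is inestimable, and to raw values
#' when each family has a single observation.
#'
#' @param records `trial_records` rows for one location-year trial.
#' @param trait trait label.
#' @return A `data.frame` (`family`, `location`, `year`, `generation`,
#'   `trait`, `blue`, `se`).
#' @export
fit_blues <- function(records, trait) {
  df <- records[records$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) stop("no records for trait ", trait)
  if (length(unique(df$location)) > 1 || length(unique(df$year)) > 1)
    stop("fit_blues expects a single location-year trial")
  df$family <- factor(df$family)
  df$rep <- factor(df$rep)
  df$block <- factor(df$block)
  gen <- tapply(df$generation, df$family, function(x) x[1])
  one_obs <- max(table(df$family)) == 1
  if (one_obs) {
    est <- tapply(df$value, df$family, mean)
    se <- rep(NA_real_, length(est))
  } else {
    fit <- tryCatch(
      lme4::lmer(value ~ 0 + family + rep + (1 | rep:block), data = df,
                 REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- stats::lm(value ~ 0 + family + rep, data = df)
    cf <- if (inherits(fit, "lm")) stats::coef(fit) else lme4::fixef(fit)
    fam_i <- grep("^family", names(cf))
    est <- cf[fam_i]
    names(est) <- sub("^family", "", names(est))
    V <- as.matrix(stats::vcov(fit))
    se <- sqrt(diag(V)[fam_i])
  }
  est <- est - mean(est) + mean(df$value)
  out <- data.frame(family = names(est), location = df$location[1],
                    year = df$year[1],
                    generation = as.integer(gen[names(est)]),
                    trait = trait, blue = as.numeric(est),
                    se = as.numeric(se), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' BLUEs for every trial and trait in a record set
#'
#' @param records a `trial_records` data.frame.
#' @param traits traits to adjust (default: all present).
#' @return Row-bound [fit_blues()] tables with a `population` column.
#' @export
fit_blues_all <- function(records, traits = unique(records$trait)) {
  out <- list()
  for (loc in unique(records$location))
    for (yr in unique(records$year[records$location == loc]))
      for (tr in traits) {
        sub <- records[records$location == loc & records$year == yr, ]
        if (!any(sub$trait == tr)) next
        out[[length(out) + 1]] <- fit_blues(sub, tr)
      }
  res <- do.call(rbind, out)
  if ("population" %in% names(records))
    res$population <- records$population[match(res$family, records$family)]
  res
}

#' Descriptive statistics per trait and location
#'
#' Mean, sample SD, min, max and CV% (`100 * SD / mean`; undefined when
#' the mean is 0) per (trait, location), plus the between-location Pearson
#' correlation of family means for families present in both locations.
#'
#' @param records a `trial_records` data.frame.
#' @return list with `stats` and `correlations` data.frames.
#' @export
descriptive_stats <- function(records) {
  stopifnot(nrow(records) > 0)
  key <- interaction(records$trait, records$location, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    v <- records$value[key == k]
    parts <- strsplit(k, "\\.")[[1]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    data.frame(trait = parts[1], location = parts[2], mean = m, sd = s,
               min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               cv_pct = if (m == 0) NA_real_ else 100 * s / m)
  })
  stats_df <- do.call(rbind, rows)
  locs <- unique(records$location)
  cors <- list()
  if (length(locs) >= 2) {
    for (tr in unique(records$trait)) {
      sub <- records[records$trait == tr, ]
      fm <- tapply(sub$value, list(sub$family, sub$location), mean,
                   na.rm = TRUE)
      for (i in seq_len(length(locs) - 1))
        for (j in (i + 1):length(locs)) {
          both <- stats::complete.cases(fm[, c(locs[i], locs[j])])
          cors[[length(cors) + 1]] <- data.frame(
            trait = tr, loc1 = locs[i], loc2 = locs[j],
            pearson = stats::cor(fm[both, locs[i]], fm[both, locs[j]]))
        }
    }
  }
  list(stats = stats_df,
       correlations = if (length(cors)) do.call(rbind, cors) else
         data.frame(trait = character(), loc1 = character(),
                    loc2 = character(), pearson = numeric()))
}
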