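#' Configuration for the synthetic breeding-population generator
#'
#' The generator emulates a selfing-crop recurrent-selection study: one
#' unstructured synthetic population of S0 plants split at random into a
#' training sub-population A and a validation sub-population B (plus a set
#' of temporal-check families drawn from A), genotyped at a few thousand
#' SNPs on 12 chromosomes, advanced by bulk selfing, and phenotyped in
#' two-location lattice trials (8 blocks x 3 replicates).
#'
#' Trait architecture is parameterized by a target entry-mean broad-sense
#' heritability and by the fraction of within-location genetic variance
#' that is location-specific (the G-by-E share); the between-location
#' genetic correlation is `1 - gxe_share`.
#'
#' @param n_individuals_A,n_individuals_B sizes of sub-populations A and B.
#' @param n_checks number of temporal-check families (a subset of A,
#'   always phenotyped at generation 2).
#' @param n_snps,n_chromosomes marker panel dimensions.
#' @param maf_min minimum realized minor allele frequency per SNP.
#' @param target_h2 named per-trait target heritability (entry-mean basis).
#' @param gxe_share named per-trait fraction of genetic variance that is
#'   location-specific.
#' @param loc_effects named list trait -> named numeric of location mean
#'   offsets.
#' @param trait_means named per-trait overall mean.
#' @param n_locations,n_reps,n_blocks trial design.
#' @param sigma2_block block variance (trait-standardized units).
#' @param n_bulk_plants plants bulk-harvested per family and generation
#'   (15-20; recorded for documentation, the advance itself uses the
#'   infinite-bulk expectation).
#' @param year_effects named per-location numeric vector of year effects
#'   (default all zero).
#' @param seed integer master seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals_A = 384, n_individuals_B = 334,
                       n_checks = 50, n_snps = 2000, n_chromosomes = 12,
                       maf_min = 0.025,
                       target_h2 = c(FL = 0.51, PH = 0.30, YLD = 0.24,
                                     ZN = 0.51),
                       gxe_share = c(FL = 0.59, PH = 0.70, YLD = 0.70,
                                     ZN = 0.57),
                       loc_effects = NULL,
                       trait_means = NULL,
                       n_locations = 2, n_reps = 3, n_blocks = 8,
                       sigma2_block = 0.10, n_bulk_plants = 18,
                       year_effects = NULL, seed = 1L) {
  traits <- names(target_h2)
  if (is.null(traits) || any(traits == ""))
    stop("target_h2 must be a named per-trait vector")
  if (!setequal(names(gxe_share), traits))
    stop("gxe_share must name the same traits as target_h2")
  gxe_share <- gxe_share[traits]
  locs <- c("PAL", "SRO")[seq_len(n_locations)]
  if (n_locations > 2) locs <- c(locs, paste0("LOC", 3:n_locations))
  if (is.null(loc_effects)) {
    loc_effects <- lapply(traits, function(t)
      stats::setNames(seq(0.75, -0.75, length.out = n_locations), locs))
    names(loc_effects) <- traits
  }
  if (is.null(trait_means)) trait_means <- stats::setNames(rep(0, length(traits)), traits)
  cfg <- list(n_individuals_A = as.integer(n_individuals_A),
              n_individuals_B = as.integer(n_individuals_B),
              n_checks = as.integer(n_checks),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              maf_min = maf_min, target_h2 = target_h2,
              gxe_share = gxe_share, loc_effects = loc_effects,
              trait_means = trait_means, locations = locs,
              n_locations = as.integer(n_locations),
              n_reps = as.integer(n_reps), n_blocks = as.integer(n_blocks),
              sigma2_block = sigma2_block,
              n_bulk_plants = as.integer(n_bulk_plants),
              year_effects = year_effects, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_individuals_A, n_individuals_B, n_snps, n_chromosomes,
              n_reps, n_blocks, n_locations) <= 0))
      stop("counts must be positive")
    if (n_checks < 0 || n_checks > n_individuals_A)
      stop("n_checks must be in [0, n_individuals_A]")
    if (n_snps < n_chromosomes)
      stop("invalid config: n_snps < n_chromosomes")
    if (maf_min <= 0 || maf_min >= 0.5)
      stop("maf_min must be in (0, 0.5)")
    if (any(target_h2 < 0 | target_h2 > 1))
      stop("target_h2 values must be in [0, 1]")
    if (any(gxe_share < 0 | gxe_share > 1))
      stop("gxe_share values must be in [0, 1]")
    if (n_bulk_plants < 15 || n_bulk_plants > 20)
      stop("n_bulk_plants must be in [15, 20]")
  })
  invisible(cfg)
}

# Approximate rice chromosome lengths (bp), used only to place SNPs.
rice_chrom_lengths <- function(n) {
  base <- c(43e6, 36e6, 36e6, 35e6, 30e6, 31e6, 30e6, 28e6,
            23e6, 23e6, 29e6, 27e6)
  rep_len(base, n)
}

#' Simulate S0 genotypes for the full population
#'
#' S0 plants are unions of two gametes drawn from an unstructured founder
#' pool whose allele frequencies follow a Beta(0.7, 0.7) distribution
#' truncated to `[maf_min, 1 - maf_min]` — a spectrum that retains rare
#' alleles while keeping S0 heterozygosity high. SNP columns whose
#' realized MAF falls below `maf_min` are redrawn. Sub-populations A and B
#' are a random split of one pool, so no structure is induced.
#'
#' @param cfg a [sim_config()].
#' @return A [marker_matrix()] with `n_individuals_A + n_individuals_B`
#'   rows (ids `A001..`, `B001..`) and an attribute `population` (named
#'   vector A/B per individual).
#' @export
simulate_s0_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_individuals_A + cfg$n_individuals_B
  ids <- c(sprintf("A%03d", seq_len(cfg$n_individuals_A)),
           sprintf("B%03d", seq_len(cfg$n_individuals_B)))
  draw_p <- function(k) {
    p <- stats::rbeta(k, 0.7, 0.7)
    bad <- p < cfg$maf_min | p > 1 - cfg$maf_min
    while (any(bad)) {
      p[bad] <- stats::rbeta(sum(bad), 0.7, 0.7)
      bad <- p < cfg$maf_min | p > 1 - cfg$maf_min
    }
    p
  }
  draw_col <- function(p) stats::rbinom(n, 1, p) + stats::rbinom(n, 1, p)
  p <- draw_p(cfg$n_snps)
  d <- vapply(p, draw_col, numeric(n))
  maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
  tries <- 0
  while (any(maf < cfg$maf_min) && tries < 200) {
    j <- which(maf < cfg$maf_min)
    p[j] <- draw_p(length(j))
    d[, j] <- vapply(p[j], draw_col, numeric(n))
    maf <- pmin(colMeans(d) / 2, 1 - colMeans(d) / 2)
    tries <- tries + 1
  }
  rownames(d) <- ids
  # spread SNPs over chromosomes as evenly as possible, sorted positions
  chr_sizes <- tabulate(rep_len(seq_len(cfg$n_chromosomes), cfg$n_snps),
                        cfg$n_chromosomes)
  lens <- rice_chrom_lengths(cfg$n_chromosomes)
  chrom <- character(0); pos <- integer(0)
  for (c in seq_len(cfg$n_chromosomes)) {
    k <- chr_sizes[c]
    pp <- sort(sample.int(lens[c], k))
    chrom <- c(chrom, rep(paste0("chr", c), k))
    pos <- c(pos, pp)
  }
  colnames(d) <- paste0(chrom, "_", pos)
  m <- marker_matrix(d, chrom, pos)
  attr(m, "population") <- stats::setNames(
    rep(c("A", "B"), c(cfg$n_individuals_A, cfg$n_individuals_B)), ids)
  m
}

#' Family genotype state under bulk selfing
#'
#' Tracks, per family, the expected allele dosage (unchanged in
#' expectation under selfing without selection) and the expected per-locus
#' heterozygosity, which halves with every selfing step in the
#' infinite-bulk approximation (15-20 bulked plants per generation make
#' drift negligible at the family level).
#'
#' @param m a [marker_matrix()] of S0 genotypes.
#' @return A list of `family_state` objects, one per individual/family.
#' @export
family_states_from_s0 <- function(m) {
  lapply(ind_ids(m), function(id) {
    dos <- m$dosage[id, ]
    structure(list(family_id = id, generation_t = 0L,
                   expected_dosage = dos,
                   expected_heterozygosity = as.numeric(dos == 1)),
              class = "family_state")
  })
}

#' Advance a family by bulk selfing
#'
#' @param state a `family_state` (see [family_states_from_s0()]).
#' @param n_steps number of selfing steps (>= 0).
#' @return The advanced `family_state`: heterozygosity multiplied by
#'   `(1/2)^n_steps`, expected dosage unchanged, generation incremented.
#' @export
advance_generation_bulk <- function(state, n_steps) {
  if (n_steps < 0) stop("n_steps must be >= 0")
  state$expected_heterozygosity <- state$expected_heterozygosity * 0.5^n_steps
  state$generation_t <- state$generation_t + as.integer(n_steps)
  state
}

#' Expected residual heterozygosity after t selfing steps
#'
#' @param t number of selfing steps.
#' @param h0 starting heterozygosity (default 1, a fully heterozygous
#'   locus).
#' @return `h0 * (1/2)^t`; homozygosity is `1 -` this value (93.75% at
#'   `t = 4` from `h0 = 1`).
#' @export
expected_selfing_heterozygosity <- function(t, h0 = 1) {
  if (any(t < 0)) stop("t must be >= 0")
  h0 * 0.5^t
}

#' Sample a realized family dosage at its current generation
#'
#' Per-locus genotype frequencies implied by the S0 genotype and t selfing
#' steps: a locus heterozygous at S0 is Aa with probability `(1/2)^t` and
#' otherwise fixed AA or aa with equal probability.
#'
#' @param state a `family_state`.
#' @return Integer dosage vector for one plant/bulk draw.
#' @export
sample_family_dosage <- function(state) {
  dos <- state$expected_dosage
  het <- state$expected_heterozygosity
  out <- dos
  seg <- which(dos == 1)
  if (length(seg)) {
    u <- stats::runif(length(seg))
    h <- het[seg]
    out[seg] <- ifelse(u < h, 1, ifelse(u < h + (1 - h) / 2, 0, 2))
  }
  out
}

#' Simulate per-trait marker effects and genetic values
#'
#' Each trait gets main-effect and per-location deviation marker effects on
#' centered dosages; realized genetic values are rescaled so the sample
#' variance partition matches the configured targets exactly:
#' `var(main) = 1 - gxe_share`, `var(deviation) = gxe_share` per location
#' (so the between-location genetic correlation is `1 - gxe_share`), and
#' the residual variance solves the entry-mean heritability identity
#' `H2 = s_g / (s_g + s_gl/NE + s_e/NR)` with `NE = n_locations` and
#' `NR = n_reps * n_locations`.
#'
#' @param cfg a [sim_config()].
#' @param markers a [marker_matrix()] from [simulate_s0_genotypes()].
#' @return A list of class `trait_architecture`: per trait, marker effects
#'   (`beta`, `delta`), genetic values (`g_main`, per-location `g_dev`),
#'   and variances (`sigma2_g`, `sigma2_gxloc`, `sigma2_e`).
#' @export
simulate_trait_architecture <- function(cfg, markers) {
  if (ncol(markers$dosage) == 0) stop("markers must be nonempty")
  set.seed(cfg$seed + 1L)
  Zc <- scale(markers$dosage, center = TRUE, scale = FALSE)
  ne <- cfg$n_locations
  nr <- cfg$n_reps * cfg$n_locations
  out <- lapply(names(cfg$target_h2), function(tr) {
    h2 <- cfg$target_h2[[tr]]
    s <- cfg$gxe_share[[tr]]
    if (s > 1) stop("gxe_share > 1 is unattainable")
    s_g <- 1 - s
    s_gl <- s
    scale_to_var <- function(x, v) {
      if (v == 0) return(x * 0)
      sdx <- stats::sd(x)
      if (sdx == 0) stop("degenerate genetic values; need >1 individual")
      x / sdx * sqrt(v)
    }
    beta <- stats::rnorm(ncol(Zc))
    g_main <- scale_to_var(drop(Zc %*% beta), s_g)
    g_main <- g_main - mean(g_main)
    delta <- matrix(stats::rnorm(ncol(Zc) * ne), ncol = ne)
    # deviations are orthogonalized in-sample against the main effect and
    # each other, so the realized partition (and the between-location
    # genetic correlation 1 - gxe_share) is exact, not just in expectation
    basis <- if (s_g > 0) cbind(g_main / sqrt(sum(g_main^2))) else
      matrix(0, nrow(Zc), 0)
    g_dev <- matrix(0, nrow(Zc), ne,
                    dimnames = list(rownames(markers$dosage), cfg$locations))
    for (l in seq_len(ne)) {
      v <- drop(Zc %*% delta[, l])
      v <- v - mean(v)
      if (ncol(basis) > 0) v <- v - basis %*% crossprod(basis, v)
      v <- scale_to_var(drop(v), s_gl)
      g_dev[, l] <- v - mean(v)
      if (s_gl > 0)
        basis <- cbind(basis, g_dev[, l] / sqrt(sum(g_dev[, l]^2)))
    }
    if (h2 > 0) {
      s_e <- nr * (s_g / h2 - s_g - s_gl / ne)
      if (s_g == 0) s_e <- 1
      if (s_e <= 0)
        stop("unattainable variance partition for trait ", tr,
             ": target_h2 too high for the given gxe_share")
    } else {
      # pure-noise trait: drop the genetic signal entirely
      g_main <- g_main * 0
      g_dev <- g_dev * 0
      s_g <- 0; s_gl <- 0
      s_e <- 1
    }
    list(trait = tr, beta = beta, delta = delta,
         g_main = stats::setNames(g_main, rownames(markers$dosage)),
         g_dev = g_dev,
         sigma2_g = s_g, sigma2_gxloc = s_gl, sigma2_e = s_e)
  })
  names(out) <- names(cfg$target_h2)
  structure(out, class = "trait_architecture")
}

#' Simulate the multi-generation two-location field trials
#'
#' Generates the study's six trials: sub-population A phenotyped at
#' generations 2 and 3 and sub-population B at generation 4, each at every
#' location, always alongside the temporal checks (the first `n_checks`
#' families of A, phenotyped at generation 2 in every trial). Each trial
#' is a lattice with `n_blocks` incomplete blocks nested in each of
#' `n_reps` replicates; block effects are `N(0, sigma2_block)`, replicate
#' effects are small fixed shifts, and year effects default to zero.
#'
#' @param cfg a [sim_config()].
#' @param markers S0 genotypes (used for ids/population split).
#' @param arch a [simulate_trait_architecture()] result.
#' @param noise logical; set `FALSE` to zero residual, block and replicate
#'   effects (phenotype = mean + location offset + genetic value).
#' @return A `trial_records` data.frame: `family`, `population`,
#'   `is_check`, `location`, `year`, `generation`, `rep`, `block`,
#'   `trait`, `value`.
#' @export
simulate_trials <- function(cfg, markers, arch, noise = TRUE) {
  set.seed(cfg$seed + 2L)
  pop <- attr(markers, "population")
  ids_A <- names(pop)[pop == "A"]
  ids_B <- names(pop)[pop == "B"]
  checks <- ids_A[seq_len(cfg$n_checks)]
  core_A <- setdiff(ids_A, checks)
  trials <- list(list(pop = "A", gen = 2L, year = 2017L, fams = core_A),
                 list(pop = "A", gen = 3L, year = 2018L, fams = core_A),
                 list(pop = "B", gen = 4L, year = 2019L, fams = ids_B))
  rep_eff <- seq(-0.1, 0.1, length.out = cfg$n_reps)
  recs <- list()
  for (loc_i in seq_along(cfg$locations)) {
    loc <- cfg$locations[loc_i]
    yr_eff <- if (is.null(cfg$year_effects)) 0 else cfg$year_effects[[loc]]
    for (tl in trials) {
      entries <- data.frame(
        family = c(tl$fams, checks),
        generation = c(rep(tl$gen, length(tl$fams)),
                       rep(2L, length(checks))),
        is_check = c(rep(FALSE, length(tl$fams)),
                     rep(TRUE, length(checks))),
        stringsAsFactors = FALSE)
      entries$population <- ifelse(entries$family %in% ids_A, "A", "B")
      n_ent <- nrow(entries)
      yeff <- if (length(yr_eff) > 1) yr_eff[[as.character(tl$year)]] else yr_eff
      for (r in seq_len(cfg$n_reps)) {
        # fresh randomization per replicate; blocks filled as evenly as possible
        ord <- sample.int(n_ent)
        block <- stats::setNames(
          rep(seq_len(cfg$n_blocks), length.out = n_ent)[order(ord)],
          entries$family)
        beff <- stats::rnorm(cfg$n_blocks, 0,
                             if (noise) sqrt(cfg$sigma2_block) else 0)
        for (tr in names(arch)) {
          a <- arch[[tr]]
          g <- a$g_main[entries$family] + a$g_dev[entries$family, loc_i]
          e <- if (noise) stats::rnorm(n_ent, 0, sqrt(a$sigma2_e)) else 0
          reff <- if (noise) rep_eff[r] else 0
          val <- cfg$trait_means[[tr]] + cfg$loc_effects[[tr]][[loc]] +
            yeff + reff + beff[block] + g + e
          recs[[length(recs) + 1]] <- data.frame(
            family = entries$family, population = entries$population,
            is_check = entries$is_check, location = loc, year = tl$year,
            generation = entries$generation, rep = r,
            block = unname(block), trait = tr, value = val,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("trial_records", "data.frame")
  out
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper: genotypes, family states, trait architecture and
#' trial records under one seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `markers`, `families`, `arch`, `trials`, `cfg`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  markers <- simulate_s0_genotypes(cfg)
  arch <- simulate_trait_architecture(cfg, markers)
  trials <- simulate_trials(cfg, markers, arch)
  list(markers = markers, families = family_states_from_s0(markers),
       arch = arch, trials = trials, cfg = cfg)
}

#' Write/read trial records CSV
#'
#' @param records a `trial_records` data.frame.
#' @param path file path.
#' @return `path` / the records, invisibly for the writer.
#' @export
write_trial_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_records", "data.frame")
  out
}
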