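# Shared in-code fixtures: all data are generated at test time.

# A small complete study (genotypes + 6 trials) cached per option set.
small_study <- local({
  cache <- new.env()
  function(seed = 4, nA = 80, nB = 70, n_checks = 12, n_snps = 300,
           target_h2 = c(FL = 0.6), gxe_share = c(FL = 0.5)) {
    key <- paste(seed, nA, nB, n_checks, n_snps,
                 paste(names(target_h2), target_h2, gxe_share,
                       collapse = "_"), sep = "|")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_individuals_A = nA, n_individuals_B = nB,
                        n_checks = n_checks, n_snps = n_snps,
                        target_h2 = target_h2, gxe_share = gxe_share,
                        seed = seed)
      cache[[key]] <- simulate_study(cfg)
    }
    cache[[key]]
  }
})

# A random dense PD relationship matrix with ids.
random_grel <- function(n, n_mark = 5 * n, seed = 1, ids = paste0("i", seq_len(n))) {
  set.seed(seed)
  M <- matrix(stats::rnorm(n * n_mark), n)
  G <- tcrossprod(scale(M, scale = FALSE)) / n_mark
  diag(G) <- diag(G) + 1e-6 * mean(diag(G))
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, ids = ids), class = "genomic_rel")
}

# A tiny marker matrix built by hand.
toy_markers <- function(dosage, chrom = NULL, pos = NULL) {
  d <- as.matrix(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", ncol(d))
  if (is.null(pos)) pos <- seq_len(ncol(d)) * 100L
  marker_matrix(d, chrom, pos)
}

# Loop-wise VanRaden G, kept deliberately naive as an oracle.
vanraden_oracle <- function(dosage) {
  p <- colMeans(dosage) / 2
  keep <- p > 0 & p < 1
  dosage <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(dosage)
  G <- matrix(0, n, n)
  denom <- 0
  for (k in seq_along(p)) denom <- denom + 2 * p[k] * (1 - p[k])
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_along(p))
        s <- s + (dosage[i, k] - 2 * p[k]) * (dosage[j, k] - 2 * p[k])
      G[i, j] <- s / denom
    }
  G
}

# Loop-wise CDmean oracle: builds and inverts the full mixed-model
# coefficient matrix element by element.
cdmean_oracle <- function(G, ids, cand, targ, ts, lambda) {
  n <- length(ids)
  Z <- matrix(0, length(ts), n)
  for (i in seq_along(ts)) Z[i, match(ts[i], ids)] <- 1
  X <- matrix(1, length(ts), 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(G)))
  C22 <- solve(C)[-1, -1]
  vals <- vapply(match(targ, ids), function(i) {
    ci <- rep(-1 / n, n); ci[i] <- ci[i] + 1
    drop(t(ci) %*% (G - lambda * C22) %*% ci) / drop(t(ci) %*% G %*% ci)
  }, numeric(1))
  mean(vals)
}

# Balanced Eq.-1-style dataset where every block contains every family,
# so REML has an ANOVA method-of-moments closed form.
balanced_trial_data <- function(f = 15, l = 2, r = 2, b = 3,
                                s_g = 4, s_gl = 6, s_bl = 1.5, s_e = 5,
                                seed = 12) {
  set.seed(seed)
  fam <- paste0("f", seq_len(f))
  g <- stats::rnorm(f, 0, sqrt(s_g))
  gl <- matrix(stats::rnorm(f * l, 0, sqrt(s_gl)), f)
  df <- expand.grid(family = fam, block = seq_len(b), rep = seq_len(r),
                    location = c("PAL", "SRO")[seq_len(l)])
  df$year <- 1L
  df$trait <- "t"
  li <- as.integer(factor(df$location))
  blk <- interaction(df$location, df$rep, df$block)
  beff <- stats::rnorm(nlevels(blk), 0, sqrt(s_bl))
  df$value <- 10 + c(0.5, -0.5)[li] + beff[as.integer(blk)] +
    g[match(df$family, fam)] + gl[cbind(match(df$family, fam), li)] +
    stats::rnorm(nrow(df), 0, sqrt(s_e))
  df
}

# ANOVA method-of-moments estimates for balanced_trial_data designs.
balanced_mom <- function(df) {
  f <- length(unique(df$family))
  l <- length(unique(df$location))
  r <- length(unique(df$rep))
  b <- length(unique(df$block))
  a <- stats::anova(stats::lm(
    value ~ location + location:factor(rep) +
      location:factor(rep):factor(block) + family + location:family,
    data = df))
  mse <- a["Residuals", "Mean Sq"]
  c(sigma2_g = (a["family", "Mean Sq"] -
                  a["location:family", "Mean Sq"]) / (l * r * b),
    sigma2_gxloc = (a["location:family", "Mean Sq"] - mse) / (r * b),
    sigma2_block = (a["location:factor(rep):factor(block)", "Mean Sq"] -
                      mse) / f,
    sigma2_e = mse)
}
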