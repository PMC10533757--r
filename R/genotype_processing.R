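#' Filter SNP markers on missingness and minor allele frequency
#'
#' Filters are applied in a declared order — missingness first, then MAF —
#' and each removed SNP is attributed to the first rule it fails. Biallelic
#' status is guaranteed by the `marker_matrix` container itself (dosage
#' coding admits only two alleles); read-depth filtering is not applicable
#' to dosage data and is reported as such.
#'
#' @param m a [marker_matrix()].
#' @param max_missing maximum tolerated fraction of missing calls per SNP.
#' @param min_maf minimum minor allele frequency (computed on observed
#'   calls).
#' @return A list with `markers` (the filtered [marker_matrix()]) and
#'   `report` (data.frame of removal counts per rule; `depth` is `NA` —
#'   not applicable without read data).
#' @export
filter_markers <- function(m, max_missing = 0.20, min_maf = 0.025) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  d <- m$dosage
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0   # fully missing SNP: fails missingness first anyway
  fail_miss <- miss >= max_missing
  fail_maf <- !fail_miss & (maf <= min_maf)
  keep <- !fail_miss & !fail_maf
  if (!any(keep))
    stop("all SNPs removed by filters (missing >= ", max_missing,
         " or MAF <= ", min_maf, ")")
  report <- data.frame(
    rule = c("missing", "maf", "depth", "retained"),
    threshold = c(max_missing, min_maf, NA, NA),
    n = c(sum(fail_miss), sum(fail_maf), NA, sum(keep)))
  list(markers = subset_markers(m, snps = which(keep)), report = report)
}

#' Mean-impute missing dosage calls
#'
#' Each missing cell is replaced by its SNP's mean observed dosage (a real
#' value), leaving observed calls and per-SNP means unchanged.
#'
#' @param m a [marker_matrix()].
#' @return A `marker_matrix` with no missing values (dosages may be
#'   fractional).
#' @export
impute_mean <- function(m) {
  d <- m$dosage
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d)))
    stop("SNP(s) fully missing, cannot impute: ",
         paste(colnames(d)[nmiss == nrow(d)], collapse = ", "))
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  out <- m
  out$dosage <- d
  out
}

#' Per-SNP minor allele frequency and per-individual heterozygosity
#'
#' @param m a [marker_matrix()]; missing calls are excluded pairwise.
#' @return A list with `maf` (named per-SNP MAF in `[0, 0.5]`) and `ho`
#'   (named per-individual observed heterozygosity, the fraction of
#'   dosage == 1 calls).
#' @export
maf_and_het <- function(m) {
  d <- m$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- rowMeans(d == 1, na.rm = TRUE)
  list(maf = maf, ho = het)
}

#' Mean linkage disequilibrium r-squared by distance bin
#'
#' r-squared is the squared Pearson correlation between dosage vectors of
#' intra-chromosome SNP pairs no further apart than `max_dist_bp`. Pairs
#' involving a SNP with MAF below `min_maf`, or a monomorphic SNP, are
#' excluded.
#'
#' @param m a [marker_matrix()] (imputed or complete).
#' @param max_dist_bp maximum pair distance in bp.
#' @param breaks distance-bin breakpoints in bp (right-closed).
#' @param min_maf MAF threshold for pair inclusion.
#' @return data.frame with `chromosome`, `bin`, `n_pairs`, `mean_r2`.
#' @export
ld_r2 <- function(m, max_dist_bp = 1e6,
                  breaks = c(0, 25e3, 100e3, 250e3, 1e6),
                  min_maf = 0.025) {
  breaks <- sort(unique(c(breaks[breaks < max_dist_bp], max_dist_bp)))
  d <- m$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  usable <- pmin(p, 1 - p) >= min_maf & apply(d, 2, stats::sd, na.rm = TRUE) > 0
  out <- list()
  for (ch in unique(m$map$chromosome)) {
    j <- which(m$map$chromosome == ch & usable)
    if (length(j) < 2) next
    pos <- m$map$position[j]
    r <- stats::cor(d[, j, drop = FALSE], use = "pairwise.complete.obs")
    pr <- which(upper.tri(r), arr.ind = TRUE)
    dist <- abs(pos[pr[, 1]] - pos[pr[, 2]])
    ok <- dist <= max_dist_bp
    if (!any(ok)) next
    bin <- cut(dist[ok], breaks = breaks, include.lowest = TRUE)
    r2 <- r[pr][ok]^2
    agg <- tapply(r2, bin, mean)
    cnt <- tapply(r2, bin, length)
    out[[ch]] <- data.frame(chromosome = ch, bin = names(agg),
                            n_pairs = as.integer(ifelse(is.na(cnt), 0, cnt)),
                            mean_r2 = as.numeric(agg))
  }
  if (length(out) == 0)
    return(data.frame(chromosome = character(), bin = character(),
                      n_pairs = integer(), mean_r2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$mean_r2), , drop = FALSE]
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_k (1 - p_k)))` where `Z` is the dosage matrix
#' column-centered at twice the observed allele frequency `p_k`.
#' Monomorphic SNPs are dropped before computation. A small ridge
#' (`1e-6 * mean(diag(G))`) is added to the diagonal so the matrix is
#' positive definite for downstream factorizations.
#'
#' @param m a complete (imputed) [marker_matrix()].
#' @param ridge logical; add the stabilizing ridge (default `TRUE`).
#' @return An object of class `genomic_rel`: list with `G` (symmetric
#'   matrix with individual ids as dimnames) and `ids`.
#' @export
vanraden_g <- function(m, ridge = TRUE) {
  d <- m$dosage
  if (any(is.na(d))) stop("impute missing dosages before computing G")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2) stop("fewer than 2 polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(d, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (ridge) diag(G) <- diag(G) + 1e-6 * mean(diag(G))
  structure(list(G = G, ids = rownames(d)), class = "genomic_rel")
}

#' @export
#' @method print genomic_rel
print.genomic_rel <- function(x, ...) {
  cat("genomic_rel:", length(x$ids), "individuals; mean diagonal",
      round(mean(diag(x$G)), 3), "\n")
  invisible(x)
}

#' Theoretical heterozygote under-call probability at a given read depth
#'
#' With reads sampling the two alleles of a heterozygote independently and
#' equiprobably, a site is miscalled homozygous when all reads carry the
#' same allele: `2 * (1/2)^depth`.
#'
#' @param depth read depth (>= 1).
#' @return Probability in `[0, 1]`.
#' @export
het_undercall_prob <- function(depth) {
  stopifnot(depth >= 1)
  2 * 0.5^depth
}
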