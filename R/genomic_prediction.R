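#' Build environment-stacked covariance kernels for GBLUP
#'
#' Records are (individual, environment) pairs. The `main` kernel carries
#' the genomic relationship between individuals regardless of environment.
#' G-by-E structures:
#' * `SM` — single-environment model: only `main`, one environment allowed;
#' * `MM` — multi-environment main-effects model: only `main`;
#' * `MDs` — adds one `gxe_common` kernel: `G` within an environment, 0
#'   across environments (a single G-by-E deviation variance);
#' * `MDe` — one `gxe_env:<e>` kernel per environment, nonzero only inside
#'   that environment (environment-specific deviation variances).
#'
#' The fixed design is an intercept plus environment indicators (first
#' environment as reference).
#'
#' @param G a `genomic_rel` from [vanraden_g()].
#' @param records data.frame with columns `individual` and `environment`.
#' @param model one of `"SM"`, `"MM"`, `"MDs"`, `"MDe"`.
#' @return An object of class `kernel_set`: `records`, `kernels` (named
#'   list of symmetric matrices), `kernel_roles`, `X` (fixed design),
#'   `model`.
#' @export
build_kernels <- function(G, records, model = c("SM", "MM", "MDs", "MDe")) {
  model <- match.arg(model)
  stopifnot(all(c("individual", "environment") %in% names(records)))
  idx <- match(records$individual, G$ids)
  if (anyNA(idx))
    stop("individual(s) absent from G: ",
         paste(unique(records$individual[is.na(idx)]), collapse = ", "))
  envs <- unique(records$environment)
  if (model == "SM" && length(envs) > 1)
    stop("SM requires a single environment")
  if (model == "MDe" && length(envs) < 2)
    stop("MDe requires at least 2 environments")
  Kmain <- G$G[idx, idx, drop = FALSE]
  dimnames(Kmain) <- NULL
  kernels <- list(main = Kmain)
  roles <- "main"
  same_env <- outer(records$environment, records$environment, "==")
  if (model == "MDs") {
    kernels$gxe_common <- Kmain * same_env
    roles <- c(roles, "gxe_common")
  } else if (model == "MDe") {
    for (e in envs) {
      in_e <- records$environment == e
      kernels[[paste0("gxe_env:", e)]] <- Kmain * outer(in_e, in_e, "&")
      roles <- c(roles, paste0("gxe_env:", e))
    }
  }
  X <- matrix(1, nrow(records), 1)
  colnames(X) <- "(Intercept)"
  if (length(envs) > 1) {
    for (e in envs[-1]) {
      X <- cbind(X, as.numeric(records$environment == e))
      colnames(X)[ncol(X)] <- paste0("env", e)
    }
  }
  structure(list(records = records, kernels = kernels, kernel_roles = roles,
                 X = X, model = model), class = "kernel_set")
}

#' MCMC settings for the Gibbs sampler
#'
#' The `"paper"` preset uses burn-in 2000, 70000 iterations and thinning
#' 100; the `"desk"` preset (default) is a lighter chain suitable for
#' replicated cross-validation.
#'
#' @param burn_in,n_iter,thin chain controls; `n_iter` is the total
#'   chain length including burn-in.
#' @param seed integer RNG seed.
#' @param prior_df scaled-inverse-chi-square prior degrees of freedom.
#' @param preset `"desk"` or `"paper"`; explicit arguments override.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burn_in = NULL, n_iter = NULL, thin = NULL,
                          seed = 1L, prior_df = 5,
                          preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") list(burn_in = 2000L, n_iter = 70000L,
                                     thin = 100L)
         else list(burn_in = 500L, n_iter = 5000L, thin = 5L)
  s <- list(burn_in = if (is.null(burn_in)) def$burn_in else as.integer(burn_in),
            n_iter = if (is.null(n_iter)) def$n_iter else as.integer(n_iter),
            thin = if (is.null(thin)) def$thin else as.integer(thin),
            seed = as.integer(seed), prior_df = prior_df, preset = preset)
  stopifnot(s$burn_in < s$n_iter, s$thin >= 1)
  class(s) <- "mcmc_settings"
  s
}

#' Eigendecompose the kernels of a kernel set
#'
#' Components with eigenvalue below `tol` are dropped. Decompositions can
#' be computed once and reused across cross-validation replicates that
#' share the record set (training-set membership only changes which
#' records carry observed phenotypes).
#'
#' @param kernels a `kernel_set`.
#' @param tol eigenvalue cutoff.
#' @return Named list of `list(U, d)` per kernel.
#' @export
kernel_eigen <- function(kernels, tol = 1e-8) {
  lapply(kernels$kernels, function(K) {
    e <- eigen(K, symmetric = TRUE)
    keep <- e$values > tol
    if (!any(keep)) stop("kernel has no eigenvalue above ", tol)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
}

#' Bayesian GBLUP via Gibbs sampling on kernel eigenspaces
#'
#' Model: `y = X beta + sum_k u_k + e`, `u_k ~ N(0, s2_k K_k)`,
#' `e ~ N(0, s2_e I)`. Each `u_k` is sampled in the eigenbasis of its
#' kernel, where the full conditional is diagonal; variances get
#' scaled-inverse-chi-square conjugate updates (prior scale set from the
#' sample variance of the observed phenotypes partitioned equally across
#' kernels plus residual); fixed effects have a flat prior. Records with
#' missing `y` are imputed from the model each iteration, so their
#' posterior-mean genetic values are predictions through the joint kernel
#' covariance.
#'
#' @param kernels a `kernel_set` from [build_kernels()].
#' @param y numeric response aligned with `kernels$records`; `NA` marks
#'   records to predict.
#' @param settings an [mcmc_settings()].
#' @param fix_variances optional named list `list(residual =, kernel =)`
#'   fixing the variances (no conjugate updates); used for closed-form
#'   oracle comparisons at a known variance ratio.
#' @param eigen_cache optional result of [kernel_eigen()] to reuse.
#' @return Object of class `prediction_result`: `gebv` (posterior-mean
#'   total genetic value per record), `u` (per-kernel posterior means),
#'   `variance_posterior_means`, `beta`, `effective_samples`, `records`.
#' @export
fit_gibbs <- function(kernels, y, settings = mcmc_settings(),
                      fix_variances = NULL, eigen_cache = NULL) {
  n <- nrow(kernels$records)
  stopifnot(length(y) == n)
  obs <- !is.na(y)
  if (sum(obs) < 2) stop("need at least 2 observed phenotypes")
  keep_iters <- seq(settings$burn_in + 1, settings$n_iter, by = settings$thin)
  if (length(keep_iters) < 2) stop("fewer than 2 kept samples")
  ed <- if (is.null(eigen_cache)) kernel_eigen(kernels) else eigen_cache
  K <- length(ed)
  X <- kernels$X
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("singular fixed-effect design"))
  cXtXi <- chol(XtXi)
  set.seed(settings$seed)
  vy <- stats::var(y[obs])
  if (vy == 0) vy <- 1e-8
  nu <- settings$prior_df
  share <- vy / (K + 1)
  S0 <- share * (nu - 2) / nu      # prior scale: E[s2] = share
  fixed <- !is.null(fix_variances)
  s2 <- rep(if (fixed) fix_variances$kernel else share, K)
  s2e <- if (fixed) fix_variances$residual else share
  b <- lapply(ed, function(e) numeric(length(e$d)))
  u <- matrix(0, n, K)
  beta <- drop(XtXi %*% crossprod(X, ifelse(obs, y, mean(y[obs]))))
  ycur <- y
  ycur[!obs] <- mean(y[obs])
  sum_u <- matrix(0, n, K); sum_beta <- numeric(length(beta))
  sum_s2 <- numeric(K); sum_s2e <- 0; kept <- 0
  keep_set <- logical(settings$n_iter)
  keep_set[keep_iters] <- TRUE
  utotal <- rowSums(u)
  for (it in seq_len(settings$n_iter)) {
    # fixed effects (flat prior)
    r <- ycur - utotal
    bmean <- drop(XtXi %*% crossprod(X, r))
    beta <- bmean + drop(crossprod(cXtXi, stats::rnorm(length(bmean)))) *
      sqrt(s2e)
    xb <- drop(X %*% beta)
    # kernel effects in eigenbasis (diagonal full conditionals)
    for (k in seq_len(K)) {
      rk <- ycur - xb - (utotal - u[, k])
      prec <- 1 / s2e + 1 / (s2[k] * ed[[k]]$d)
      mu_b <- (crossprod(ed[[k]]$U, rk) / s2e) / prec
      b[[k]] <- drop(mu_b) + stats::rnorm(length(prec)) / sqrt(prec)
      unew <- drop(ed[[k]]$U %*% b[[k]])
      utotal <- utotal - u[, k] + unew
      u[, k] <- unew
      if (!fixed) {
        ss <- sum(b[[k]]^2 / ed[[k]]$d)
        s2[k] <- (ss + nu * S0) / stats::rchisq(1, nu + length(b[[k]]))
      }
    }
    # residual variance and missing-phenotype imputation
    fitmean <- xb + utotal
    if (!fixed) {
      sse <- sum((ycur - fitmean)^2)
      s2e <- (sse + nu * S0) / stats::rchisq(1, nu + n)
    }
    if (any(!obs))
      ycur[!obs] <- fitmean[!obs] + stats::rnorm(sum(!obs)) * sqrt(s2e)
    if (keep_set[it]) {
      kept <- kept + 1
      sum_u <- sum_u + u
      sum_beta <- sum_beta + beta
      sum_s2 <- sum_s2 + s2
      sum_s2e <- sum_s2e + s2e
    }
  }
  u_mean <- sum_u / kept
  colnames(u_mean) <- kernels$kernel_roles
  vpost <- c(stats::setNames(sum_s2 / kept, kernels$kernel_roles),
             residual = sum_s2e / kept)
  structure(list(gebv = rowSums(u_mean), u = u_mean,
                 beta = sum_beta / kept,
                 variance_posterior_means = vpost,
                 effective_samples = kept,
                 records = kernels$records), class = "prediction_result")
}

#' @export
#' @method print prediction_result
print.prediction_result <- function(x, ...) {
  cat("prediction_result:", length(x$gebv), "records,",
      x$effective_samples, "kept samples; variances:",
      paste(names(x$variance_posterior_means),
            signif(x$variance_posterior_means, 3),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Closed-form GBLUP at a fixed variance ratio
#'
#' `u_hat = K (K + lambda I)^-1 (y - mu_hat)` on the training records;
#' held-out records are predicted as
#' `K[pred, train] (K[train, train] + lambda I)^-1 (y - mu_hat)`.
#' With `intercept = "gls"` (default) the mean `mu_hat` is the
#' generalized-least-squares intercept under covariance `K + lambda I`,
#' which makes the result identical to the Henderson mixed-model-equations
#' solution with a jointly estimated intercept — and hence to the
#' posterior mean of [fit_gibbs()] at fixed variances and a flat
#' intercept prior, up to Monte-Carlo error. `intercept = "mean"` uses
#' the simple training mean. Serves as the deterministic oracle for
#' [fit_gibbs()].
#'
#' @param K symmetric kernel over all records (training rows first is not
#'   required; `train` indexes rows of `K`).
#' @param y observed phenotypes for the training records.
#' @param lambda residual-to-genetic variance ratio (> 0).
#' @param train integer/logical index of training records (default: all).
#' @param intercept `"gls"` or `"mean"`.
#' @return Numeric vector of genetic-value predictions for all records.
#' @export
gblup_closed_form <- function(K, y, lambda, train = seq_len(nrow(K)),
                              intercept = c("gls", "mean")) {
  stopifnot(lambda > 0)
  intercept <- match.arg(intercept)
  train <- seq_len(nrow(K))[train]
  stopifnot(length(y) == length(train))
  Ktt <- K[train, train, drop = FALSE]
  A <- Ktt + diag(lambda, length(train))
  solveA <- function(b) tryCatch(solve(A, b), error = function(e)
    solve(A + diag(1e-8 * mean(diag(Ktt)), length(train)), b))
  mu <- if (intercept == "mean") mean(y) else {
    one <- rep(1, length(train))
    drop(crossprod(one, solveA(y)) / crossprod(one, solveA(one)))
  }
  sol <- solveA(y - mu)
  drop(K[, train, drop = FALSE] %*% sol)
}

#' Predictive ability
#'
#' Pearson correlation between predictions and trial-adjusted phenotypes
#' (BLUEs) over the validation families.
#'
#' @param predictions,blues aligned numeric vectors (>= 3 pairs).
#' @return Correlation, or `NA` when either vector has zero variance.
#' @export
predictive_ability <- function(predictions, blues) {
  ok <- stats::complete.cases(predictions, blues)
  if (sum(ok) < 3) stop("need at least 3 paired values")
  if (stats::sd(predictions[ok]) == 0 || stats::sd(blues[ok]) == 0)
    return(NA_real_)
  stats::cor(predictions[ok], blues[ok])
}

#' Fisher Z transform of a correlation
#'
#' `Z = 0.5 * log((1 + r) / (1 - r))`.
#'
#' @param pa correlation(s) with `|pa| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(pa) {
  if (any(abs(pa) >= 1, na.rm = TRUE)) stop("|PA| must be < 1")
  0.5 * log((1 + pa) / (1 - pa))
}
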