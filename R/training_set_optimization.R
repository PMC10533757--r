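#' Define a training-set optimization problem
#'
#' @param G a `genomic_rel` covering candidates, targets and any fixed
#'   training individuals.
#' @param candidate_ids individuals available for selection into the
#'   training set.
#' @param target_ids individuals whose predictions the criterion is
#'   evaluated on (the validation set).
#' @param n_select number of candidates to select.
#' @param lambda residual-to-genetic variance ratio
#'   (`(1 - h2) / h2`; 1 corresponds to h2 = 0.5).
#' @param fixed_ts_ids individuals always in the training set (e.g. the
#'   families already phenotyped at the surrogate location), entered as a
#'   single environment-collapsed record each.
#' @return list of class `ts_opt_problem`.
#' @export
ts_opt_problem <- function(G, candidate_ids, target_ids, n_select,
                           lambda = 1, fixed_ts_ids = character(0)) {
  stopifnot(inherits(G, "genomic_rel"), lambda > 0,
            n_select <= length(candidate_ids))
  miss <- setdiff(c(candidate_ids, target_ids, fixed_ts_ids), G$ids)
  if (length(miss)) stop("ids absent from G: ", paste(miss, collapse = ", "))
  structure(list(G = G, Ginv = chol2inv(chol(G$G)),
                 candidate_ids = candidate_ids,
                 target_ids = target_ids, n_select = as.integer(n_select),
                 lambda = lambda, fixed_ts_ids = fixed_ts_ids),
            class = "ts_opt_problem")
}

#' Mean coefficient of determination of target contrasts (CDmean)
#'
#' For each target individual i, the contrast `c_i = e_i - 1/n` between i
#' and the population mean is scored by its expected reliability under a
#' GBLUP mixed model trained on the proposed set:
#' `CD(c_i) = c_i' (G - lambda C22) c_i / (c_i' G c_i)`, where `C22` is
#' the random-effect block of the inverse coefficient matrix of the
#' mixed-model equations (intercept-only fixed effect, one record per
#' training member, variance ratio `lambda`). Returns the mean over
#' targets.
#'
#' @param problem a [ts_opt_problem()].
#' @param ts_subset character ids, a subset of `candidate_ids`; the
#'   training set is `ts_subset` plus `fixed_ts_ids`.
#' @return Mean CD, in `(0, 1)` for nondegenerate problems.
#' @export
cdmean <- function(problem, ts_subset) {
  stopifnot(all(ts_subset %in% problem$candidate_ids))
  ts <- union(ts_subset, problem$fixed_ts_ids)
  if (length(ts) == 0) stop("empty training set")
  ids <- problem$G$ids
  n <- length(ids)
  Gm <- problem$G$G
  lam <- problem$lambda
  Ginv <- problem$Ginv
  cnt <- as.numeric(ids %in% ts)         # Z'Z diagonal and Z'1
  nts <- sum(cnt)
  # Schur complement of the fixed-effect block: C22^-1 in closed form
  M <- diag(cnt) + lam * Ginv - tcrossprod(cnt) / nts
  C22 <- tryCatch(solve(M), error = function(e)
    solve(M + diag(1e-8 * mean(diag(M)), n)))
  A <- Gm - lam * C22
  targ <- match(problem$target_ids, ids)
  cds <- vapply(targ, function(i) {
    ci <- rep(-1 / n, n); ci[i] <- ci[i] + 1
    num <- drop(crossprod(ci, A %*% ci))
    den <- drop(crossprod(ci, Gm %*% ci))
    num / den
  }, numeric(1))
  mean(cds)
}

#' Genetic-algorithm settings for training-set selection
#'
#' Defaults follow common practice for this criterion: 200 iterations,
#' population 300, 10 elite solutions.
#'
#' @param n_iterations,pop_size,n_elites GA controls.
#' @param mutation_rate probability a child swaps one member.
#' @param seed integer RNG seed.
#' @return list of class `ga_settings`.
#' @export
ga_settings <- function(n_iterations = 200, pop_size = 300, n_elites = 10,
                        mutation_rate = 0.1, seed = 1L) {
  stopifnot(n_elites < pop_size)
  structure(list(n_iterations = as.integer(n_iterations),
                 pop_size = as.integer(pop_size),
                 n_elites = as.integer(n_elites),
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "ga_settings")
}

#' Select a training set by genetic algorithm on the CDmean criterion
#'
#' Fixed-size index-set encoding; tournament selection (size 3), uniform
#' crossover on set membership with repair to the exact size, one-member
#' swap mutation, and elitism. The best-so-far criterion trajectory is
#' non-decreasing by construction.
#'
#' @param problem a [ts_opt_problem()].
#' @param settings a [ga_settings()].
#' @return list with `selected` (character ids, length `n_select`),
#'   `criterion`, and `trajectory` (data.frame generation/best/mean).
#' @export
ga_select <- function(problem, settings = ga_settings()) {
  set.seed(settings$seed)
  cand <- problem$candidate_ids
  k <- problem$n_select
  if (k == length(cand)) {
    sel <- cand
    return(list(selected = sel, criterion = cdmean(problem, sel),
                trajectory = data.frame(generation = 0L,
                                        best = cdmean(problem, sel),
                                        mean = cdmean(problem, sel))))
  }
  np <- settings$pop_size
  pop <- replicate(np, sort(sample(cand, k)), simplify = FALSE)
  fit <- vapply(pop, function(s) cdmean(problem, s), numeric(1))
  traj <- data.frame(generation = 0L, best = max(fit), mean = mean(fit))
  tourney <- function() {
    i <- sample.int(np, 3)
    i[which.max(fit[i])]
  }
  for (g in seq_len(settings$n_iterations)) {
    ord <- order(fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(settings$n_elites)]]
    newfit <- fit[ord[seq_len(settings$n_elites)]]
    while (length(newpop) < np) {
      p1 <- pop[[tourney()]]; p2 <- pop[[tourney()]]
      pool <- union(p1, p2)
      child <- if (length(pool) <= k) pool else sample(pool, k)
      if (length(child) < k)
        child <- c(child, sample(setdiff(cand, child), k - length(child)))
      if (stats::runif(1) < settings$mutation_rate) {
        out_id <- sample(child, 1)
        in_id <- sample(setdiff(cand, child), 1)
        child <- c(setdiff(child, out_id), in_id)
      }
      child <- sort(child)
      newpop[[length(newpop) + 1]] <- child
      newfit <- c(newfit, cdmean(problem, child))
    }
    pop <- newpop; fit <- newfit
    traj <- rbind(traj, data.frame(generation = g,
                                   best = max(max(fit), traj$best[nrow(traj)]),
                                   mean = mean(fit)))
  }
  best <- which.max(fit)
  list(selected = pop[[best]], criterion = fit[best], trajectory = traj)
}

#' Random training-set draw
#'
#' Uniform sampling without replacement.
#'
#' @param candidates character ids.
#' @param n_select number to draw.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return Character ids of the selected subset.
#' @export
random_select <- function(candidates, n_select, seed = NULL) {
  stopifnot(n_select <= length(candidates))
  if (!is.null(seed)) set.seed(seed)
  sort(sample(candidates, n_select))
}
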