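# Statistical machinery: head-to-head bootstrap significance, Hungarian
# difficulty matching, KDE-weighted bootstrap resampling, the paired
# progress test, and the metric correlation matrix.

#' Head-to-head bootstrap win fraction between two groups
#'
#' Resamples the common EUs with replacement; in each replicate the two
#' groups are compared on the EU-weight-weighted sum of their composite
#' z-scores. A strict win counts 1, a tie counts 0.5 for each side.
#'
#' @param tA,tB Data frames with columns `eu`, `weight`, `composite` for
#'   the two groups (e.g. rows of [eu_composites()]).
#' @param n_boot Number of bootstrap replicates (the assessment
#'   convention is 1000).
#' @param seed Integer seed; fixed seed gives identical fractions.
#' @return Fraction of replicates won by the first group, in [0, 1].
#' @export
head_to_head <- function(tA, tB, n_boot = 1000, seed = 1) {
  common <- intersect(tA$eu, tB$eu)
  if (!length(common)) stop("no common EUs between the two groups")
  a <- tA$composite[match(common, tA$eu)]
  b <- tB$composite[match(common, tB$eu)]
  w <- tA$weight[match(common, tA$eu)]
  set.seed(seed)
  n <- length(common)
  wins <- 0
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sa <- sum(w[idx] * a[idx])
    sb <- sum(w[idx] * b[idx])
    wins <- wins + if (sa > sb) 1 else if (sa == sb) 0.5 else 0
  }
  wins / n_boot
}

#' Pairwise head-to-head matrix over a set of groups
#'
#' @param comp Output of [eu_composites()] (only rows with
#'   `submitted = TRUE` enter the comparison for each group).
#' @param groups Groups to compare (default: all in `comp`).
#' @param n_boot,seed See [head_to_head()].
#' @param alpha Confidence level for significance flags.
#' @return List of class `head_to_head_matrix`: `groups` (ordered by
#'   descending row sum of win fractions), `win_fraction`, `significant`,
#'   `n_boot`, `alpha`.
#' @export
head_to_head_matrix <- function(comp, groups = NULL, n_boot = 1000,
                                seed = 1, alpha = 0.05) {
  if (is.null(groups)) groups <- sort(unique(comp$group))
  k <- length(groups)
  wf <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  per_group <- lapply(groups, function(g)
    comp[comp$group == g & comp$submitted, c("eu", "weight", "composite")])
  names(per_group) <- groups
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (j > i) {
        # one bootstrap stream per unordered pair keeps the matrix
        # complementary: wf[i,j] + wf[j,i] = 1 under tie-splitting
        wf[i, j] <- head_to_head(per_group[[i]], per_group[[j]],
                                 n_boot = n_boot,
                                 seed = seed + i * 1009L + j)
        wf[j, i] <- 1 - wf[i, j]
      }
    }
  }
  ord <- order(-rowSums(wf, na.rm = TRUE))
  wf <- wf[ord, ord]
  structure(list(groups = groups[ord], win_fraction = wf,
                 significant = significance_matrix(wf, alpha),
                 n_boot = n_boot, alpha = alpha),
            class = "head_to_head_matrix")
}

#' Significance flags from a win-fraction matrix
#'
#' A pairwise difference is significant at confidence `alpha` when the
#' win fraction reaches `1 - alpha`.
#'
#' @param win_fraction Square matrix of bootstrap win fractions (or a
#'   `head_to_head_matrix`).
#' @param alpha Confidence level in (0, 1).
#' @return Logical matrix.
#' @export
significance_matrix <- function(win_fraction, alpha = 0.05) {
  if (inherits(win_fraction, "head_to_head_matrix"))
    win_fraction <- win_fraction$win_fraction
  stopifnot(alpha > 0, alpha < 1)
  win_fraction >= 1 - alpha
}

# ---- Hungarian assignment ------------------------------------------------

# O(n^3) shortest augmenting path algorithm for the square assignment
# problem (minimization); returns for each row the assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign_col <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign_col[p[j]] <- j - 1L
  assign_col
}

#' Difficulty-matched one-to-one assignment (Hungarian algorithm)
#'
#' Matches every reference item to a distinct source item minimizing the
#' total absolute difficulty difference. Surplus source items stay
#' unmatched (rectangular assignment via zero-cost dummy references).
#' Ties are broken toward the lower source index.
#'
#' @param d_source,d_reference Numeric difficulty vectors (e.g. baseline
#'   first-model GDT_HA per EU); the source must be at least as large as
#'   the reference.
#' @param best_source,best_reference Optional per-EU best scores carried
#'   into the result for the downstream progress test.
#' @return List of class `match_result`: `pairs` (data frame
#'   `source_idx`, `reference_idx`), `total_cost`, `mean_difficulty`
#'   (source-matched, reference), and when best scores are supplied,
#'   `best` (data frame of matched best-score pairs) and `mean_best`.
#' @export
hungarian_match <- function(d_source, d_reference,
                            best_source = NULL, best_reference = NULL) {
  ns <- length(d_source); nr <- length(d_reference)
  if (!ns || !nr) stop("empty difficulty vector")
  if (nr > ns) stop("reference set larger than source set")
  # square cost matrix: rows = source, columns = reference + dummies.
  # a tiny index-proportional epsilon on real columns steers ties to the
  # lower source index without affecting optimality.
  eps <- 1e-9
  cost <- matrix(0, ns, ns)
  cost[, seq_len(nr)] <- abs(outer(d_source, d_reference, "-")) +
    eps * seq_len(ns)
  assign_col <- solve_assignment(cost)
  src <- which(assign_col <= nr)
  pairs <- data.frame(source_idx = src, reference_idx = assign_col[src])
  pairs <- pairs[order(pairs$reference_idx), ]
  rownames(pairs) <- NULL
  total <- sum(abs(d_source[pairs$source_idx] - d_reference[pairs$reference_idx]))
  out <- list(pairs = pairs, total_cost = total,
              mean_difficulty = c(source = mean(d_source[pairs$source_idx]),
                                  reference = mean(d_reference[pairs$reference_idx])))
  if (!is.null(best_source) && !is.null(best_reference)) {
    out$best <- data.frame(source = best_source[pairs$source_idx],
                           reference = best_reference[pairs$reference_idx])
    out$mean_best <- c(source = mean(out$best$source),
                       reference = mean(out$best$reference))
  }
  structure(out, class = "match_result")
}

# ---- KDE-weighted bootstrap ---------------------------------------------

# Gaussian KDE evaluated at points; Scott's rule bandwidth by default
gaussian_kde <- function(data, at, bandwidth = NULL) {
  if (is.null(bandwidth))
    bandwidth <- stats::sd(data) * length(data)^(-1 / 5)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    bandwidth <- max(diff(range(data)) / 10, 1e-3)
  vapply(at, function(x) mean(stats::dnorm(x, data, bandwidth)), 0)
}

#' Difficulty-weighted bootstrap resampling
#'
#' Fits Gaussian kernel density estimates to the source and reference
#' difficulty distributions and resamples source records with weights
#' proportional to the density ratio `f_ref(d) / f_src(d)`, so each
#' bootstrap sample mimics the reference difficulty distribution.
#'
#' @param d_source,d_reference Numeric difficulty vectors (>= 2 each).
#' @param best_source Optional per-record best scores of the source;
#'   their resampled means are reported per sample.
#' @param best_reference Optional reference best scores; when given, the
#'   fraction of samples whose mean best exceeds their mean is reported.
#' @param n Records per sample (default: reference set size).
#' @param n_samples Number of bootstrap samples.
#' @param seed Integer seed.
#' @param bandwidth `NULL` for Scott's rule, or a numeric bandwidth.
#' @param weight_floor Densities below this floor are clipped (with a
#'   warning) to keep weights finite.
#' @return List: `samples` (list of index vectors), `mean_difficulty` and
#'   `mean_best` (per-sample means; the latter `NULL` without
#'   `best_source`), `weights`, and `frac_better` when reference best
#'   scores are supplied.
#' @export
kde_weighted_resample <- function(d_source, d_reference, best_source = NULL,
                                  best_reference = NULL, n = NULL,
                                  n_samples = 1000, seed = 1,
                                  bandwidth = NULL, weight_floor = 1e-12) {
  if (length(d_source) < 2 || length(d_reference) < 2)
    stop("source and reference need at least 2 records each")
  if (is.null(n)) n <- length(d_reference)
  stopifnot(n >= 1)
  f_src <- gaussian_kde(d_source, d_source, bandwidth)
  f_ref <- gaussian_kde(d_reference, d_source, bandwidth)
  if (any(!is.finite(f_src) | f_src < weight_floor)) {
    warning("source density at or below floor; clipping")
    f_src <- pmax(f_src, weight_floor)
  }
  w <- f_ref / f_src
  if (any(!is.finite(w))) {
    warning("non-finite resampling weight; clipping")
    w[!is.finite(w)] <- weight_floor
  }
  w <- w / sum(w)
  set.seed(seed)
  samples <- lapply(seq_len(n_samples), function(r)
    sample.int(length(d_source), n, replace = TRUE, prob = w))
  mean_diff <- vapply(samples, function(s) mean(d_source[s]), 0)
  mean_best <- if (!is.null(best_source))
    vapply(samples, function(s) mean(best_source[s]), 0)
  out <- list(samples = samples, mean_difficulty = mean_diff,
              mean_best = mean_best, weights = w)
  if (!is.null(mean_best) && !is.null(best_reference))
    out$frac_better <- mean(mean_best > mean(best_reference))
  out
}

#' Paired progress test on difficulty-matched EUs
#'
#' Tests whether the reference experiment's best scores exceed the
#' matched source scores: paired differences (reference - source), mean
#' difference, and the two-sided p-value of a paired t-test (default) or
#' paired Wilcoxon signed-rank test. With zero variance in the
#' differences the t statistic is undefined; the p-value is then 1 for a
#' zero mean difference and 0 otherwise (the limit of an epsilon-jitter).
#'
#' @param matched A `match_result` carrying `best` (from
#'   [hungarian_match()] with best scores), or a data frame with columns
#'   `source` and `reference`.
#' @param method `"t"` or `"wilcoxon"`.
#' @return List: `mean_difference`, `p_value`, `n`, `method`.
#' @export
progress_test <- function(matched, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  best <- if (inherits(matched, "match_result")) matched$best else matched
  if (is.null(best) || nrow(best) < 2)
    stop("progress test needs at least 2 matched pairs with best scores")
  d <- best$reference - best$source
  md <- mean(d)
  if (stats::sd(d) < 1e-10 * max(abs(md), 1)) {
    p <- if (md == 0) 1 else 0
  } else if (method == "t") {
    p <- stats::t.test(best$reference, best$source, paired = TRUE)$p.value
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(best$reference, best$source, paired = TRUE))$p.value
  }
  list(mean_difference = md, p_value = p, n = nrow(best), method = method)
}

#' Pearson correlation matrix of metrics over complete score rows
#'
#' Pivots a long score table to wide (one row per group/EU/model) and
#' correlates raw scores over rows complete for all requested metrics.
#' Metrics constant across rows get `NA` correlations.
#'
#' @param t Long score table.
#' @param metrics Metric names (>= 2).
#' @return Correlation matrix.
#' @export
metric_correlation <- function(t, metrics) {
  validate_score_table(t)
  if (length(metrics) < 2) stop("need at least 2 metrics")
  t <- t[t$metric %in% metrics, ]
  key <- paste(t$group, t$eu, t$model, sep = "\r")
  wide <- matrix(NA_real_, length(unique(key)), length(metrics),
                 dimnames = list(unique(key), metrics))
  wide[cbind(match(key, rownames(wide)), match(t$metric, metrics))] <- t$value
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) < 3) stop("fewer than 3 complete rows")
  const <- apply(wide, 2, function(x) stats::sd(x) == 0)
  cm <- suppressWarnings(stats::cor(wide))
  cm[const, ] <- NA; cm[, const] <- NA
  diag(cm) <- 1
  cm
}
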