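# Ranking engine: model selection, within-model imputation, two-round
# z-scores with outlier exclusion and a -2 floor, the weighted nine-metric
# composite, EU-weighted group totals, and first-model statistics.
#
# Score tables are long-form data frames with columns
# group, target, eu, phase, model, metric, value.

RANKING_METRICS <- c("gdt_ha", "ase", "rellg_const", "sphgr", "cad_aa",
                     "gdc_sc", "al0_p", "lddt", "molprobity")

#' Default composite weight scheme
#'
#' The nine-metric scheme: weight 1/6 for GDT_HA, ASE (QSE) and
#' reLLG_const; 1/8 for SphGr and CAD_AA; 1/16 for GDC_SC, AL0_P, lDDT
#' and MolProbity. MolProbity is oriented lower-is-better; all others
#' higher-is-better. Weights sum to 1.
#'
#' @return Data frame with columns `metric`, `weight`, `orientation`.
#' @export
default_weight_scheme <- function() {
  data.frame(
    metric = RANKING_METRICS,
    weight = c(1/6, 1/6, 1/6, 1/8, 1/8, 1/16, 1/16, 1/16, 1/16),
    orientation = c(rep("higher_better", 8), "lower_better"),
    stringsAsFactors = FALSE)
}

validate_weight_scheme <- function(w) {
  stopifnot(is.data.frame(w),
            all(c("metric", "weight", "orientation") %in% names(w)))
  if (abs(sum(w$weight) - 1) > 1e-12)
    stop("weight scheme must sum to 1 (got ", sum(w$weight), ")")
  if (!all(w$orientation %in% c("higher_better", "lower_better")))
    stop("orientation must be higher_better or lower_better")
  w
}

#' Renormalize a weight scheme to the metrics actually available
#'
#' Drops metrics absent from `available` and rescales the remaining
#' weights to sum to 1. Used when externally computed metrics
#' (MolProbity, CAD_AA, SphGr, reLLG_const) are not supplied.
#'
#' @param w Weight scheme data frame.
#' @param available Character vector of metric names present.
#' @return Renormalized weight scheme.
#' @export
renormalize_weights <- function(w, available) {
  keep <- w$metric %in% available
  if (!any(keep)) stop("no scheme metric is available")
  if (!all(keep))
    warning("metrics dropped from weight scheme (weights renormalized): ",
            paste(w$metric[!keep], collapse = ", "))
  w <- w[keep, , drop = FALSE]
  w$weight <- w$weight / sum(w$weight)
  rownames(w) <- NULL
  w
}

validate_score_table <- function(t) {
  need <- c("group", "eu", "model", "metric", "value")
  if (!all(need %in% names(t)))
    stop("score table must have columns ", paste(need, collapse = ", "))
  if (!nrow(t)) stop("empty score table")
  t
}

#' Two-round z-scores for one EU and metric
#'
#' Round 1 computes z-scores from the mean and population standard
#' deviation of all submitted values; entries with z below -2 are treated
#' as outliers and excluded. Round 2 recomputes mean/sd from the
#' remainder and assigns z to every group from those parameters; final
#' values are floored at -2. Groups listed in `groups` with no submission
#' receive -2 (flag `imputed_missing`). Lower-is-better metrics are
#' negated before standardization. With zero round-2 spread, members of
#' the remainder get z = 0.
#'
#' @param values Named numeric vector (names = groups) of raw metric
#'   values for one EU; may omit groups.
#' @param orientation `"higher_better"` or `"lower_better"`.
#' @param groups All groups that should appear in the output; defaults to
#'   `names(values)`.
#' @param floor Floor for final z-scores (-2 default; 0 gives the
#'   alternative floor-at-zero strategy).
#' @return Data frame: `group`, `z`, and logical flags `imputed_missing`,
#'   `floored`, `excluded_round1`.
#' @export
two_round_z <- function(values, orientation = "higher_better",
                        groups = names(values), floor = -2) {
  v <- values[!is.na(values)]
  if (orientation == "lower_better") v <- -v
  out <- data.frame(group = groups, z = floor, imputed_missing = TRUE,
                    floored = FALSE, excluded_round1 = FALSE,
                    stringsAsFactors = FALSE)
  if (length(v) < 2) {
    warning("fewer than 2 scored groups: all z set to 0")
    out$z <- 0
    out$imputed_missing <- !(groups %in% names(v))
    return(out)
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  s1 <- pop_sd(v)
  z1 <- if (s1 > 0) (v - mean(v)) / s1 else rep(0, length(v))
  keep <- z1 >= -2
  v2 <- v[keep]
  m2 <- mean(v2)
  s2 <- pop_sd(v2)
  z2 <- if (s2 > 0) (v - m2) / s2 else ifelse(v == m2, 0, sign(v - m2) * Inf)
  zfin <- pmax(z2, floor)
  zfin[!is.finite(zfin)] <- 0  # defensive: +Inf cannot arise from exclusion
  i <- match(names(v), out$group)
  out$z[i] <- zfin
  out$imputed_missing[i] <- FALSE
  out$floored[i] <- z2 < floor
  out$excluded_round1[i] <- !keep
  out
}

#' Impute missing metric values for submitted models
#'
#' A submitted model lacking a value for one metric receives the worst
#' observed value of that metric for the EU: the minimum for
#' higher-is-better metrics, the maximum for lower-is-better ones.
#' Entirely missing submissions are not touched here; they are imputed at
#' the z-score level. A metric with no observed value on an EU is dropped
#' for that EU with a warning.
#'
#' @param t Long score table (`group`, `eu`, `model`, `metric`, `value`;
#'   `NA` value = submitted but unscored).
#' @param scheme Weight scheme giving each metric's orientation.
#' @return The score table with `NA` values filled in.
#' @export
impute_unscored <- function(t, scheme = default_weight_scheme()) {
  validate_score_table(t)
  miss <- which(is.na(t$value))
  if (!length(miss)) return(t)
  ori <- scheme$orientation[match(t$metric, scheme$metric)]
  ori[is.na(ori)] <- "higher_better"
  key <- paste(t$eu, t$metric)
  for (i in miss) {
    obs <- t$value[key == key[i] & !is.na(t$value)]
    if (!length(obs)) {
      warning("metric ", t$metric[i], " has no scored model on EU ",
              t$eu[i], ": dropped for that EU")
      next
    }
    t$value[i] <- if (ori[i] == "lower_better") max(obs) else min(obs)
  }
  t[!(is.na(t$value)), , drop = FALSE]
}

#' Composite weighted z-score
#'
#' Weighted sum of per-metric z-scores under a weight scheme. Orientation
#' is already handled during standardization, so all z enter positively.
#'
#' @param z Named numeric vector of per-metric z-scores (must cover every
#'   scheme metric).
#' @param scheme Weight scheme data frame.
#' @return Single number.
#' @export
composite_z <- function(z, scheme = default_weight_scheme()) {
  validate_weight_scheme(scheme)
  missing <- setdiff(scheme$metric, names(z))
  if (length(missing))
    stop("z-scores missing for scheme metric(s): ",
         paste(missing, collapse = ", "))
  sum(scheme$weight * z[scheme$metric])
}

# per-model composite z used only to pick each group's best model:
# one-round z over all submitted models of the EU, per metric
model_composites <- function(sub, scheme) {
  sub_index <- unique(sub[c("group", "model")])
  names_idx <- paste(sub_index$group, sub_index$model)
  comp <- setNames(numeric(length(names_idx)), names_idx)
  wsum <- setNames(numeric(length(names_idx)), names_idx)
  for (met in unique(sub$metric)) {
    srow <- scheme[scheme$metric == met, ]
    if (!nrow(srow)) next
    rows <- sub[sub$metric == met, ]
    v <- rows$value
    if (srow$orientation == "lower_better") v <- -v
    s <- sqrt(mean((v - mean(v))^2))
    z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    k <- paste(rows$group, rows$model)
    comp[k] <- comp[k] + srow$weight * z
    wsum[k] <- wsum[k] + srow$weight
  }
  data.frame(group = sub_index$group, model = sub_index$model,
             composite = as.numeric(comp), stringsAsFactors = FALSE)
}

#' Select one model per group and EU
#'
#' `"first"` takes model index 1, or the lowest index submitted when no
#' model 1 exists. `"best"` takes the model maximizing a composite
#' weighted z computed over all models of the EU (ties go to the lowest
#' index). `"model6"` takes model 6 only; groups without a model 6 simply
#' drop out. Models with index 6 are not candidates for first/best.
#'
#' @param t Long score table.
#' @param mode `"best"`, `"first"` or `"model6"`.
#' @param scheme Weight scheme used by `"best"`.
#' @return Score table restricted to the selected model per (group, eu).
#' @export
select_models <- function(t, mode = c("best", "first", "model6"),
                          scheme = default_weight_scheme()) {
  mode <- match.arg(mode)
  validate_score_table(t)
  if (mode == "model6") return(t[t$model == 6, , drop = FALSE])
  t <- t[t$model <= 5, , drop = FALSE]
  if (!nrow(t)) stop("no models with index <= 5 in score table")
  keep <- logical(nrow(t))
  for (eu in unique(t$eu)) {
    te <- t$eu == eu
    sub <- t[te, ]
    if (mode == "first") {
      low <- stats::aggregate(model ~ group, sub, min)
      sel <- paste(low$group, low$model)
    } else {
      mc <- model_composites(sub, scheme)
      # order: composite descending, model index ascending; first per group
      mc <- mc[order(mc$group, -mc$composite, mc$model), ]
      mc <- mc[!duplicated(mc$group), ]
      sel <- paste(mc$group, mc$model)
    }
    keep[te] <- paste(sub$group, sub$model) %in% sel
  }
  t[keep, , drop = FALSE]
}

#' Aggregate EU-level z-scores into a group ranking
#'
#' For every EU and metric, two-round z-scores are computed across groups
#' (one model per group, chosen by `mode`); the per-EU composite is the
#' weighted sum over metrics; the group total is the EU-weight-weighted
#' sum over all EUs, so each target carries equal weight.
#'
#' @param t Long score table.
#' @param eus List of `eu_definition` objects (or a data frame with
#'   columns `eu` and `weight`) covering every EU in the table.
#' @param scheme Weight scheme.
#' @param mode Model-selection mode (see [select_models()]).
#' @param floor z floor (-2 default, 0 for the alternative strategy).
#' @param groups Group universe; groups listed here but absent from the
#'   table receive the floor z on every EU. Default: groups in the table.
#' @return Data frame of class `group_ranking`, sorted by descending
#'   `total_z`, with one column of per-EU-summed contribution per metric.
#' @export
aggregate_ranking <- function(t, eus, scheme = default_weight_scheme(),
                              mode = "best", floor = -2, groups = NULL) {
  validate_weight_scheme(scheme)
  sel <- select_models(t, mode, scheme)
  sel <- sel[sel$metric %in% scheme$metric, , drop = FALSE]
  if (is.data.frame(eus)) {
    wEU <- setNames(eus$weight, eus$eu)
  } else {
    wEU <- setNames(vapply(eus, `[[`, 0, "weight"),
                    vapply(eus, `[[`, "", "eu_id"))
  }
  unknown <- setdiff(unique(sel$eu), names(wEU))
  if (length(unknown))
    stop("EU(s) in score table without definition: ",
         paste(unknown, collapse = ", "))
  groups <- if (is.null(groups)) sort(unique(sel$group))
            else sort(union(groups, unique(sel$group)))
  total <- setNames(numeric(length(groups)), groups)
  contrib <- matrix(0, length(groups), nrow(scheme),
                    dimnames = list(groups, scheme$metric))
  n_sub <- setNames(integer(length(groups)), groups)
  for (eu in unique(sel$eu)) {
    sub <- sel[sel$eu == eu, ]
    n_sub[unique(sub$group)] <- n_sub[unique(sub$group)] + 1L
    for (i in seq_len(nrow(scheme))) {
      met <- scheme$metric[i]
      rows <- sub[sub$metric == met, ]
      vals <- setNames(rows$value, rows$group)
      zz <- suppressWarnings(
        two_round_z(vals, scheme$orientation[i], groups = groups,
                    floor = floor))
      add <- wEU[eu] * scheme$weight[i] * zz$z
      total <- total + setNames(add, zz$group)[groups]
      contrib[, met] <- contrib[, met] + setNames(add, zz$group)[groups]
    }
  }
  out <- data.frame(group = groups, total_z = as.numeric(total),
                    n_submitted = as.integer(n_sub),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(contrib))
  out <- out[order(-out$total_z, out$group), ]
  rownames(out) <- NULL
  class(out) <- c("group_ranking", class(out))
  out
}

#' @export
print.group_ranking <- function(x, n = 10, ...) {
  cat("Group ranking (total composite z, EU-weighted)\n")
  print.data.frame(utils::head(x[c("group", "total_z", "n_submitted")], n),
                   row.names = TRUE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more groups\n")
  invisible(x)
}

#' Per-EU composite z-scores for each group
#'
#' The building block for head-to-head bootstrap comparisons: the same
#' two-round z and composite as [aggregate_ranking()], but returned per
#' (group, EU) instead of summed.
#'
#' @inheritParams aggregate_ranking
#' @return Data frame: `group`, `eu`, `weight` (EU weight), `composite`.
#' @export
eu_composites <- function(t, eus, scheme = default_weight_scheme(),
                          mode = "best", floor = -2) {
  validate_weight_scheme(scheme)
  sel <- select_models(t, mode, scheme)
  sel <- sel[sel$metric %in% scheme$metric, , drop = FALSE]
  if (is.data.frame(eus)) {
    wEU <- setNames(eus$weight, eus$eu)
  } else {
    wEU <- setNames(vapply(eus, `[[`, 0, "weight"),
                    vapply(eus, `[[`, "", "eu_id"))
  }
  groups <- sort(unique(sel$group))
  res <- list()
  for (eu in unique(sel$eu)) {
    sub <- sel[sel$eu == eu, ]
    comp <- setNames(numeric(length(groups)), groups)
    for (i in seq_len(nrow(scheme))) {
      met <- scheme$metric[i]
      rows <- sub[sub$metric == met, ]
      zz <- suppressWarnings(
        two_round_z(setNames(rows$value, rows$group),
                    scheme$orientation[i], groups = groups))
      comp <- comp + scheme$weight[i] * setNames(zz$z, zz$group)[groups]
    }
    res[[eu]] <- data.frame(group = groups, eu = eu,
                            weight = unname(wEU[eu]),
                            composite = as.numeric(comp),
                            submitted = groups %in% unique(sub$group),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Frequency of a group's first model being its best
#'
#' Over EUs where a group submitted at least two models, counts those
#' where the first model (index 1, or lowest submitted index) attains the
#' maximum of the chosen metric among the group's models; ties are
#' credited to the first model.
#'
#' @param t Long score table.
#' @param metric Metric to compare on (default `"gdt_ha"`).
#' @return Data frame: `group`, `count_best_first`, `n_targets`, `ratio`.
#' @export
first_model_best_frequency <- function(t, metric = "gdt_ha") {
  validate_score_table(t)
  t <- t[t$metric == metric & t$model <= 5 & !is.na(t$value), ]
  if (!nrow(t)) stop("no rows for metric ", metric)
  key <- paste(t$group, t$eu, sep = "\r")
  nmod <- stats::ave(t$model, key, FUN = function(m) length(unique(m)))
  t <- t[nmod >= 2, ]
  if (!nrow(t)) stop("no (group, EU) blocks with >= 2 models")
  key <- paste(t$group, t$eu, sep = "\r")
  vmax <- stats::ave(t$value, key, FUN = max)
  mmin <- stats::ave(t$model, key, FUN = min)
  firsts <- t$model == mmin
  hit <- firsts & (t$value >= vmax - 1e-12)
  per_block <- data.frame(group = t$group[firsts], hit = hit[firsts])
  agg <- stats::aggregate(hit ~ group, per_block, function(h) c(sum(h), length(h)))
  out <- data.frame(group = agg$group,
                    count_best_first = agg$hit[, 1],
                    n_targets = agg$hit[, 2],
                    ratio = agg$hit[, 1] / agg$hit[, 2],
                    stringsAsFactors = FALSE)
  out[order(-out$ratio, out$group), ]
}
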