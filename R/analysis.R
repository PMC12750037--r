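# Secondary analyses: EU difficulty classification, interface vs
# non-interface accuracy, Grishin merge check, model-6 ratios,
# cross-phase deltas, and best-of-pool comparison.

#' EU difficulty from the 95% quantile of GDT_TS
#'
#' Computes `GDT_TS95`, the 95th percentile of GDT_TS over all models of
#' each EU (linear-interpolation quantile, R type 7), and labels an EU
#' difficult when `GDT_TS95` falls below a size-dependent partition line
#' `slope * size + intercept`. Larger EUs tend to score lower because
#' coordinate errors accumulate globally, which the line absorbs.
#'
#' @param t Long score table with `gdt_ts` rows.
#' @param sizes Named vector: EU -> residue count.
#' @param line Numeric `c(slope, intercept)` of the partition line.
#' @return Data frame: `eu`, `gdt_ts95`, `size`, `label`.
#' @export
eu_difficulty <- function(t, sizes, line = c(0, 60)) {
  validate_score_table(t)
  t <- t[t$metric == "gdt_ts" & !is.na(t$value), ]
  eus <- unique(t$eu)
  missing <- setdiff(eus, names(sizes))
  if (length(missing))
    stop("missing sizes for EU(s): ", paste(missing, collapse = ", "))
  q95 <- vapply(eus, function(e) {
    v <- t$value[t$eu == e]
    if (length(v) < 5) stop("EU ", e, " has fewer than 5 GDT_TS values")
    stats::quantile(v, 0.95, type = 7, names = FALSE)
  }, 0)
  size <- sizes[eus]
  data.frame(eu = eus, gdt_ts95 = q95, size = as.numeric(size),
             label = ifelse(q95 < line[1] * size + line[2],
                            "difficult", "easy"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Interface residues between units of an assembly
#'
#' A residue is an interface residue iff any of its heavy atoms lies
#' within `cutoff` of a heavy atom of a residue assigned to a different
#' unit (chain or EU).
#'
#' @param assembly A `casp_structure`.
#' @param partition Named character/integer vector: residue key -> unit
#'   id (defaults to the chain id of each residue).
#' @param cutoff Contact distance in Angstrom (default 5).
#' @return Character vector of interface residue keys.
#' @export
interface_residues <- function(assembly, partition = NULL, cutoff = 5) {
  a <- assembly$atoms[assembly$atoms$record == "ATOM", ]
  a <- a[a$elem != "H", ]
  if (is.null(partition)) {
    rt <- residue_table(assembly)
    partition <- setNames(rt$chain, rt$res_key)
  }
  unit <- partition[a$res_key]
  if (length(unique(unit)) < 2)
    stop("interface definition needs at least 2 units")
  xyz <- cbind(a$x, a$y, a$z)
  d <- as.matrix(stats::dist(xyz))
  contact <- d <= cutoff & outer(unit, unit, "!=")
  iface <- unique(a$res_key[rowSums(contact) > 0])
  iface
}

#' Interface vs non-interface accuracy split
#'
#' Pools per-residue mainchain scores of models whose global GDT_TS
#' exceeds `gate` (so only essentially correct models enter) and reports
#' the mean over interface residues and over the complement.
#'
#' @param per_res_list List (one element per model) of named per-residue
#'   score vectors (e.g. per-residue mainchain GDC).
#' @param gdt_ts_values Numeric vector of the models' global GDT_TS.
#' @param iface Character vector of interface residue keys.
#' @param gate GDT_TS gate (default 80, strict `>`).
#' @return List: `interface_mean`, `non_interface_mean`, `models_used`.
#' @export
interface_split <- function(per_res_list, gdt_ts_values, iface, gate = 80) {
  keep <- which(gdt_ts_values > gate)
  if (!length(keep)) stop("no model passes the GDT_TS gate of ", gate)
  inside <- numeric(0); outside <- numeric(0)
  for (i in keep) {
    pr <- per_res_list[[i]]
    is_if <- names(pr) %in% iface
    inside <- c(inside, pr[is_if])
    outside <- c(outside, pr[!is_if])
  }
  list(interface_mean = mean(inside), non_interface_mean = mean(outside),
       models_used = length(keep))
}

#' Grishin-plot merge check for two EUs
#'
#' Decides whether two provisional EUs should be evaluated as one unit:
#' for each model, the merged-unit GDT_TS is compared against the better
#' of the two split-unit scores. The degradation statistic is the median
#' over models of `min(d1, d2) - merged`; merging is recommended when it
#' does not exceed `tolerance` (boundary inclusive).
#'
#' @param scores_d1,scores_d2,scores_merged Named numeric vectors of
#'   per-model GDT_TS for the two parts and the merged unit (same model
#'   set).
#' @param tolerance Maximum acceptable degradation (score points).
#' @return List: `decision` (`"merge"` or `"keep_split"`), `degradation`,
#'   and `plot_data` (per-model `min_split` vs `merged`, the Grishin
#'   scatter).
#' @export
grishin_merge_check <- function(scores_d1, scores_d2, scores_merged,
                                tolerance = 10) {
  models <- names(scores_d1)
  if (!setequal(models, names(scores_d2)) ||
      !setequal(models, names(scores_merged)))
    stop("mismatched model sets across the three score lists")
  min_split <- pmin(scores_d1[models], scores_d2[models])
  merged <- scores_merged[models]
  degradation <- stats::median(min_split - merged)
  list(decision = if (degradation <= tolerance) "merge" else "keep_split",
       degradation = degradation,
       plot_data = data.frame(model = models, min_split = min_split,
                              merged = merged, row.names = NULL))
}

#' Model-6 ratio evaluation
#'
#' For each group and each target where both model 6 and the baseline
#' model 1 are scored, computes the metric ratio model6 / baseline and
#' averages over targets. The baseline is either the group's own model 1
#' or an external group's model 1 (e.g. an automated reference
#' predictor).
#'
#' @param t Long score table.
#' @param baseline `"own_model1"` or the name of a baseline group whose
#'   model 1 supplies the denominator.
#' @param metric Metric name (default `"gdt_ha"`).
#' @return Data frame: `group`, `mean_ratio`, `n`.
#' @export
model6_ratio <- function(t, baseline = "own_model1", metric = "gdt_ha") {
  validate_score_table(t)
  t <- t[t$metric == metric & !is.na(t$value), ]
  m6 <- t[t$model == 6, ]
  if (!nrow(m6)) stop("no model-6 rows for metric ", metric)
  res <- list()
  for (g in unique(m6$group)) {
    num <- m6[m6$group == g, ]
    den <- if (identical(baseline, "own_model1"))
      t[t$group == g & t$model == 1, ]
    else
      t[t$group == baseline & t$model == 1, ]
    common <- intersect(num$eu, den$eu)
    if (!length(common)) next
    nv <- num$value[match(common, num$eu)]
    dv <- den$value[match(common, den$eu)]
    ok <- dv != 0
    if (any(!ok)) warning("zero baseline value: target(s) skipped for ", g)
    if (!any(ok)) next
    res[[g]] <- data.frame(group = g, mean_ratio = mean(nv[ok] / dv[ok]),
                           n = sum(ok), stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("no group has overlapping model-6/baseline targets")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-group score change between two phases
#'
#' For targets shared between two phases, the per-target delta is
#' `metric(next) - metric(prev)` using the chosen model mode, averaged
#' per group. Groups without shared targets are omitted with a warning.
#'
#' @param t_prev,t_next Long score tables for the two phases.
#' @param model_mode `"first"` or `"best"` (best by raw metric value).
#' @param metric Metric name.
#' @return Data frame: `group`, `mean_delta`, `n`.
#' @export
cross_phase_delta <- function(t_prev, t_next, model_mode = c("first", "best"),
                              metric = "gdt_ha") {
  model_mode <- match.arg(model_mode)
  pick <- function(t) {
    t <- t[t$metric == metric & t$model <= 5 & !is.na(t$value), ]
    key <- paste(t$group, t$eu, sep = "\r")
    if (model_mode == "first") {
      ord <- order(key, t$model)
    } else {
      ord <- order(key, -t$value, t$model)
    }
    t <- t[ord, ]
    t[!duplicated(paste(t$group, t$eu, sep = "\r")), ]
  }
  a <- pick(validate_score_table(t_prev))
  b <- pick(validate_score_table(t_next))
  res <- list()
  dropped <- character(0)
  for (g in union(unique(a$group), unique(b$group))) {
    ga <- a[a$group == g, ]; gb <- b[b$group == g, ]
    common <- intersect(ga$eu, gb$eu)
    if (!length(common)) { dropped <- c(dropped, g); next }
    delta <- gb$value[match(common, gb$eu)] - ga$value[match(common, ga$eu)]
    res[[g]] <- data.frame(group = g, mean_delta = mean(delta),
                           n = length(common), stringsAsFactors = FALSE)
  }
  if (length(dropped))
    warning("group(s) without shared targets omitted: ",
            paste(dropped, collapse = ", "))
  if (!length(res)) stop("no group shares targets between the two phases")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Best-of-pool comparison
#'
#' Per target, compares the maximum score found in a large model pool
#' (e.g. mass-sampled models) against submitted reference values (best
#' submitted model, first model, named baselines, ...). Targets with an
#' empty pool are excluded with a warning. Output rows are ordered by
#' descending best submitted value (first column of `submitted`).
#'
#' @param pool_scores Named list: target -> numeric vector of pool scores.
#' @param submitted Data frame with a `target` column plus one column per
#'   submitted-set value.
#' @return Data frame: `target`, `pool_max`, then the submitted columns.
#' @export
best_of_pool <- function(pool_scores, submitted) {
  stopifnot("target" %in% names(submitted))
  empty <- names(pool_scores)[!vapply(pool_scores, length, 1L)]
  if (length(empty))
    warning("target(s) with empty pool excluded: ",
            paste(empty, collapse = ", "))
  targets <- intersect(submitted$target,
                       setdiff(names(pool_scores), empty))
  if (!length(targets)) stop("no target with both pool and submitted scores")
  pool_max <- vapply(pool_scores[targets], max, 0)
  out <- cbind(data.frame(target = targets, pool_max = pool_max,
                          stringsAsFactors = FALSE),
               submitted[match(targets, submitted$target),
                         setdiff(names(submitted), "target"), drop = FALSE])
  first_sub <- setdiff(names(submitted), "target")[1]
  out <- out[order(-out[[first_sub]]), ]
  rownames(out) <- NULL
  out
}
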