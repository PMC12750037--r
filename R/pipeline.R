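# Full-assessment orchestration: score every model against its target
# EUs, merge externally computed metrics, rank, and run the head-to-head
# bootstrap. File layout convention:
#   targets_dir/<target_id>.pdb           (+ <version_id>.pdb for
#                                          alternative conformations)
#   models_dir/<target_id>.<group>.<model>.pdb
# Outputs are plain TSV plus a JSON manifest; identical inputs and seed
# give byte-identical outputs.

#' Assemble a run configuration
#'
#' @param targets_dir,models_dir Directories of PDB files (see layout
#'   convention in the package source / vignette).
#' @param eu_file JSON file of EU definitions ([read_eu_definitions()]).
#' @param external_scores Optional TSV of externally computed metrics
#'   (columns group, target, eu, phase, model, metric, value), e.g.
#'   MolProbity, CAD_AA, SphGr, reLLG_const.
#' @param scheme Weight scheme data frame.
#' @param floor z floor (-2 or 0).
#' @param mode Ranking model mode, `"best"` or `"first"`.
#' @param n_boot Bootstrap replicates for head-to-head.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param strict If `TRUE`, refuse to run unless every scheme metric is
#'   available (fidelity mode); otherwise the scheme is renormalized to
#'   the available metrics with a warning.
#' @return List of class `run_config`.
#' @export
run_config <- function(targets_dir, models_dir, eu_file,
                       external_scores = NULL,
                       scheme = default_weight_scheme(), floor = -2,
                       mode = "best", n_boot = 200, seed = 1,
                       out_dir = tempfile("assessment"), strict = FALSE) {
  for (p in c(targets_dir, models_dir, eu_file))
    if (!file.exists(p)) stop("path does not exist: ", p)
  if (!is.null(external_scores) && !file.exists(external_scores))
    stop("external score table does not exist: ", external_scores)
  structure(list(targets_dir = targets_dir, models_dir = models_dir,
                 eu_file = eu_file, external_scores = external_scores,
                 scheme = validate_weight_scheme(scheme), floor = floor,
                 mode = mode, n_boot = n_boot, seed = seed,
                 out_dir = out_dir, strict = strict),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full assessment
#'
#' Scores every model/target pair per EU with the internal metrics,
#' merges external metric columns by (group, eu, model), builds best- and
#' first-model rankings with the two-round z protocol, and runs the
#' head-to-head bootstrap. Writes `scores.tsv`, `ranking_best.tsv`,
#' `ranking_first.tsv`, `h2h.tsv` and `manifest.json` to the output
#' directory.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with the score table, both rankings, the
#'   head-to-head matrix and the output paths.
#' @export
run_assessment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  eus <- read_eu_definitions(cfg$eu_file)
  if (!length(eus)) stop("zero EU definitions: nothing to assess")
  target_ids <- unique(vapply(eus, `[[`, "", "target_id"))
  model_files <- sort(list.files(cfg$models_dir, pattern = "\\.pdb$",
                                 full.names = TRUE))
  parse_model_name <- function(f) {
    parts <- strsplit(sub("\\.pdb$", "", basename(f)), ".", fixed = TRUE)[[1]]
    if (length(parts) != 3) return(NULL)
    list(target = parts[1], group = parts[2], model = as.integer(parts[3]))
  }
  targets <- list()
  for (tid in target_ids) {
    f <- file.path(cfg$targets_dir, paste0(tid, ".pdb"))
    if (!file.exists(f)) stop("target file missing: ", f)
    targets[[tid]] <- parse_structure(file = f, id = tid)
  }
  if (!length(targets)) stop("zero targets")
  rows <- list()
  skipped <- character(0)
  for (f in model_files) {
    info <- parse_model_name(f)
    if (is.null(info) || !(info$target %in% target_ids)) {
      skipped <- c(skipped, basename(f))
      next
    }
    model <- parse_structure(file = f, id = basename(f))
    for (eu in eus) {
      if (eu$target_id != info$target) next
      versions <- list(extract_eu(targets[[info$target]], eu))
      for (vid in eu$versions) {
        vf <- file.path(cfg$targets_dir, paste0(vid, ".pdb"))
        if (file.exists(vf))
          versions <- c(versions,
                        list(extract_eu(parse_structure(file = vf, id = vid),
                                        eu)))
      }
      eu_model <- try(extract_eu(model, eu), silent = TRUE)
      if (inherits(eu_model, "try-error")) {
        skipped <- c(skipped, paste(basename(f), eu$eu_id))
        next
      }
      vals <- compute_metrics(versions, eu_model)
      rows[[length(rows) + 1L]] <- data.frame(
        group = info$group, target = info$target, eu = eu$eu_id,
        phase = 1L, model = info$model, metric = names(vals),
        value = as.numeric(vals), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no model could be scored")
  scores <- do.call(rbind, rows)
  if (length(skipped))
    warning("skipped inputs: ", paste(skipped, collapse = "; "))
  if (!is.null(cfg$external_scores)) {
    ext <- utils::read.delim(cfg$external_scores, stringsAsFactors = FALSE)
    known <- paste(scores$group, scores$eu, scores$model)
    orphan <- !(paste(ext$group, ext$eu, ext$model) %in% known)
    if (any(orphan))
      warning("external rows not matching any scored model: ",
              sum(orphan))
    scores <- rbind(scores, ext[!orphan, names(scores)])
  }
  scores <- scores[!is.na(scores$value), ]
  scores <- scores[order(scores$group, scores$eu, scores$model,
                         scores$metric), ]
  rownames(scores) <- NULL
  available <- unique(scores$metric)
  scheme <- cfg$scheme
  if (!all(scheme$metric %in% available)) {
    if (cfg$strict)
      stop("strict mode: scheme metric(s) unavailable: ",
           paste(setdiff(scheme$metric, available), collapse = ", "))
    scheme <- renormalize_weights(scheme, available)
  }
  eu_tab <- data.frame(eu = vapply(eus, `[[`, "", "eu_id"),
                       weight = vapply(eus, `[[`, 0, "weight"),
                       stringsAsFactors = FALSE)
  imputed <- impute_unscored(scores, scheme)
  rank_best <- aggregate_ranking(imputed, eu_tab, scheme, mode = "best",
                                 floor = cfg$floor)
  rank_first <- aggregate_ranking(imputed, eu_tab, scheme, mode = "first",
                                  floor = cfg$floor)
  comp <- eu_composites(imputed, eu_tab, scheme, mode = cfg$mode,
                        floor = cfg$floor)
  h2h <- head_to_head_matrix(comp, n_boot = cfg$n_boot, seed = cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$out_dir,
                     c("scores.tsv", "ranking_best.tsv", "ranking_first.tsv",
                       "h2h.tsv", "manifest.json"))
  names(paths) <- c("scores", "ranking_best", "ranking_first", "h2h",
                    "manifest")
  write_tsv(scores, paths["scores"])
  write_tsv(as.data.frame(rank_best), paths["ranking_best"])
  write_tsv(as.data.frame(rank_first), paths["ranking_first"])
  h2h_df <- data.frame(group = rownames(h2h$win_fraction),
                       round(h2h$win_fraction, 6))
  write_tsv(h2h_df, paths["h2h"])
  manifest <- list(seed = cfg$seed, mode = cfg$mode, floor = cfg$floor,
                   n_boot = cfg$n_boot,
                   metrics_used = scheme$metric,
                   weights = scheme$weight,
                   n_targets = length(targets),
                   n_models = length(model_files),
                   n_score_rows = nrow(scores),
                   skipped = skipped)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(scores = scores, ranking_best = rank_best,
                 ranking_first = rank_first, h2h = h2h, paths = paths))
}
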