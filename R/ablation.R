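#' Run an ablation grid over architectures, preprocessing and augmentation
#'
#' Trains and evaluates one model per combination of the supplied choices
#' on a fixed dataset split, mirroring a staged architecture /
#' preprocessing / augmentation comparison. Completed combinations are
#' cached as JSON files in `out_dir` (keyed by a hash of the combination
#' plus seeds) and skipped on re-run, so an interrupted grid resumes
#' without retraining. A failed run is recorded as an `NA` row and the
#' grid continues.
#'
#' @param ds A labeled [colony_dataset()].
#' @param architectures Character vector of registry names.
#' @param preprocess_methods Character vector of [preprocess_spec()]
#'   methods.
#' @param augment_options Named list of [augment_spec()] objects (names
#'   become the `augment` column), e.g. `list(none = augment_spec())`.
#' @param train_cfg A [train_config()]; also provides the split seed.
#' @param input_side Network input side (and preprocess target side).
#' @param width_factor Channel width multiplier.
#' @param out_dir Optional directory for the resume registry.
#' @return An object of class `ablation_results`: a data.frame with one
#'   row per combination (architecture, preprocess, augment, accuracy,
#'   precision, recall, f1, auc, failed) carrying the run configuration as
#'   attributes.
#' @export
run_ablation <- function(ds, architectures = names(arch_registry()),
                         preprocess_methods = "none",
                         augment_options = list(none = augment_spec()),
                         train_cfg = train_config(), input_side = 64L,
                         width_factor = 1 / 8, out_dir = NULL) {
  stopifnot(inherits(ds, "colony_dataset"))
  if (!length(architectures) || !length(preprocess_methods) ||
      !length(augment_options))
    stop("ablation grid must be nonempty", call. = FALSE)
  if (is.null(names(augment_options)))
    names(augment_options) <- paste0("augment", seq_along(augment_options))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- split_dataset(ds, train_cfg$split_ratio, seed = train_cfg$seed)
  grid <- expand.grid(architecture = architectures,
                      preprocess = preprocess_methods,
                      augment = names(augment_options),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    key <- sprintf("%s_%s_%s_s%d_w%.4f_i%d", g$architecture, g$preprocess,
                   g$augment, train_cfg$seed, width_factor, input_side)
    key <- gsub("[^A-Za-z0-9_.-]", "-", key)
    cache_file <- if (!is.null(out_dir))
      file.path(out_dir, paste0(key, ".json")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rec <- jsonlite::read_json(cache_file, simplifyVector = TRUE)
    } else {
      rec <- tryCatch({
        pp <- preprocess_spec(g$preprocess, target_side_px = input_side)
        mdl <- build_model(g$architecture, input_side = input_side,
                           seed = train_cfg$seed,
                           width_factor = width_factor)
        tr <- fit(mdl, sp$train, sp$validation, train_cfg,
                  preprocess = pp, augment = augment_options[[g$augment]])
        ev <- evaluate_model(tr$model, sp$validation, preprocess = pp)
        list(accuracy = ev$accuracy, precision = ev$precision,
             recall = ev$recall, f1 = ev$f1, auc = ev$auc, failed = FALSE)
      }, error = function(e) {
        warning(sprintf("combination %s failed: %s", key,
                        conditionMessage(e)))
        list(accuracy = NA_real_, precision = NA_real_, recall = NA_real_,
             f1 = NA_real_, auc = NA_real_, failed = TRUE)
      })
      if (!is.null(cache_file))
        jsonlite::write_json(rec, cache_file, auto_unbox = TRUE,
                             digits = NA)
    }
    rows[[i]] <- cbind(g, as.data.frame(rec))
  }
  out <- do.call(rbind, rows)
  attr(out, "train_cfg") <- train_cfg
  attr(out, "input_side") <- input_side
  attr(out, "width_factor") <- width_factor
  class(out) <- c("ablation_results", "data.frame")
  out
}

#' Write ablation results as CSV, JSON and a rendered text summary
#'
#' The summary marks the per-measure maximum in each column with an
#' asterisk (the text equivalent of boldface); failed rows render as
#' "failed".
#'
#' @param results An [run_ablation()] results table.
#' @param dir Output directory.
#' @return Invisibly, a named list of the three file paths.
#' @export
report_results <- function(results, dir) {
  stopifnot(inherits(results, "ablation_results"), nrow(results) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "ablation.csv")
  jsn <- file.path(dir, "ablation.json")
  txt <- file.path(dir, "ablation.txt")
  df <- as.data.frame(results)
  write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, jsn, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  measures <- c("accuracy", "precision", "recall", "f1", "auc")
  lines <- c(sprintf("%-20s %-10s %-12s %s", "architecture", "preprocess",
                     "augment", paste(sprintf("%9s", measures),
                                      collapse = " ")))
  best <- vapply(measures, function(m)
    if (all(is.na(df[[m]]))) -Inf else max(df[[m]], na.rm = TRUE),
    numeric(1))
  for (i in seq_len(nrow(df))) {
    vals <- vapply(measures, function(m) {
      v <- df[[m]][i]
      if (is.na(v)) return(sprintf("%9s", "failed"))
      sprintf("%8.4f%s", v, if (isTRUE(all.equal(v, best[[m]]))) "*" else " ")
    }, character(1))
    lines <- c(lines, sprintf("%-20s %-10s %-12s %s", df$architecture[i],
                              df$preprocess[i], df$augment[i],
                              paste(vals, collapse = " ")))
  }
  writeLines(lines, txt)
  invisible(list(csv = csv, json = jsn, txt = txt))
}

#' Read a YAML run configuration
#'
#' Maps a YAML file onto the package's specification objects. Recognized
#' top-level keys: `dataset` (either `manifest: path` or `synth:` with
#' `n_good`, `n_bad`, `seed` and [generator_params()] fields),
#' `preprocess` ([preprocess_spec()] fields), `augment` ([augment_spec()]
#' fields), `model` (`name`, `input_side`, `width_factor`, `seed`) and
#' `train` ([train_config()] fields).
#'
#' @param path YAML file path.
#' @return A named list of constructed specification objects plus the raw
#'   configuration under `$raw`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(raw = cfg)
  pp <- cfg$preprocess %||% list()
  out$preprocess <- do.call(preprocess_spec, pp)
  ag <- cfg$augment %||% list()
  out$augment <- do.call(augment_spec, ag)
  tr <- cfg$train %||% list()
  if (!is.null(tr$split_ratio)) tr$split_ratio <- as.numeric(tr$split_ratio)
  out$train <- do.call(train_config, tr)
  out$model <- modifyList(list(name = "VGG13", input_side = 256L,
                               width_factor = 1, seed = 0L),
                          cfg$model %||% list())
  ds <- cfg$dataset %||% list()
  if (!is.null(ds$manifest)) {
    out$dataset_source <- list(type = "manifest", manifest = ds$manifest)
  } else if (!is.null(ds$synth)) {
    sy <- ds$synth
    gp_fields <- intersect(names(sy), names(formals(generator_params)))
    out$dataset_source <- list(
      type = "synth",
      n_good = sy$n_good %||% 50L, n_bad = sy$n_bad %||% 50L,
      seed = sy$seed %||% 1L,
      params = do.call(generator_params, sy[gp_fields]))
  } else {
    out$dataset_source <- NULL
  }
  out
}

#' Materialize the dataset described by a run configuration
#'
#' @param config A [read_run_config()] result.
#' @return A [colony_dataset()].
#' @export
load_config_dataset <- function(config) {
  src <- config$dataset_source
  if (is.null(src)) stop("run configuration has no dataset source",
                         call. = FALSE)
  if (src$type == "manifest") read_manifest(src$manifest)
  else generate_dataset(src$n_good, src$n_bad, src$params, src$seed)
}
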