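#' Axial slice positions of the stented region
#'
#' Half-open sampling of the stented region of a vessel of length
#' `vessel_length`, excluding `margin` at each end, at `spacing` steps:
#' positions `margin, margin + spacing, ...` strictly below
#' `vessel_length - margin`. The reference geometry (26 mm vessel, 7 mm
#' margins, 0.1 mm spacing) yields exactly 120 slices.
#'
#' @param vessel_length,margin,spacing mm.
#' @return Numeric vector of axial positions, mm.
#' @export
axial_positions <- function(vessel_length = 26, margin = 7, spacing = 0.1) {
  stopifnot(vessel_length > 2 * margin, spacing > 0)
  n <- ceiling((vessel_length - 2 * margin) / spacing - 1e-9)
  margin + spacing * (seq_len(n) - 1)
}

#' Target lumen area and underexpansion threshold
#'
#' Circular lumen area at a given stent diameter (7.06 mm^2 at the 3 mm
#' nominal size) and the conventional underexpansion threshold (80% of the
#' target area, 5.65 mm^2).
#'
#' @param diameter stent diameter, mm.
#' @param fraction underexpansion fraction of the target area.
#' @return Area in mm^2.
#' @export
target_lumen_area <- function(diameter = 3.0) {
  stopifnot(diameter > 0)
  pi * (diameter / 2)^2
}

#' @rdname target_lumen_area
#' @export
underexpansion_threshold <- function(diameter = 3.0, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  fraction * target_lumen_area(diameter)
}

#' Pipeline configuration
#'
#' Bundles the generator configuration, stent parameters and the
#' experiment grid of the end-to-end run.
#'
#' @param vessel_gen a [vessel_gen_config()].
#' @param stent a [stent_params()].
#' @param models named list of [model_spec()]s; the default grid is the
#'   four reference models `lr`, `svr_l`, `svr_p`, `svr_rbf`.
#' @param feature_groups subset of `c("all", "stretch", "calcification")`.
#' @param split `"segment"` (leading slices train) or `"random"`.
#' @param n_train training rows.
#' @param neighbor_average also run the experiment with features averaged
#'   over eight neighboring slices.
#' @param seed global seed; the generator seed is derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(vessel_gen = NULL,
                            stent = NULL,
                            models = default_model_grid(),
                            feature_groups = c("all", "stretch", "calcification"),
                            split = c("segment", "random"),
                            n_train = 90,
                            neighbor_average = TRUE,
                            seed = 1L) {
  split <- match.arg(split)
  seed <- as.integer(seed)
  if (is.null(vessel_gen)) vessel_gen <- vessel_gen_config(seed = seed)
  if (is.null(stent)) stent <- stent_params()
  stopifnot(length(models) >= 1, length(feature_groups) >= 1,
            all(feature_groups %in% c("all", "stretch", "calcification")))
  structure(list(vessel_gen = vessel_gen, stent = stent, models = models,
                 feature_groups = feature_groups, split = split,
                 n_train = n_train, neighbor_average = neighbor_average,
                 seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_model_grid <- function() {
  list(lr = model_spec("LR"),
       svr_l = model_spec("SVR", "linear"),
       svr_p = model_spec("SVR", "polynomial"),
       svr_rbf = model_spec("SVR", "rbf"))
}

fit_model <- function(spec, train) {
  if (spec$family == "LR") fit_lr(train) else fit_svr(train, spec)
}

#' Run the end-to-end pipeline
#'
#' Generates a synthetic vessel, expands every slice with the
#' composite-ring surrogate to obtain post-stenting lumen-area labels,
#' extracts the eight pre-stenting features, splits into train/test,
#' fits every model of the grid on every feature group (with and, when
#' requested, without neighbor-averaged features), and reports per-slice
#' percentage errors with group statistics. Fully reproducible from
#' (configuration, seed).
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, the feature table,
#'   per-slice expansion results, a tidy error table and a JSON summary
#'   are written there.
#' @return Object of class `pipeline_result`: list with `features`
#'   (data frame), `expansion` (data frame), `reports` (nested list:
#'   averaging condition / feature group / model), `summary` (tidy data
#'   frame of bias/range per grid cell) and `model_comparison` (ANOVA
#'   across the four models on all features, individual slices).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  vessel <- generate_vessel(cfg$vessel_gen)
  results <- expand_vessel(vessel, cfg$stent)
  features <- extract_features_vessel(vessel)
  y <- vapply(results, function(r) r$post_lumen_area, numeric(1))

  conditions <- list(individual = features)
  if (isTRUE(cfg$neighbor_average))
    conditions$averaged <- neighbor_average(features)

  reports <- list()
  summary_rows <- list()
  for (cond in names(conditions)) {
    data <- make_dataset(conditions[[cond]], y)
    sp <- if (cfg$split == "segment") segment_split(data, cfg$n_train)
          else random_split(data, cfg$n_train, seed = cfg$seed)
    reports[[cond]] <- list()
    for (grp in cfg$feature_groups) {
      tr <- subgroup(sp$train, grp)
      te <- subgroup(sp$test, grp)
      reports[[cond]][[grp]] <- list()
      for (mn in names(cfg$models)) {
        model <- fit_model(cfg$models[[mn]], tr)
        rep <- evaluate_model(model, te,
                              label = paste(cond, grp, mn, sep = "/"))
        reports[[cond]][[grp]][[mn]] <- rep
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          condition = cond, features = grp, model = mn,
          bias = rep$bias, err_min = rep$error_range[1],
          err_max = rep$error_range[2], max_area_diff = rep$max_area_diff,
          n_test = rep$n_test)
      }
    }
  }
  summary_df <- do.call(rbind, summary_rows)

  model_comparison <- if ("all" %in% cfg$feature_groups &&
                          length(cfg$models) >= 2)
    compare_groups(reports$individual[["all"]]) else NULL

  out <- structure(list(features = features,
                        expansion = expansion_results_df(
                          results, z = features$z),
                        labels = y,
                        reports = reports, summary = summary_df,
                        model_comparison = model_comparison,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d slices; %d grid cells\n",
              nrow(x$features), nrow(x$summary)))
  print(x$summary, digits = 3)
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(result$expansion, post_area_label = result$labels),
                   file.path(out_dir, "expansion.csv"), row.names = FALSE)
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  errors <- do.call(rbind, lapply(names(result$reports), function(cond)
    do.call(rbind, lapply(names(result$reports[[cond]]), function(grp)
      do.call(rbind, lapply(names(result$reports[[cond]][[grp]]), function(mn) {
        r <- result$reports[[cond]][[grp]][[mn]]
        data.frame(condition = cond, features = grp, model = mn,
                   slice_index = r$slice_index, pct_error = r$per_slice_pct_error)
      }))))))
  utils::write.csv(errors, file.path(out_dir, "errors.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$summary,
         model_comparison = result$model_comparison$anova),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(seed = result$config$seed,
                   generator_seed = result$config$vessel_gen$seed,
                   n_sections = result$config$vessel_gen$n_sections,
                   split = result$config$split,
                   n_train = result$config$n_train,
                   models = names(result$config$models),
                   feature_groups = result$config$feature_groups)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Build a deterministic test fixture
#'
#' Miniature (12-slice) or full-size (120-slice) synthetic vessel plus
#' its post-stenting lumen-area labels.
#'
#' @param size `"small"` (12 slices) or `"default"` (120 slices).
#' @param seed integer seed.
#' @return List with `vessel` (list of cross sections), `features`
#'   (data frame) and `labels` (numeric vector of post-stenting areas).
#' @export
make_fixture <- function(size = c("small", "default"), seed = 1L) {
  size <- match.arg(size)
  n <- if (size == "small") 12L else 120L
  cfg <- vessel_gen_config(n_sections = n, seed = seed)
  vessel <- generate_vessel(cfg)
  results <- expand_vessel(vessel)
  list(vessel = vessel,
       features = extract_features_vessel(vessel),
       labels = vapply(results, function(r) r$post_lumen_area, numeric(1)))
}
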