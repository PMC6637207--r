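#' @name runners
#' @title End-to-end pipeline runners
#' @description
#' Thin orchestration over the package's modules, mirroring the stages
#' of the workflow: `run_simulate` writes a synthetic dataset with ground
#' truth; `run_smat` turns TIFF stacks into normalized decay curves and
#' per-timepoint comparisons; `run_fit` estimates kinetic parameters from
#' the curves; `run_hcia` performs the dual-stain single-cell analysis.
#' All outputs are CSVs with metadata headers; re-running with the same
#' seed reproduces them byte for byte. A command-line front end wrapping
#' these functions ships in `inst/scripts/smat.R`.
NULL

#' Generate a synthetic dataset on disk
#'
#' @param preset Preset name (see [scenario_preset()]) or an
#'   `smat_scenario`.
#' @param out Output directory.
#' @param seed Scenario seed (ignored when `preset` is a scenario).
#' @param ... Scenario overrides passed to [scenario_preset()].
#' @return Invisibly, the scenario used.
#' @export
run_simulate <- function(preset, out, seed = 1, ...) {
  scn <- if (inherits(preset, "smat_scenario")) preset
         else scenario_preset(preset, seed = seed, ...)
  generate_timelapse_stack(scn, out)
  traces <- generate_traces(scn)
  write_csv_meta(traces, file.path(out, "traces.csv"), seed = scn$seed,
                 extra = list(stage = "simulate", mode = scn$mode))
  invisible(scn)
}

#' Quantify decay curves from a time-lapse dataset
#'
#' @param manifest_path Path to the dataset's `manifest.csv`.
#' @param out Output directory for `curves.csv` and `comparisons.csv`.
#' @param reference Reference condition for the per-timepoint
#'   comparisons (default: first condition in the manifest).
#' @param background Background handling, see [read_stack_traces()].
#' @param switch_time Optional media-switch time; when given, the
#'   comparisons are computed on the post-switch window re-referenced to
#'   the switch frame (a `comparisons_preswitch.csv` is also written).
#' @param seed Seed recorded in output metadata (the stage itself is
#'   deterministic).
#' @return Invisibly, list with `traces`, `curves`, `comparison`.
#' @export
run_smat <- function(manifest_path, out, reference = NULL,
                     background = "none", switch_time = NULL, seed = NA) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  traces <- read_stack_traces(manifest_path, background = background)
  norm <- normalize_traces(traces)
  curves <- do.call(rbind, lapply(split(norm, norm$condition),
                                  aggregate_condition))
  rownames(curves) <- NULL
  if (is.null(reference)) reference <- as.character(norm$condition[1])
  meta <- list(stage = "smat", reference = reference, background = background)
  if (is.null(switch_time)) {
    cmp <- compare_conditions(norm, reference)
    write_csv_meta(cmp$table, file.path(out, "comparisons.csv"), seed, meta)
  } else {
    sw <- segment_switch_analysis(norm, switch_time, reference)
    cmp <- sw$post
    write_csv_meta(cmp$table, file.path(out, "comparisons.csv"), seed,
                   c(meta, list(window = "post-switch",
                                switch_time = switch_time)))
    if (!is.null(sw$pre))
      write_csv_meta(sw$pre$table, file.path(out, "comparisons_preswitch.csv"),
                     seed, c(meta, list(window = "pre-switch",
                                        switch_time = switch_time)))
  }
  write_csv_meta(curves, file.path(out, "curves.csv"), seed, meta)
  invisible(list(traces = norm, curves = curves, comparison = cmp))
}

#' Fit kinetic parameters to per-condition decay curves
#'
#' Fits the dissociation model to each condition's mean curve and writes
#' a parameter table including the `kr/kf_d` dissociation ratio. When an
#' association curve table is also supplied, `L_T` is estimated
#' sequentially with the dissociation-fitted rates held fixed.
#'
#' @param curves Curves data frame (`condition`, `time_min`, `mean`) or
#'   path to a `curves.csv`.
#' @param out Output directory for `fits.csv`.
#' @param association_curves Optional association-mode curves (same
#'   format) for the sequential `L_T` step.
#' @param seed Seed recorded in output metadata.
#' @return Invisibly, the fit table.
#' @export
run_fit <- function(curves, out, association_curves = NULL, seed = NA) {
  if (is.character(curves)) curves <- read_csv_meta(curves)
  if (is.character(association_curves))
    association_curves <- read_csv_meta(association_curves)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cn in unique(as.character(curves$condition))) {
    cc <- curves[curves$condition == cn, ]
    cc <- cc[order(cc$time_min), ]
    traj <- bound_probe_trajectory(cc$time_min, pmax(cc$mean, 0),
                                   "dissociation")
    fit <- fit_dissociation(traj)
    lt <- NA_real_
    if (!is.null(association_curves) &&
        cn %in% association_curves$condition) {
      ac <- association_curves[association_curves$condition == cn, ]
      ac <- ac[order(ac$time_min), ]
      at <- bound_probe_trajectory(ac$time_min, pmax(ac$mean, 0),
                                   "association")
      afit <- fit_association(at, fit$params, c_init = ac$mean[1])
      if (afit$identifiable) lt <- afit$params$L_T
    }
    p <- fit$params
    rows[[length(rows) + 1]] <- data.frame(
      condition = cn, kf_d = p$kf_d, kr = p$kr, L_T = lt,
      kr_over_kf_d = if (p$kf_d > 0) p$kr / p$kf_d else NA_real_,
      sse = fit$residual_sse, converged = fit$converged)
  }
  fits <- do.call(rbind, rows)
  rownames(fits) <- NULL
  write_csv_meta(fits, file.path(out, "fits.csv"), seed,
                 list(stage = "fit", model = "ligand-receptor"))
  invisible(fits)
}

#' Dual-stain high-content analysis of a generated cell population
#'
#' Segments every field, extracts the 41-feature descriptor table, and
#' runs both the simultaneous (all conditions) and the binary
#' (condition vs basal) canonical discriminant analyses, Wilks' lambda,
#' 50% canonical contour ellipses, and bootstrap-forest predictor
#' ranking. Conditions in which no cell survives segmentation are
#' dropped with a warning.
#'
#' @param population Output of [generate_dual_stain_population()], or a
#'   list of `list(condition, img)` fields.
#' @param basal Name of the basal reference condition (default: first).
#' @param n_boot Trees for the predictor ranking.
#' @param seed Seed for the ranking and cross-validation folds.
#' @return An `hcia_result`: `features`, `model`, `report` (4-way),
#'   `binary` (per-condition vs basal reports), `wilks`, `contours`,
#'   `ranking`.
#' @export
hcia_analyze <- function(population, basal = NULL, n_boot = 200, seed = 1) {
  fields <- if (!is.null(population$images)) population$images else population
  feats <- list()
  for (fl in fields) {
    seg <- segment_cells(fl$img)
    if (seg$n_cells == 0) next
    feats[[length(feats) + 1]] <-
      extract_all_features(fl$img, seg, condition = fl$condition)
  }
  features <- do.call(rbind, feats)
  if (is.null(features) || nrow(features) == 0)
    stop("no cells segmented in any field")
  counts <- table(features$condition)
  dropped <- names(counts)[counts < 2]
  if (length(dropped)) {
    warning("conditions dropped (fewer than 2 segmented cells): ",
            paste(dropped, collapse = ", "))
    features <- features[!features$condition %in% dropped, ]
  }
  X <- as.matrix(features[, feature_names()])
  y <- factor(features$condition)
  if (is.null(basal)) basal <- levels(y)[1]

  # The 41-descriptor panel carries two exact linear identities (for a
  # symmetric co-occurrence matrix, sum_variance + contrast = 4 variance,
  # once per channel), so the multivariate analyses run on the pivoted
  # full-rank column subset; the feature table itself keeps all 41.
  Zs <- scale(X)
  Zs[, attr(Zs, "scaled:scale") == 0] <- 0
  qz <- qr(Zs)
  used <- sort(qz$pivot[seq_len(qz$rank)])
  Xr <- X[, used, drop = FALSE]

  model <- fit_lda(Xr, y)
  report <- classify(model, Xr, y)
  scores <- canonical_scores(model, Xr)
  contours <- lapply(stats::setNames(nm = levels(y)), function(g)
    tryCatch(canonical_contour(model, scores, y, g), error = function(e) NULL))

  binary <- list()
  for (g in setdiff(levels(y), basal)) {
    sel <- y %in% c(basal, g)
    m2 <- fit_lda(Xr[sel, , drop = FALSE], droplevels(y[sel]))
    binary[[g]] <- classify(m2, Xr[sel, , drop = FALSE], droplevels(y[sel]))
  }

  wl <- if (nrow(Xr) - nlevels(y) > ncol(Xr)) wilks_test(Xr, y) else {
    warning("too few cells for the full-feature Wilks test; ",
            "using the canonical scores instead")
    wilks_test(scores, y)
  }
  ranking <- rank_predictors(X, y, n_boot = n_boot, seed = seed)
  structure(list(features = features, model = model, report = report,
                 binary = binary, wilks = wl, contours = contours,
                 ranking = ranking, basal = basal,
                 features_used = colnames(Xr)),
            class = "hcia_result")
}

#' @export
print.hcia_result <- function(x, ...) {
  cat(sprintf("HCIA: %d cells, %d conditions; %.1f%% correctly classified\n",
              nrow(x$features), nlevels(factor(x$features$condition)),
              x$report$percent_correct))
  print(x$wilks)
  invisible(x)
}

#' Run the dual-stain analysis across a divergence schedule
#'
#' Generates the dual-stain population at every timepoint of the
#' scenario's divergence schedule and runs [hcia_analyze()] on each,
#' writing per-timepoint feature, classification, confusion, ellipse and
#' ranking CSVs.
#'
#' @param scn An `smat_scenario`.
#' @param out Output directory.
#' @param n_fields Fields per condition and timepoint.
#' @param n_boot,seed Passed to [hcia_analyze()].
#' @return Invisibly, a named list of `hcia_result` per timepoint.
#' @export
run_hcia <- function(scn, out, n_fields = 2, n_boot = 200, seed = 1) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary_rows <- list()
  for (tp in names(scn$divergence_schedule)) {
    pop <- generate_dual_stain_population(scn, as.numeric(tp),
                                          n_fields = n_fields)
    res <- hcia_analyze(pop, n_boot = n_boot, seed = seed)
    results[[tp]] <- res
    meta <- list(stage = "hcia", timepoint_min = tp,
                 feature_set = attr(feature_names(), "version"))
    write_csv_meta(res$features, file.path(out, paste0("features_t", tp, ".csv")),
                   seed, meta)
    write_csv_meta(as.data.frame(res$report$confusion),
                   file.path(out, paste0("confusion_t", tp, ".csv")), seed, meta)
    write_csv_meta(res$ranking, file.path(out, paste0("ranking_t", tp, ".csv")),
                   seed, meta)
    ell <- do.call(rbind, lapply(names(res$contours), function(g) {
      ct <- res$contours[[g]]
      if (is.null(ct)) return(NULL)
      data.frame(condition = g, center1 = ct$center[1], center2 = ct$center[2],
                 radius_major = ct$radii[1], radius_minor = ct$radii[2],
                 angle = ct$angle, coverage = ct$coverage)
    }))
    if (!is.null(ell))
      write_csv_meta(ell, file.path(out, paste0("ellipses_t", tp, ".csv")),
                     seed, meta)
    summary_rows[[tp]] <- data.frame(
      timepoint_min = as.numeric(tp), n_cells = nrow(res$features),
      percent_correct_all = res$report$percent_correct,
      wilks_lambda = res$wilks$lambda, wilks_p_F = res$wilks$p_F)
  }
  write_csv_meta(do.call(rbind, summary_rows),
                 file.path(out, "hcia_summary.csv"), seed,
                 list(stage = "hcia"))
  invisible(results)
}
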