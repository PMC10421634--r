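#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis in one place.
#' Defaults are the standard posture-mapping settings: 10-frame gap
#' interpolation, K = 100 mutual nearest neighbors with a 15th-order median
#' filter, PCA to 95% variance, embedding with `min_dist = 0.001` and
#' `n_neighbors = 20`, a 200 x 200 density grid, dendrogram cuts over
#' 0.4-1.4, and 100-permutation nulls. The full config is serialized into
#' the run manifest.
#'
#' @param ... overrides of any default parameter.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    cage_bounds = default_cage_bounds(),
    min_mean_limb = 0.10,
    max_gap_frames = 10,
    align = TRUE,
    K = 100,
    filter_order = 15,
    mnn_weighting = "kernel",
    var_fraction = 0.95,
    min_dist = 0.001,
    n_neighbors = 20,
    n_epochs = 200,
    grid_n = 200,
    cut_heights = seq(0.4, 1.4, length.out = 51),
    lags = c(1, 2, 3, 5, 7, 10, 15, 20, 30, 50),
    n_permutations = 100,
    fps = 30,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field: %s", unknown[1])
  modifyList(cfg, over)
}

#' Run the full behavioral-decomposition pipeline
#'
#' Orchestrates preprocess, align, embed, cluster, graph and statistics
#' stages over a set of pose sessions and writes all artifacts (per-frame
#' posture labels, transition matrices, Newick dendrograms, module tables,
#' metric curves, statistics report and a manifest with the config and
#' seed) into `out_dir`. Re-running with an identical config and inputs
#' reproduces identical label tables.
#'
#' @param sessions either a tibble with columns `pose_file` (paths read via
#'   [read_pose_table()]) — e.g. the manifest written by [make_demo()] — or
#'   a named list of [pose_sequence()] objects.
#' @param out_dir output directory; created if needed. `NULL` skips
#'   writing.
#' @param config a [run_config()].
#' @param skeleton a [skeleton_model()].
#' @return Invisibly, a list with per-stage results: `features`, `pca`,
#'   `embedding`, `postures` (posture_map), `labels` (tibble), `sessions`
#'   (per-session graphs, dendrograms, modules, nulls, curves, fits),
#'   `stats`, `qc`, `alignment`.
#' @export
run_pipeline <- function(sessions, out_dir = NULL, config = run_config(),
                         skeleton = macaque_skeleton()) {
  t0 <- Sys.time()
  seqs <- load_sessions(sessions, skeleton)
  say <- function(fmt, ...) message(sprintf("[ethokit %s] %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(fmt, ...)))
  say("preprocess: %d sessions", length(seqs))
  prep <- lapply(seqs, preprocess_session, skeleton = skeleton,
                 cage_bounds = config$cage_bounds,
                 min_mean_limb = config$min_mean_limb,
                 max_gap_frames = config$max_gap_frames)
  say("features")
  feats <- lapply(prep, function(p)
    compute_features(p$normalized, p$raw, skeleton))
  fm <- normalize_features(dplyr::bind_rows(feats))
  fm_split <- split(fm, fm$session_id)[unique(fm$session_id)]
  alignment <- NULL
  if (isTRUE(config$align) && length(fm_split) > 1) {
    say("align: MNN to reference, K = %d", config$K)
    mats <- lapply(fm_split, function(x) as.matrix(x[, feature_cols()]))
    al <- align_sessions(mats, K = config$K,
                         filter_order = config$filter_order,
                         weighting = config$mnn_weighting)
    for (nm in names(fm_split))
      fm_split[[nm]][, feature_cols()] <- al$aligned[[nm]]
    fm <- dplyr::bind_rows(fm_split)
    alignment <- al$report
  }
  say("PCA to %.0f%% variance", 100 * config$var_fraction)
  pca <- pca_reduce(fm, var_fraction = config$var_fraction)
  say("embedding %d frames (kept %d PCs)", nrow(fm), pca$n_components)
  emb <- umap_embed(pca, n_neighbors = config$n_neighbors,
                    min_dist = config$min_dist, n_epochs = config$n_epochs,
                    seed = child_seed(config$seed, "embed"))
  say("density + watershed on %d x %d grid", config$grid_n, config$grid_n)
  dens <- density_map(emb, grid_n = config$grid_n)
  pm <- watershed_postures(dens, emb)
  labels <- dplyr::bind_cols(
    fm[, c("frame", "subject_id", "session_id", "task")],
    tibble::tibble(dim1 = emb[, 1], dim2 = emb[, 2], posture = pm$labels))
  say("postures: %d basins", pm$n_postures)
  per_session <- lapply(split(labels, labels$session_id), function(ls) {
    runs <- compress_runs(ls$posture, fps = config$fps)
    g1 <- transition_matrix(runs, lag = 1)
    d1 <- paris_dendrogram(g1)
    bc1 <- suppressWarnings(best_cut(d1, g1, heights = config$cut_heights))
    nd <- shuffle_null(runs, "modularity", n = config$n_permutations,
                       seed = child_seed(config$seed, paste0("null", ls$session_id[1])),
                       heights = config$cut_heights)
    mc <- metric_curve(runs, lags = config$lags, metric = "modularity",
                       heights = config$cut_heights)
    fit <- tryCatch(fit_half_life(mc), error = function(e) NULL)
    list(session = ls$session_id[1], subject = ls$subject_id[1],
         task = ls$task[1], runs = runs, graph = g1, dendrogram = d1,
         modules = bc1, dasgupta = dasgupta_score(d1, g1), null = nd,
         curve = mc, fit = fit, dwell = dwell_summary(runs))
  })
  say("statistics")
  sess_tbl <- dplyr::bind_rows(lapply(per_session, function(s) tibble::tibble(
    session = s$session, subject = s$subject, task = s$task,
    n_postures = length(unique(s$runs$posture)),
    n_modules = s$modules$n_modules, modularity = s$modules$Q,
    dasgupta = s$dasgupta, modularity_p = s$null$p_value,
    mean_dwell_s = s$dwell$mean_s,
    half_life = if (is.null(s$fit)) NA_real_ else s$fit$half_life)))
  stats <- list(sessions = sess_tbl)
  if (length(unique(sess_tbl$subject)) > 1 && length(unique(sess_tbl$task)) > 1 &&
      nrow(sess_tbl) >= 4) {
    stats$anova_modularity <- tryCatch(
      compare_sessions(dplyr::rename(sess_tbl, value = "modularity"), "anova"),
      error = function(e) NULL)
    mod_tbl <- tibble::tibble(
      session = sess_tbl$session, subject = sess_tbl$subject,
      task = sess_tbl$task,
      modules = lapply(per_session, function(s) s$modules))
    stats$pairwise_ami <- compare_sessions(
      mod_tbl, "paired_ami", n_permutations = config$n_permutations,
      seed = child_seed(config$seed, "pairami"))
    stats$partialled <- tryCatch(
      compare_sessions(stats$pairwise_ami, "partialled_ttest"),
      error = function(e) NULL)
  }
  res <- list(features = fm, pca = pca, embedding = emb, density = dens,
              postures = pm, labels = labels, sessions = per_session,
              stats = stats, alignment = alignment,
              qc = lapply(prep, `[[`, "qc"), config = config)
  if (!is.null(out_dir)) write_run_dir(res, out_dir, t0)
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}

load_sessions <- function(sessions, skeleton) {
  if (is.data.frame(sessions)) {
    stopifnot("pose_file" %in% names(sessions))
    seqs <- lapply(sessions$pose_file, read_pose_table, skeleton = skeleton)
    names(seqs) <- vapply(seqs, `[[`, "", "session_id")
    seqs
  } else if (is.list(sessions) && all(vapply(sessions, inherits, TRUE, "pose_sequence"))) {
    if (is.null(names(sessions)))
      names(sessions) <- vapply(sessions, `[[`, "", "session_id")
    sessions
  } else stopf("sessions must be a manifest tibble or a list of pose_sequence objects")
}

write_run_dir <- function(res, out_dir, t0 = Sys.time()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(res$labels, file.path(out_dir, "posture_labels.csv"),
                   progress = FALSE)
  readr::write_csv(res$stats$sessions, file.path(out_dir, "session_metrics.csv"),
                   progress = FALSE)
  for (s in res$sessions) {
    base <- file.path(out_dir, s$session)
    M <- s$graph$M
    readr::write_csv(tibble::as_tibble(as.data.frame(M), rownames = "to"),
                     paste0(base, "_transition_lag1.csv"), progress = FALSE)
    write_dendrogram_newick(s$dendrogram, paste0(base, "_dendrogram.nwk"))
    readr::write_csv(tibble::enframe(s$modules$membership,
                                     name = "posture", value = "module"),
                     paste0(base, "_modules.csv"), progress = FALSE)
    readr::write_csv(s$curve, paste0(base, "_modularity_curve.csv"),
                     progress = FALSE)
  }
  if (!is.null(res$stats$pairwise_ami))
    readr::write_csv(res$stats$pairwise_ami,
                     file.path(out_dir, "pairwise_ami.csv"), progress = FALSE)
  report <- list(
    sessions = res$stats$sessions,
    anova_modularity = res$stats$anova_modularity,
    partialled = res$stats$partialled,
    qc = res$qc,
    alignment = res$alignment)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  cfg <- res$config
  cfg$cage_bounds <- unlist(cfg$cage_bounds)
  jsonlite::write_json(
    list(config = cfg,
         n_frames = nrow(res$labels),
         n_postures = res$postures$n_postures,
         started = format(t0), finished = format(Sys.time()),
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("ethokit"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
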