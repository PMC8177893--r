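#' Write a region time series as TSV + JSON sidecar
#'
#' The TSV holds samples in rows and channels in columns with a header
#' of channel labels; the sidecar (same path with `.json`) carries the
#' sampling rate, labels, group tags, subject and condition. The round
#' trip is lossless to the printed float precision.
#'
#' @param x a `region_ts`.
#' @param path output TSV path.
#' @export
write_region_timeseries <- function(x, path) {
  stopifnot(inherits(x, "region_ts"))
  df <- as.data.frame(t(x$data))
  names(df) <- x$labels
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(list(fs = x$fs, labels = x$labels,
                            groups = x$groups, subject_id = x$subject_id,
                            condition = x$condition),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region time series written by [write_region_timeseries()]
#'
#' @param path TSV path; the `.json` sidecar must sit next to it.
#' @return a `region_ts`.
#' @export
read_region_timeseries <- function(path) {
  side <- sub("\\.tsv$", ".json", path)
  if (identical(side, path)) side <- paste0(path, ".json")
  if (!file.exists(side)) stopf("missing JSON sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$fs)) stopf("sidecar %s has no 'fs' field", side)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  if (!length(header) || any(!nzchar(header)))
    stopf("malformed header at line 1 of %s", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, TRUE))
  if (length(bad))
    stopf("non-numeric data in column '%s' of %s", names(df)[bad[1]], path)
  region_timeseries(t(as.matrix(df)), fs = meta$fs,
                    labels = meta$labels %||% header,
                    groups = meta$groups,
                    subject_id = meta$subject_id %||% "S01",
                    condition = meta$condition %||% "A")
}

#' Write a simulated cohort to a directory
#'
#' One TSV + sidecar per subject per condition plus a `ground_truth.json`
#' with the state sequences, condition permutations and true edge
#' specifications.
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in names(cohort$data)) {
    for (s in seq_along(cohort$data[[cond]])) {
      write_region_timeseries(
        cohort$data[[cond]][[s]],
        file.path(dir, sprintf("%s_S%02d.tsv", cond, s)))
    }
  }
  tr <- cohort$truth
  jsonlite::write_json(list(
    K = tr$K, fs = tr$fs,
    permutations = tr$permutations,
    state_sequences = tr$state_sequences,
    fractional_occupancy = tr$fractional_occupancy,
    state_specs = lapply(tr$state_specs, function(specs)
      lapply(specs, function(sp)
        list(state_id = sp$state_id, edges = sp$edges,
             psd_background = sp$psd_background)))),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(dir)
}

#' Pipeline configuration with the study defaults
#'
#' Every tunable parameter of the analysis chain, preset to the
#' configuration this package reproduces: 250 Hz sampling, 60 ms
#' embedding window, PCA to twice the channel count, 6 states,
#' transition prior diagonal 10, 7 Slepian tapers with time-bandwidth 4
#' and a 0.5 Hz grid, 1-45 Hz band, 4 frequency modes, alpha 0.05, and
#' a 100 ms lifetime filter.
#'
#' @param ... overrides for any default.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs = 250, window_ms = 60, n_components = NULL, K = 6,
    transition_diag = 10, n_tapers = 7, time_bandwidth = 4,
    resolution_hz = 0.5, band = c(1, 45), n_modes = 4,
    alpha = 0.05, min_lifetime_ms = 100, seed = 1L,
    orthogonalise = TRUE, sign_flip = TRUE, stochastic = NULL,
    hmm_max_iter = 30, hmm_tol = 1e-6, restarts = 5,
    correction_intra = "BH", correction_inter = "bonferroni")
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config fields: %s",
                         paste(bad, collapse = ", "))
  structure(modifyList(cfg, over), class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full state-network analysis pipeline
#'
#' Per condition: preprocessing (leakage correction, z-scoring,
#' concatenation, sign flipping), time-delay embedding with PCA, VB-HMM
#' fitting, state-wise multitaper spectra, STN-cortex frequency modes,
#' and mixture-thresholded networks. Across the first two conditions:
#' Riemannian state matching, cluster-pair t-tests, and temporal-metric
#' ANOVAs. All artefacts are written as TSV/JSON under `out_dir` with a
#' manifest. The run is deterministic under `config$seed`.
#'
#' @param data named list (per condition) of lists of `region_ts`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return (invisibly) a list with per-condition `concat`, `embedded`,
#'   `hmm`, `spectra`, `coherence`, `modes`, `network`, plus `match`,
#'   `intermed`, `temporal`, `config`.
#' @export
run_pipeline <- function(data, config = pipeline_config(),
                         out_dir = NULL) {
  t0 <- Sys.time()
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)
  conds <- names(data)
  for (cond in conds) {
    concat <- preprocess_cohort(data[[cond]],
                                orthogonalise = config$orthogonalise,
                                sign_flip = config$sign_flip)
    embedded <- tde_embed_pca(concat, config$window_ms,
                              config$n_components)
    priors <- hmm_priors(embedded$data, config$K, config$transition_diag)
    fit <- hmm_fit(embedded, K = config$K, priors = priors,
                   stochastic = config$stochastic,
                   seed = derive_seed(config$seed, match(cond, conds)),
                   max_iter = config$hmm_max_iter, tol = config$hmm_tol,
                   restarts = config$restarts)
    spectra <- compute_state_spectra(concat, fit$posterior, config$K,
                                     band = config$band,
                                     n_tapers = config$n_tapers,
                                     time_bandwidth = config$time_bandwidth,
                                     resolution_hz = config$resolution_hz)
    gc_ <- build_group_coherence(spectra)
    modes <- nnmf_frequency_modes(gc_$group, gc_$freqs,
                                  n_modes = config$n_modes,
                                  seed = derive_seed(config$seed, 50L))
    proj_group <- project_onto_modes(gc_$group, modes)
    proj_subj <- lapply(gc_$subject, function(M) {
      M[!is.finite(M)] <- 0
      project_onto_modes(M, modes)
    })
    network <- gmm_threshold(proj_group, K = config$K, block = gc_$block,
                             alpha = config$alpha,
                             correction = config$correction_intra)
    res[[cond]] <- list(concat = concat, embedded = embedded,
                        hmm = fit, spectra = spectra, coherence = gc_,
                        modes = modes, proj_group = proj_group,
                        proj_subject = proj_subj, network = network)
  }
  if (length(conds) >= 2) {
    a <- res[[conds[1]]]; b <- res[[conds[2]]]
    res$match <- match_states(a$hmm$model, b$hmm$model)
    res$intermed <- intermed_ttests(
      a$proj_subject, b$proj_subject, edge_table(a$coherence),
      clusters = a$concat$groups, pairing = res$match$pairing,
      K = config$K, block = a$coherence$block, alpha = config$alpha,
      correction = config$correction_inter)
    tm <- lapply(conds[1:2], function(cond) {
      post <- res[[cond]]$hmm$posterior
      lapply(seq_along(post$boundaries), function(s) {
        eb <- post$boundaries[[s]]
        gam <- post$gamma[eb[1]:eb[2], , drop = FALSE]
        compute_temporal_metrics(max.col(gam, ties.method = "first"),
                                 fs = config$fs,
                                 min_lifetime_ms = config$min_lifetime_ms,
                                 n_states = config$K)
      })
    })
    res$temporal_metrics <- stats::setNames(tm, conds[1:2])
    res$temporal <- suppressWarnings(
      anova_temporal(tm[[1]], tm[[2]], conditions = conds[1:2]))
  }
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir, t0)
  invisible(res)
}

write_pipeline_artifacts <- function(res, out_dir, t0) {
  cfg <- res$config
  conds <- setdiff(names(res), c("config", "match", "intermed",
                                 "temporal", "temporal_metrics"))
  for (cond in conds) {
    r <- res[[cond]]
    md <- data.frame(freq_hz = r$modes$freqs, t(r$modes$modes))
    names(md) <- c("freq_hz", sprintf("mode%d_%s", seq_len(cfg$n_modes),
                                      gsub("/", "", r$modes$labels)))
    write.table(md, file.path(out_dir, sprintf("modes_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(r$network$edges,
                file.path(out_dir, sprintf("network_%s.tsv", cond)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      K = r$hmm$model$K,
      free_energy = tail(r$hmm$model$free_energy_trace, 1),
      transition = r$hmm$model$transition,
      n_pca_components = nrow(r$embedded$data)),
      file.path(out_dir, sprintf("hmm_%s.json", cond)), digits = NA)
  }
  if (!is.null(res$match))
    jsonlite::write_json(list(distance_matrix = res$match$distance_matrix,
                              pairing = res$match$pairing,
                              total_distance = res$match$total_distance),
                         file.path(out_dir, "state_match.json"),
                         digits = NA)
  if (!is.null(res$intermed))
    write.table(res$intermed$tests, file.path(out_dir, "intermed.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$temporal)) {
    write.table(res$temporal$tables$fo,
                file.path(out_dir, "temporal_fo.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$temporal$lifetime$anova,
                file.path(out_dir, "temporal_lifetime_anova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    config = res$config[!vapply(res$config, is.null, TRUE)],
    config_hash = config_hash(res$config),
    n_pca_components = if (length(conds))
      nrow(res[[conds[1]]]$embedded$data) else NULL,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("tdehmm")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
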