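#' Configuration for an end-to-end pipeline run
#'
#' Collects and validates every tunable of the analysis. A config
#' round-trips losslessly through JSON ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param values_a,covariates_a,values_b,covariates_b Paths to the two
#'   groups' panel files ([write_panel()] format). Leave `NULL` together
#'   with `simulate = TRUE` to generate a synthetic cohort instead.
#' @param simulate Generate the input cohort with [generate_cohort()]
#'   (default `TRUE` when no input paths are given).
#' @param spec A [cohort_spec()] used when `simulate` is `TRUE`.
#' @param d_min,d_max,d_step Connection-density sweep (defaults 0.10-0.40
#'   by 0.01).
#' @param nodal_density Fixed density for the nodal analysis (default 0.10).
#' @param n_perm Permutations for both tests (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param hub_threshold Normalized-betweenness hub cutoff (default 1.5).
#' @param n_random_refs Random references for the observed networks
#'   (default 100).
#' @param n_random_refs_perm Random references inside permutations
#'   (default 10).
#' @param covariates Covariates to residualize.
#' @param global_metrics Metrics for the global test.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (created if absent).
#' @return A list of class `run_config`.
#' @export
run_config <- function(values_a = NULL, covariates_a = NULL,
                       values_b = NULL, covariates_b = NULL,
                       simulate = is.null(values_a),
                       spec = cohort_spec(),
                       d_min = 0.10, d_max = 0.40, d_step = 0.01,
                       nodal_density = 0.10,
                       n_perm = 1000, alpha = 0.05, hub_threshold = 1.5,
                       n_random_refs = 100, n_random_refs_perm = 10,
                       covariates = c("age", "sex", "glucose"),
                       global_metrics = c("gamma", "lambda", "sigma"),
                       seed = 1L, out_dir = "metabnet_run") {
  stopifnot(d_min > 0, d_max < 1, d_min <= d_max, d_step > 0,
            nodal_density > 0, nodal_density < 1,
            n_perm >= 20, alpha > 0, alpha < 1, hub_threshold > 0,
            n_random_refs >= 1, n_random_refs_perm >= 1)
  if (!simulate && (is.null(values_a) || is.null(covariates_a) ||
                    is.null(values_b) || is.null(covariates_b))) {
    stop("either set simulate = TRUE or supply all four panel paths")
  }
  structure(list(values_a = values_a, covariates_a = covariates_a,
                 values_b = values_b, covariates_b = covariates_b,
                 simulate = simulate, spec = spec,
                 d_min = d_min, d_max = d_max, d_step = d_step,
                 nodal_density = nodal_density, n_perm = n_perm,
                 alpha = alpha, hub_threshold = hub_threshold,
                 n_random_refs = n_random_refs,
                 n_random_refs_perm = n_random_refs_perm,
                 covariates = covariates, global_metrics = global_metrics,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the reconstructed `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(cohort_spec, c(
    x$spec[setdiff(names(x$spec), "covariate_effects")],
    list(covariate_effects = as.list(x$spec$covariate_effects))))
  do.call(run_config, c(x[setdiff(names(x), "spec")], list(spec = spec)))
}

#' Mean regional values from a 3-D image and an integer label atlas
#'
#' Averages image intensities over the voxels of each atlas label, returning
#' one value per region in canonical label order — the ROI-mean extraction
#' that turns an (already spatially normalized) metabolic image into one row
#' of a subject panel.
#'
#' @param image 3-D numeric array, or a NIfTI file path (read with the
#'   RNifti package when installed).
#' @param atlas_labels Integer 3-D array (or NIfTI path) of the same
#'   dimensions; 0 = background, labels 1..K = regions.
#' @param labels Label values to extract (default `1:max`).
#' @return Named numeric vector of per-region means.
#' @export
extract_roi_means <- function(image, atlas_labels, labels = NULL) {
  load_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        stop("reading NIfTI files requires the RNifti package")
      }
      x <- as.array(RNifti::readNifti(x))
    }
    x
  }
  image <- load_vol(image)
  atlas_labels <- load_vol(atlas_labels)
  if (!identical(dim(image), dim(atlas_labels))) {
    stop("image and atlas grids do not match: ",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(atlas_labels), collapse = "x"))
  }
  lab <- as.integer(round(atlas_labels))
  if (is.null(labels)) labels <- seq_len(max(lab))
  out <- vapply(labels, function(l) {
    sel <- lab == l
    if (!any(sel)) {
      stop("atlas label ", l, " has no voxels")
    }
    mean(image[sel])
  }, numeric(1))
  names(out) <- sprintf("R%03d", labels)
  out
}

#' Run the full covariance-network pipeline
#'
#' Sequences every stage: load or simulate the two panels, global-mean
#' normalization, covariate residualization (per group), per-group Pearson
#' correlation, density sweep and small-world characterization, hub
#' identification at the fixed nodal density, the global and nodal
#' permutation tests, and the betweenness-distribution correlation. All
#' intermediate artifacts (panels, matrices, metric tables, significance
#' tables) are written under `config$out_dir` as TSV/JSON, together with a
#' JSON `summary.json` and a plain-text run log. Outputs are byte-identical
#' for identical config and seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: panels,
#'   correlation matrices, `small_world` objects per density per group,
#'   hub tables, shared hubs, the two `permutation_result`s, and the
#'   betweenness-distribution correlation.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("metabnet %s", as.character(utils::packageVersion("metabnet"))),
                 sprintf("seed: %d", config$seed))
  logmsg <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # --- stage: input panels -------------------------------------------------
  if (config$simulate) {
    logmsg("stage simulate: generating synthetic cohort (seed %d)",
           config$spec$seed)
    cohort <- generate_cohort(config$spec)
    panel_a <- cohort$panel_a
    panel_b <- cohort$panel_b
    write_panel(panel_a, file.path(config$out_dir, "values_A.tsv"),
                file.path(config$out_dir, "covariates_A.tsv"))
    write_panel(panel_b, file.path(config$out_dir, "values_B.tsv"),
                file.path(config$out_dir, "covariates_B.tsv"))
    write_matrix_tsv(cohort$truth$adjacency_a,
                     file.path(config$out_dir, "truth_adjacency_A.tsv"))
    write_matrix_tsv(cohort$truth$adjacency_b,
                     file.path(config$out_dir, "truth_adjacency_B.tsv"))
  } else {
    logmsg("stage load: reading panels")
    panel_a <- read_panel(config$values_a, config$covariates_a)
    panel_b <- read_panel(config$values_b, config$covariates_b)
  }
  n_regions <- ncol(panel_a$values)
  region_table <- if (n_regions == 90) load_region_table() else NULL

  # --- stage: preprocess ---------------------------------------------------
  logmsg("stage preprocess: normalization + residualization (%s)",
         paste(config$covariates, collapse = ", "))
  res_a <- preprocess_panel(panel_a, covariates = config$covariates)
  res_b <- preprocess_panel(panel_b, covariates = config$covariates)

  # --- stage: network ------------------------------------------------------
  corr_a <- pearson_matrix(res_a)
  corr_b <- pearson_matrix(res_b)
  labels <- colnames(panel_a$values)
  write_matrix_tsv(corr_a$r, file.path(config$out_dir, "correlation_A.tsv"),
                   metadata = list(group = panel_a$group,
                                   n_subjects = corr_a$n_subjects))
  write_matrix_tsv(corr_b$r, file.path(config$out_dir, "correlation_B.tsv"),
                   metadata = list(group = panel_b$group,
                                   n_subjects = corr_b$n_subjects))
  densities <- seq(config$d_min, config$d_max, by = config$d_step)
  mfc_a <- min_full_connection_density(corr_a, densities)
  mfc_b <- min_full_connection_density(corr_b, densities)
  logmsg("stage network: lowest fully-connecting density A=%s B=%s",
         format(mfc_a), format(mfc_b))

  # --- stage: metrics ------------------------------------------------------
  sw <- list()
  global_rows <- list()
  .with_seed(config$seed + 1L, {
    for (g in c("A", "B")) {
      corr <- if (g == "A") corr_a else corr_b
      for (d in densities) {
        net <- density_threshold(corr, d)
        if (largest_component_size(net) < n_regions) {
          logmsg("stage metrics: group %s density %.2f disconnected; skipped",
                 g, d)
          global_rows[[length(global_rows) + 1L]] <- data.frame(
            group = g, density = d, C = NA_real_, L = NA_real_,
            gamma = NA_real_, lambda = NA_real_, sigma = NA_real_)
          next
        }
        s <- small_world(net, n_random = config$n_random_refs)
        sw[[g]][[sprintf("%.2f", d)]] <- s
        global_rows[[length(global_rows) + 1L]] <- data.frame(
          group = g, density = d, C = s$C, L = s$L, gamma = s$gamma,
          lambda = s$lambda, sigma = s$sigma)
      }
    }
  })
  global_tab <- do.call(rbind, global_rows)
  utils::write.table(global_tab,
                     file.path(config$out_dir, "global_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  net_a0 <- density_threshold(corr_a, config$nodal_density)
  net_b0 <- density_threshold(corr_b, config$nodal_density)
  nc_a <- nodal_centrality(net_a0, region_table)
  nc_b <- nodal_centrality(net_b0, region_table)
  rt_eff <- if (!is.null(region_table)) region_table else {
    data.frame(index = seq_len(n_regions), abbreviation = labels,
               hemisphere = NA_character_, func_class = NA_character_)
  }
  hubs_a <- identify_hubs(nc_a, rt_eff, threshold = config$hub_threshold)
  hubs_b <- identify_hubs(nc_b, rt_eff, threshold = config$hub_threshold)
  shared <- shared_hubs(hubs_a, hubs_b)
  utils::write.table(nc_a, file.path(config$out_dir, "nodal_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(nc_b, file.path(config$out_dir, "nodal_B.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logmsg("stage metrics: %d hubs in A, %d in B, %d shared (b > %.2f at density %.2f)",
         nrow(hubs_a), nrow(hubs_b), nrow(shared), config$hub_threshold,
         config$nodal_density)
  bcorr <- centrality_distribution_correlation(nc_a$b, nc_b$b)

  # --- stage: inference ----------------------------------------------------
  logmsg("stage permtest: %d relabelings (global seed %d, nodal seed %d)",
         config$n_perm, config$seed + 2L, config$seed + 3L)
  gtest <- global_permutation_test(
    panel_a, panel_b, densities = densities,
    metrics = config$global_metrics, n_perm = config$n_perm,
    alpha = config$alpha, n_random_refs = config$n_random_refs_perm,
    covariates = config$covariates, seed = config$seed + 2L)
  ntest <- nodal_permutation_test(
    panel_a, panel_b, density = config$nodal_density,
    n_perm = config$n_perm, alpha = config$alpha,
    covariates = config$covariates, region_table = region_table,
    seed = config$seed + 3L)
  utils::write.table(gtest$table,
                     file.path(config$out_dir, "global_permutation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ntest$table,
                     file.path(config$out_dir, "nodal_permutation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sig_runs <- lapply(split(gtest$table[gtest$table$significant, "density"],
                           gtest$table[gtest$table$significant, "metric"]),
                     format_density_runs)
  summary <- list(
    config = list(seed = config$seed, n_perm = config$n_perm,
                  alpha = config$alpha, densities = range(densities),
                  nodal_density = config$nodal_density,
                  hub_threshold = config$hub_threshold,
                  n_random_refs = config$n_random_refs,
                  n_random_refs_perm = config$n_random_refs_perm,
                  covariates = config$covariates),
    groups = list(A = list(n_subjects = nrow(panel_a$values)),
                  B = list(n_subjects = nrow(panel_b$values))),
    min_full_connection_density = list(A = mfc_a, B = mfc_b),
    global_metrics = global_tab,
    hubs = list(A = hubs_a, B = hubs_b, shared = shared),
    betweenness_distribution_correlation = bcorr,
    global_significant_densities_pct = sig_runs,
    nodal_significant = list(
      decreased = ntest$table$abbreviation[ntest$table$significant_decrease],
      increased = ntest$table$abbreviation[ntest$table$significant_increase])
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(panel_a = panel_a, panel_b = panel_b,
                 residuals_a = res_a, residuals_b = res_b,
                 correlation_a = corr_a, correlation_b = corr_b,
                 small_world = sw, global_metrics = global_tab,
                 nodal_a = nc_a, nodal_b = nc_b,
                 hubs_a = hubs_a, hubs_b = hubs_b, shared_hubs = shared,
                 betweenness_correlation = bcorr,
                 global_test = gtest, nodal_test = ntest,
                 summary = summary))
}
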