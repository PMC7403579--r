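#' Long-format radar data for compound response scores
#'
#' One row per compound x latent vector with the response score and a
#' zero baseline column, vectors in `P1V...PKV` (clockwise) order —
#' plotting-front-end agnostic; [plot_radar()] consumes it directly.
#'
#' @param fit An `olsa_fit`.
#' @param compounds Character vector of compound ids in the fit.
#' @return A tibble with `compound_id`, `vector`, `score`, `baseline`
#'   (always 0, the zero-score reference line).
#' @export
radar_data <- function(fit, compounds) {
  stopifnot(inherits(fit, "olsa_fit"))
  unknown <- setdiff(compounds, rownames(fit$scores))
  if (length(unknown) > 0) {
    abort(sprintf("unknown compound(s): %s", fmt_ids(unknown)))
  }
  vnames <- colnames(fit$scores)
  purrr::map_dfr(compounds, function(cpd) {
    tibble(compound_id = cpd, vector = vnames,
           score = unname(fit$scores[cpd, ]), baseline = 0)
  })
}

default_run_config <- function() {
  list(orientation = "compounds_as_rows", threshold = 0.8,
       unit_normalize = TRUE, fraction = 0.01,
       vector = "auto", auto_term = NULL,
       m_values = c(0.25, 0.5, 0.75, 1, 1.5, 2),
       markers = character(0), references = character(0),
       moderate_m = 0.75, high_m = 2, n_negative = 3,
       cluster_unit_normalize = FALSE)
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path")
  cfg <- utils::modifyList(default_run_config(), config)
  for (field in c("input", "out_dir")) {
    if (is.null(cfg[[field]])) abort(sprintf("config field `%s` is required", field))
  }
  for (field in c("input", "gene_sets", "flags")) {
    if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]])) {
      abort(sprintf("config field `%s`: file not found: '%s'",
                    field, cfg[[field]]))
    }
  }
  for (field in c("threshold", "fraction")) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("config field `%s` must be in (0, 1]", field))
    }
  }
  if (identical(cfg$vector, "auto") && !is.null(cfg$gene_sets) &&
      is.null(cfg$auto_term)) {
    abort("config field `auto_term` is required when `vector` is \"auto\"")
  }
  cfg
}

#' Run the full separation pipeline and write a report bundle
#'
#' Orchestrates decompose -> annotate -> select -> cluster on one profile
#' matrix and writes a deterministic bundle of plain-text outputs:
#' `loadings.tsv`, `scores.tsv`, `variance.tsv`, `strength.tsv`,
#' `enrichment.tsv` (all vectors, when gene sets are given),
#' `selection_report.tsv`, `indicator_comparison.tsv`, `dendrogram.tsv`,
#' `radar.tsv`, and `manifest.yaml` (config hash + software version +
#' per-stage shapes). Identical config and inputs yield byte-identical
#' bundles. Outputs are staged in a temporary directory and moved into
#' `out_dir` only on success, so a failed stage (reported with its stage
#' name) leaves no partial bundle.
#'
#' Config fields (list or YAML file): `input` (profile path, required),
#' `out_dir` (required), `orientation`, `threshold`, `unit_normalize`,
#' `gene_sets` (GMT path), `flags` (flags path), `fraction`, `vector`
#' (explicit name like `"P14V"`, or `"auto"` to pick the vector whose
#' enrichment for `auto_term` has the smallest FDR, ties to the lower
#' vector index), `m_values`, `markers`, `references`, `moderate_m`,
#' `high_m`, `n_negative`, `cluster_unit_normalize`.
#'
#' @param config A named list or path to a YAML file.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the fitted objects (`fit`,
#'   `selection`, `indicators`, `dendrogram`, `enrichment`,
#'   `vector_name`, `config`, `out_dir`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- validate_run_config(config)
  stage <- "setup"
  log_line <- function(...) if (!quiet) message(sprintf(...))
  staging <- file.path(tempfile("latentfx_run_"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  result <- tryCatch({
    stage <- "read"
    profile <- read_profile_matrix(cfg$input, orientation = cfg$orientation)
    sets <- if (!is.null(cfg$gene_sets)) read_gene_sets(cfg$gene_sets)
    flags <- if (!is.null(cfg$flags)) read_flags(cfg$flags)
    log_line("[read] profile %d x %d; %s gene sets; %s flags",
             nrow(profile), ncol(profile) - 1,
             if (is.null(sets)) 0 else nrow(sets),
             if (is.null(flags)) 0 else nrow(flags))

    stage <- "decompose"
    fit <- decompose_profiles(profile, threshold = cfg$threshold,
                              unit_normalize = cfg$unit_normalize)
    readr::write_tsv(
      dplyr::bind_cols(tibble(gene_id = rownames(fit$loadings)),
                       as_tibble(fit$loadings)),
      file.path(staging, "loadings.tsv"))
    write_profile_matrix(fit$scores, file.path(staging, "scores.tsv"))
    readr::write_tsv(tidy(fit, "variance"), file.path(staging, "variance.tsv"))
    readr::write_tsv(tidy(fit, "strength"), file.path(staging, "strength.tsv"))
    log_line("[decompose] K=%d at threshold %.2f (varimax sweeps %d, converged %s)",
             fit$n_components, cfg$threshold, fit$varimax$iterations,
             fit$varimax$converged)

    stage <- "annotate"
    enrichment <- NULL
    vector_name <- cfg$vector
    gene_ids <- setdiff(names(profile), "compound_id")
    if (!is.null(sets)) {
      enrichment <- purrr::map_dfr(colnames(fit$scores), function(v) {
        sig <- top_fraction_genes(fit, v, fraction = cfg$fraction)
        dplyr::mutate(enrich(sig, sets, gene_ids), vector = v,
                      .before = 1)
      })
      readr::write_tsv(enrichment, file.path(staging, "enrichment.tsv"))
      if (identical(cfg$vector, "auto")) {
        hits <- dplyr::filter(enrichment, .data$term_id == cfg$auto_term)
        if (nrow(hits) == 0) {
          abort(sprintf("auto_term '%s' not found in any enrichment table",
                        cfg$auto_term))
        }
        hits$index <- as.integer(sub("^P(\\d+)V$", "\\1", hits$vector))
        hits <- dplyr::arrange(hits, .data$fdr, .data$index)
        vector_name <- hits$vector[1]
      }
    } else if (identical(cfg$vector, "auto")) {
      vector_name <- colnames(fit$scores)[1]
    }
    log_line("[annotate] vector of interest: %s", vector_name)

    stage <- "select"
    scores <- score_table(fit, vector_name)
    selection <- categorize(scores, flags, moderate_m = cfg$moderate_m,
                            high_m = cfg$high_m, n_negative = cfg$n_negative)
    readr::write_tsv(as_tibble(selection),
                     file.path(staging, "selection_report.tsv"))
    indicators <- c(
      setNames(list(scores), paste0("vector_score:", vector_name)),
      setNames(lapply(cfg$markers, function(g) {
        marker_indicator(profile, g)
      }), if (length(cfg$markers)) paste0("marker:", cfg$markers)),
      setNames(lapply(cfg$references, function(cpd) {
        reference_correlation(profile, cpd)
      }), if (length(cfg$references)) paste0("refcorr:", cfg$references)))
    comparison <- compare_indicators(indicators, cfg$m_values, flags)
    flat <- dplyr::mutate(comparison,
                          hits = vapply(.data$hits, paste, character(1),
                                        collapse = ","))
    readr::write_tsv(flat, file.path(staging, "indicator_comparison.tsv"))
    log_line("[select] %d high, %d moderate, %d negative",
             sum(selection$category == "high"),
             sum(selection$category == "moderate"),
             sum(selection$category == "negative"))

    stage <- "cluster"
    dend <- ward_linkage(profile, unit_normalize = cfg$cluster_unit_normalize)
    write_dendrogram(dend, file.path(staging, "dendrogram.tsv"))
    log_line("[cluster] %d merges, max height %.4g",
             nrow(dend$merges), max(dend$merges$height))

    stage <- "report"
    featured <- selection$compound_id[selection$category != "other"]
    if (length(featured) == 0) featured <- selection$compound_id
    readr::write_tsv(radar_data(fit, featured),
                     file.path(staging, "radar.tsv"))
    ## out_dir is a location, not an analysis parameter: excluding it from
    ## the hash keeps bundles byte-identical across output locations
    manifest <- list(
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
      package_version = as.character(utils::packageVersion("latentfx")),
      n_compounds = fit$n_compounds, n_genes = fit$n_genes,
      n_components = fit$n_components,
      varimax_iterations = fit$varimax$iterations,
      varimax_converged = fit$varimax$converged,
      vector_of_interest = vector_name,
      outputs = sort(list.files(staging)))
    yaml::write_yaml(manifest, file.path(staging, "manifest.yaml"))

    list(fit = fit, selection = selection, indicators = comparison,
         dendrogram = dend, enrichment = enrichment,
         vector_name = vector_name, config = cfg, out_dir = cfg$out_dir)
  }, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)), parent = e)
  })

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(cfg$out_dir, f),
              overwrite = TRUE)
  }
  invisible(result)
}
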