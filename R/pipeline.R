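#' Run configuration
#'
#' Bundles the tunable analysis parameters: the sparsity grid, permutation
#' count (>= 100 for reported runs), master seed, the covariate sets for
#' group contrasts and symptom associations, the FDR level and the output
#' directory.
#'
#' @param grid_from,grid_to,grid_by sparsity grid bounds and step.
#' @param n_perm permutations (default 1000).
#' @param seed master seed.
#' @param covariates_group covariates for group contrasts.
#' @param covariates_assoc covariates for symptom associations.
#' @param q FDR level in (0, 1).
#' @param metrics nodal metrics to analyze.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(grid_from = 0.10, grid_to = 0.30, grid_by = 0.01,
                       n_perm = 1000, seed = 1,
                       covariates_group = c("age", "sex", "volume"),
                       covariates_assoc = c("age", "sex", "volume",
                                            "medication_history"),
                       q = 0.05,
                       metrics = c("strength", "betweenness", "clustering"),
                       out_dir = "limbconn_results") {
  if (n_perm < 100) stop("n_perm must be >= 100 for reported runs")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  cfg <- as.list(environment())
  cfg$grid <- sparsity_grid(grid_from, grid_to, grid_by)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the [run_config()] arguments (`grid_from`,
#' `grid_to`, `grid_by`, `n_perm`, `seed`, `covariates_group`,
#' `covariates_assoc`, `q`, `metrics`, `out_dir`); missing keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  allowed <- setdiff(names(formals(run_config)), "")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, y)
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes metrics + AUC summarization, the covariate-adjusted permutation
#' group comparison, limbic volume comparisons, and the MADRS and QIDS
#' symptom associations; writes all result CSVs plus a run-metadata JSON to
#' `cfg$out_dir`. Deterministic: the same cohort, config and seed produce
#' byte-identical outputs.
#'
#' @param cohort a `limb_cohort` or a cohort directory path.
#' @param cfg a [run_config()].
#' @return the results bundle (list), invisibly.
#' @export
run_pipeline <- function(cohort, cfg = run_config()) {
  if (is.character(cohort)) cohort <- load_cohort(cohort)
  stopifnot(inherits(cohort, "limb_cohort"), inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    log_msg("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  features <- stage("metrics",
    compute_nodal_features(cohort, cfg$grid, cfg$metrics))
  groups <- stage("group_comparison",
    compare_groups(features, cohort, cfg$covariates_group, cfg$n_perm,
                   cfg$seed, cfg$q, cfg$metrics))
  has_limbic <- any(cohort$region_table$family != "none")
  volumes <- if (has_limbic) stage("volume_comparison",
                                   compare_volumes(cohort)) else NULL
  assoc <- NULL
  if (has_limbic) {
    assoc <- stage("associations", do.call(rbind, lapply(
      intersect(c("madrs", "qids"), names(cohort$subjects)),
      function(sc) associate_limbic(features, cohort, sc,
                                    cfg$covariates_assoc, cfg$metrics, cfg$q))))
  }
  demo <- stage("demographics", demographics_table(cohort))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results(groups, file.path(cfg$out_dir, "group_comparison.csv"))
  if (!is.null(volumes))
    write_results(volumes, file.path(cfg$out_dir, "volume_comparison.csv"))
  if (!is.null(assoc))
    write_results(assoc, file.path(cfg$out_dir, "associations.csv"))
  write.csv(demo, file.path(cfg$out_dir, "demographics.csv"),
            row.names = FALSE)
  data.table::fwrite(features, file.path(cfg$out_dir, "nodal_features.csv"))
  meta <- list(n_subjects = nrow(cohort$subjects),
               n_regions = nrow(cohort$region_table),
               grid = cfg$grid, n_perm = cfg$n_perm, seed = cfg$seed,
               covariates_group = cfg$covariates_group,
               covariates_assoc = cfg$covariates_assoc, q = cfg$q,
               metrics = cfg$metrics,
               package_version = as.character(utils::packageVersion("limbconn")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  bundle <- list(features = features, groups = groups, volumes = volumes,
                 associations = assoc, demographics = demo, config = cfg)
  invisible(bundle)
}

#' Render a markdown report from a results bundle
#'
#' Deterministic, human-readable summary: FDR discoveries per metric,
#' demographics table, volume checks and symptom-association tables.
#'
#' @param bundle results list from [run_pipeline()].
#' @param path optional file to write; `NULL` returns the text.
#' @return the markdown text, invisibly if written to file.
#' @export
render_report <- function(bundle, path = NULL) {
  req <- c("groups", "demographics")
  miss <- req[!vapply(req, function(k) !is.null(bundle[[k]]), logical(1))]
  if (length(miss)) stop("incomplete bundle, missing: ",
                         paste(miss, collapse = ", "))
  q <- bundle$config$q %||% 0.05
  fmt_tab <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    paste(c(header, sep, body), collapse = "\n")
  }
  out <- c("# Connectome hierarchy analysis report", "",
           "## Group comparison (FDR-corrected nodal features)", "")
  for (m in unique(bundle$groups$metric)) {
    gm <- bundle$groups[bundle$groups$metric == m, ]
    disc <- gm[gm$q_fdr <= q, , drop = FALSE]
    out <- c(out, sprintf("### %s", m), "")
    if (nrow(disc) == 0) {
      out <- c(out, sprintf("Zero FDR discoveries at q <= %.2g.", q), "")
    } else {
      disc <- disc[order(-abs(disc$t)), ]
      out <- c(out, fmt_tab(disc[, c("region", "t", "df", "cohen_d",
                                     "p_perm", "q_fdr", "direction")]), "")
    }
  }
  out <- c(out, "## Demographics", "", fmt_tab(bundle$demographics), "")
  if (!is.null(bundle$volumes))
    out <- c(out, "## Limbic subregion volumes (uncorrected two-sample t)",
             "", fmt_tab(bundle$volumes), "")
  if (!is.null(bundle$associations)) {
    out <- c(out, "## Symptom associations (patients only)", "",
             fmt_tab(bundle$associations[
               order(bundle$associations$p),
               c("region", "metric", "score", "rho", "p", "q_fdr",
                 "n_used")]), "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (emit a synthetic cohort directory), `run` (full
#' pipeline on a cohort directory), `report` (markdown report from a results
#' directory's bundle is not persisted, so `report` re-runs are driven by
#' `run`'s outputs). Invoke via
#' `Rscript -e 'limbconn::limbconn_main()' simulate --out cohort_dir`.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
limbconn_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: limbconn <simulate|run> [--config file.yaml] [--seed n]",
        "[--n-perm n] [--grid from:to:by] [--q q] [--out dir]",
        "[--cohort dir] [--delta d] [--deficit-node i]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i])
    opt[[key]] <- if (i + 1 <= length(kv)) kv[i + 1] else ""
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (!is.null(opt$`n-perm`)) cfg$n_perm <- as.integer(opt$`n-perm`)
  if (!is.null(opt$q)) cfg$q <- as.numeric(opt$q)
  if (!is.null(opt$grid)) {
    g <- as.numeric(strsplit(opt$grid, ":")[[1]])
    cfg$grid <- sparsity_grid(g[1], g[2], g[3])
  }
  if (!is.null(opt$out)) cfg$out_dir <- opt$out

  if (cmd == "simulate") {
    sim <- simulation_config(
      seed = cfg$seed,
      deficit_nodes = if (!is.null(opt$`deficit-node`))
        as.integer(opt$`deficit-node`) else integer(0),
      delta = if (!is.null(opt$delta)) as.numeric(opt$delta) else 0)
    co <- generate_cohort(sim)
    write_cohort(co, cfg$out_dir)
    log_msg("wrote synthetic cohort to %s", cfg$out_dir)
  } else if (cmd == "run") {
    if (is.null(opt$cohort)) stop("run requires --cohort <dir>")
    bundle <- run_pipeline(opt$cohort, cfg)
    render_report(bundle, file.path(cfg$out_dir, "report.md"))
    log_msg("results written to %s", cfg$out_dir)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
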