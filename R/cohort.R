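#' Validate and normalize a connectivity matrix
#'
#' A structural connectivity matrix holds SIFT2-weighted streamline counts
#' between all region pairs. It must be square, nonnegative, symmetric
#' within tolerance and have a zero diagonal. Small asymmetries (at most
#' `tol * max(W)`) are silently symmetrized by averaging `(W + t(W)) / 2`;
#' anything larger is treated as corrupt input. A nonzero diagonal is forced
#' to zero with a warning.
#'
#' @param W numeric square matrix of nonnegative weights.
#' @param n_regions expected dimension (e.g. `nrow(region_table)`); `NULL`
#'   skips the check.
#' @param tol relative asymmetry tolerance (default `1e-8`).
#' @return the validated, symmetrized matrix with zero diagonal.
#' @export
validate_matrix <- function(W, n_regions = NULL, tol = 1e-8) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("connectivity matrix must be square")
  if (!is.null(n_regions) && nrow(W) != n_regions)
    stop(sprintf("matrix dimension %d does not match region table (%d regions)",
                 nrow(W), n_regions))
  if (!is.numeric(W) || anyNA(W)) stop("matrix must be numeric without NA")
  if (any(W < 0)) stop("negative weight in connectivity matrix")
  mx <- max(W)
  asym <- max(abs(W - t(W)))
  if (mx > 0 && asym > tol * mx)
    stop(sprintf("asymmetry %.3g exceeds tolerance %.3g * max weight",
                 asym, tol * mx))
  W <- (W + t(W)) / 2
  if (any(diag(W) != 0)) {
    warning("nonzero diagonal forced to zero")
    diag(W) <- 0
  }
  dimnames(W) <- NULL
  W
}

#' Assemble a cohort object
#'
#' A cohort pairs a region table with subject metadata and one connectivity
#' matrix per subject. Required metadata columns: `subject_id`, `group`
#' (`MDD`/`HC`), `age`, `sex` (`male`/`female`), `medication_history`
#' (0/1), `madrs`, `qids` (may be `NA`), plus per-region volume columns
#' `vol_<region name>` (may be absent or `NA`). Missing scores/volumes are
#' kept as `NA`; downstream operations drop incomplete subjects listwise
#' and log the count.
#'
#' @param region_table valid region table.
#' @param subjects metadata data.frame (one row per subject).
#' @param matrices named list of matrices, one per subject, in subject order.
#' @param ground_truth optional list describing planted effects (from the
#'   synthetic generator).
#' @return an object of class `limb_cohort`.
#' @export
new_cohort <- function(region_table, subjects, matrices, ground_truth = NULL) {
  validate_region_table(region_table)
  req <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("metadata missing required columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  if (!all(subjects$group %in% c("MDD", "HC"))) stop("group must be MDD or HC")
  if (anyNA(subjects$age) || anyNA(subjects$sex) || anyNA(subjects$group))
    stop("group, age and sex must be present for every subject")
  if (length(matrices) != nrow(subjects))
    stop("need exactly one matrix per subject")
  n <- nrow(region_table)
  matrices <- lapply(matrices, validate_matrix, n_regions = n)
  names(matrices) <- subjects$subject_id
  structure(list(region_table = region_table, subjects = subjects,
                 matrices = matrices, ground_truth = ground_truth),
            class = "limb_cohort")
}

#' @export
print.limb_cohort <- function(x, ...) {
  cat(sprintf("limb_cohort: %d subjects (%d MDD / %d HC), %d regions\n",
              nrow(x$subjects), sum(x$subjects$group == "MDD"),
              sum(x$subjects$group == "HC"), nrow(x$region_table)))
  if (!is.null(x$ground_truth)) cat("  (synthetic, ground truth attached)\n")
  invisible(x)
}

#' Read a cohort from its on-disk layout
#'
#' Matrices are plain square numeric TSV files without headers, one file per
#' subject, ordered as in the metadata table; region order is defined solely
#' by the region table file.
#'
#' @param matrix_paths character vector of per-subject matrix TSV paths, in
#'   metadata row order.
#' @param metadata_path subject metadata CSV.
#' @param region_path region table CSV.
#' @return a `limb_cohort`.
#' @export
read_cohort <- function(matrix_paths, metadata_path, region_path) {
  rt <- read.csv(region_path, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  mats <- lapply(matrix_paths, function(p)
    as.matrix(data.table::fread(p, header = FALSE, sep = "\t")))
  new_cohort(rt, meta, mats)
}

#' Write a cohort to a directory
#'
#' Emits `regions.csv`, `metadata.csv`, one `matrix_<subject_id>.tsv` per
#' subject, and (for synthetic cohorts) `ground_truth.json`.
#'
#' @param cohort a `limb_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of matrix paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$region_table, file.path(dir, "regions.csv"),
            row.names = FALSE)
  write.csv(cohort$subjects, file.path(dir, "metadata.csv"),
            row.names = FALSE)
  paths <- vapply(seq_along(cohort$matrices), function(i) {
    p <- file.path(dir, sprintf("matrix_%s.tsv", cohort$subjects$subject_id[i]))
    data.table::fwrite(as.data.frame(cohort$matrices[[i]]), p, sep = "\t",
                       col.names = FALSE)
    p
  }, character(1))
  if (!is.null(cohort$ground_truth))
    jsonlite::write_json(cohort$ground_truth,
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @return a `limb_cohort`.
#' @export
load_cohort <- function(dir) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  paths <- file.path(dir, sprintf("matrix_%s.tsv", meta$subject_id))
  co <- read_cohort(paths, file.path(dir, "metadata.csv"),
                    file.path(dir, "regions.csv"))
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path))
    co$ground_truth <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  co
}

# Extract the per-subject volume column for a region, NA-filled if absent.
region_volumes <- function(cohort, region_name) {
  col <- paste0("vol_", region_name)
  if (col %in% names(cohort$subjects)) cohort$subjects[[col]]
  else rep(NA_real_, nrow(cohort$subjects))
}

#' Write a results table to CSV
#'
#' Fixed column order with `region` and `metric` first, rows sorted by
#' `(region_index, metric)`; numeric columns round-trip losslessly at 12
#' significant digits through [read_results()].
#'
#' @param results nonempty data.frame of per-region statistics (a
#'   group-comparison or association table).
#' @param path output CSV path.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) stop("results table is empty")
  ord <- order(results$region_index,
               if ("metric" %in% names(results)) results$metric else
                 seq_len(nrow(results)))
  results <- results[ord, , drop = FALSE]
  lead <- intersect(c("region", "metric", "score"), names(results))
  results <- results[, c(lead, setdiff(names(results), lead)), drop = FALSE]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], signif, digits = 12)
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results <- function(path) read.csv(path, stringsAsFactors = FALSE)
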