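#' The default 98-region parcellation table
#'
#' Builds the region table used throughout the pipeline: 68 cortical parcels
#' (34 Desikan-Killiany parcels per hemisphere), 10 subcortical structures
#' (bilateral thalamus, caudate, putamen, pallidum, accumbens), 8 hippocampal
#' subfield groupings (CA1, CA3/4, subicular complex, GC-DG, per hemisphere)
#' and 12 amygdala nuclei (LA, BA, ABA, CoA, CeA, CAT, per hemisphere). The
#' medial nucleus is excluded (too small for reliable delineation).
#'
#' @return A data.frame with columns `region_index` (0-based, contiguous),
#'   `name`, `hemisphere` (`left`/`right`/`midline`), `category`
#'   (`cortical`/`subcortical`/`hippocampal_subfield`/`amygdala_nucleus`),
#'   `family` (`none`/`hippocampus`/`amygdala`) and `lobe`.
#' @export
#' @examples
#' rt <- default_region_table()
#' nrow(rt)                      # 98
#' table(rt$family)
default_region_table <- function() {
  dk <- c(
    bankssts = "temporal", caudalanteriorcingulate = "cingulate",
    caudalmiddlefrontal = "frontal", cuneus = "occipital",
    entorhinal = "temporal", fusiform = "temporal",
    inferiorparietal = "parietal", inferiortemporal = "temporal",
    isthmuscingulate = "cingulate", lateraloccipital = "occipital",
    lateralorbitofrontal = "frontal", lingual = "occipital",
    medialorbitofrontal = "frontal", middletemporal = "temporal",
    parahippocampal = "temporal", paracentral = "frontal",
    parsopercularis = "frontal", parsorbitalis = "frontal",
    parstriangularis = "frontal", pericalcarine = "occipital",
    postcentral = "parietal", posteriorcingulate = "cingulate",
    precentral = "frontal", precuneus = "parietal",
    rostralanteriorcingulate = "cingulate", rostralmiddlefrontal = "frontal",
    superiorfrontal = "frontal", superiorparietal = "parietal",
    superiortemporal = "temporal", supramarginal = "parietal",
    frontalpole = "frontal", temporalpole = "temporal",
    transversetemporal = "temporal", insula = "insula")
  subcort <- c("thalamus", "caudate", "putamen", "pallidum", "accumbens")
  hip <- c("CA1", "CA3_4", "subicular_complex", "GC_DG")
  amy <- c("LA", "BA", "ABA", "CoA", "CeA", "CAT")

  rows <- list()
  for (h in c("left", "right")) {
    p <- if (h == "left") "lh" else "rh"
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste(p, names(dk), sep = "_"), hemisphere = h,
      category = "cortical", family = "none", lobe = unname(dk))
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste(p, subcort, sep = "_"), hemisphere = h,
      category = "subcortical", family = "none", lobe = "subcortical")
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste(p, "hippocampus", hip, sep = "_"), hemisphere = h,
      category = "hippocampal_subfield", family = "hippocampus",
      lobe = "limbic")
    rows[[length(rows) + 1L]] <- data.frame(
      name = paste(p, "amygdala", amy, sep = "_"), hemisphere = h,
      category = "amygdala_nucleus", family = "amygdala", lobe = "limbic")
  }
  rt <- do.call(rbind, rows)
  rt <- data.frame(region_index = seq_len(nrow(rt)) - 1L, rt,
                   stringsAsFactors = FALSE)
  rownames(rt) <- NULL
  rt
}

#' Generic region table for simulated networks of arbitrary size
#'
#' Used by the synthetic-cohort generator when `n_nodes != 98`. Nodes are
#' split into a left and a right hemisphere block; all regions are generic
#' cortical parcels without a limbic family (limbic-family analyses require
#' the full [default_region_table()] parcellation).
#'
#' @param n_nodes number of regions (>= 2).
#' @return A valid region table data.frame.
#' @export
generic_region_table <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  n_left <- ceiling(n_nodes / 2)
  data.frame(
    region_index = seq_len(n_nodes) - 1L,
    name = sprintf("node_%03d", seq_len(n_nodes) - 1L),
    hemisphere = rep(c("left", "right"), c(n_left, n_nodes - n_left)),
    category = "cortical", family = "none", lobe = "generic",
    stringsAsFactors = FALSE)
}

#' Validate a region table
#'
#' Checks the structural invariants: required columns, unique contiguous
#' 0-based `region_index`, legal factor levels, and (when the table carries
#' limbic families) exactly 8 hippocampal and 12 amygdala members.
#'
#' @param rt a region table data.frame.
#' @return `rt`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_region_table <- function(rt) {
  req <- c("region_index", "name", "hemisphere", "category", "family", "lobe")
  miss <- setdiff(req, names(rt))
  if (length(miss)) stop("region table missing columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(rt)
  if (!identical(sort(as.integer(rt$region_index)), seq_len(n) - 1L))
    stop("region_index must be unique and contiguous from 0 to N-1")
  if (anyDuplicated(rt$name)) stop("duplicate region names")
  if (!all(rt$hemisphere %in% c("left", "right", "midline")))
    stop("invalid hemisphere label")
  if (!all(rt$category %in% c("cortical", "subcortical",
                              "hippocampal_subfield", "amygdala_nucleus")))
    stop("invalid category label")
  if (!all(rt$family %in% c("none", "hippocampus", "amygdala")))
    stop("invalid family label")
  n_hip <- sum(rt$family == "hippocampus")
  n_amy <- sum(rt$family == "amygdala")
  if (n_hip > 0 && n_hip != 8L)
    stop("hippocampus family must have exactly 8 members, found ", n_hip)
  if (n_amy > 0 && n_amy != 12L)
    stop("amygdala family must have exactly 12 members, found ", n_amy)
  invisible(rt)
}
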