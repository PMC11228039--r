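#' Controlled vocabularies for the Visual-Hippocampal pathway analysis
#'
#' `vh_regions()` returns the five pathway regions in anatomical order
#' (occipital visual cortex to hippocampus). `stage_levels()` returns the
#' four ordered disease-severity labels of one of the two supported cohort
#' dialects: `"gse84422"` (Normal / Possible AD / Probable AD / Definite AD)
#' or `"gse1297"` (Control / Incipient / Moderate / Severe).
#' `hemoglobin_genes()` returns the three hemoglobin-subunit gene symbols
#' whose per-sample expression triple forms the hemoglobin expression vector.
#'
#' @param dialect Which staging vocabulary, `"gse84422"` or `"gse1297"`.
#' @return A character vector of labels.
#' @examples
#' vh_regions()
#' stage_levels("gse1297")
#' @export
vh_regions <- function() c("OVC", "MTG", "ITG", "PHG", "HC")

#' @rdname vh_regions
#' @export
stage_levels <- function(dialect = c("gse84422", "gse1297")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    gse84422 = c("Normal", "Possible AD", "Probable AD", "Definite AD"),
    gse1297  = c("Control", "Incipient", "Moderate", "Severe")
  )
}

#' @rdname vh_regions
#' @export
hemoglobin_genes <- function() c("HBB", "HBA1", "HBA2")

#' Adjacent region pairs of the Visual-Hippocampal pathway
#'
#' The pathway carries visual information from the occipital visual cortex
#' to the hippocampus along a dorsal stream (via MTG) and a ventral stream
#' (via ITG); coordination statistics are computed along its five edges:
#' OVC-MTG, OVC-ITG, MTG-PHG, ITG-PHG, PHG-HC.
#'
#' @return A tibble with columns `region_a`, `region_b`, one row per edge.
#' @examples
#' pathway_edges()
#' @export
pathway_edges <- function() {
  tibble::tibble(
    region_a = c("OVC", "OVC", "MTG", "ITG", "PHG"),
    region_b = c("MTG", "ITG", "PHG", "PHG", "HC")
  )
}

# --- expression-table helpers -------------------------------------------

# An expression table is a tibble whose first column is `gene_id` and whose
# remaining columns are numeric sample columns; the measurement scale
# ("raw", "log2" or "standardized") rides along as an attribute so that
# transforms that are only valid on one scale can refuse the wrong input.

#' Tag or query the measurement scale of an expression table
#'
#' @param expr An expression tibble (`gene_id` column plus sample columns).
#' @param scale One of `"raw"`, `"log2"`, `"standardized"`.
#' @return `set_expr_scale()` returns `expr` with the scale recorded;
#'   `expr_scale()` returns the recorded scale (or `NA` if untagged).
#' @examples
#' tbl <- tibble::tibble(gene_id = "HBB", s1 = 7, s2 = 7.5)
#' tbl <- set_expr_scale(tbl, "log2")
#' expr_scale(tbl)
#' @export
set_expr_scale <- function(expr, scale = c("raw", "log2", "standardized")) {
  scale <- match.arg(scale)
  check_expr(expr)
  attr(expr, "expr_scale") <- scale
  expr
}

#' @rdname set_expr_scale
#' @export
expr_scale <- function(expr) {
  attr(expr, "expr_scale") %||% NA_character_
}

check_expr <- function(expr, call = rlang::caller_env()) {
  if (!is.data.frame(expr) || !identical(names(expr)[1], "gene_id")) {
    abort("`expr` must be a data frame whose first column is `gene_id`.",
          call = call)
  }
  if (ncol(expr) < 2L) {
    abort("`expr` has no sample columns.", call = call)
  }
  invisible(expr)
}

expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

expr_from_values <- function(values, scale) {
  out <- tibble::as_tibble(as.data.frame(values))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)), out)
  set_expr_scale(out, scale)
}

sample_ids <- function(expr) names(expr)[-1]

check_alignment <- function(expr, annot, call = rlang::caller_env()) {
  if (!identical(sample_ids(expr), annot$sample_id)) {
    abort(paste0(
      "Expression columns and annotation rows are not aligned: ",
      "matrix has ", ncol(expr) - 1L, " samples, annotation has ",
      nrow(annot), " rows, or the identifiers differ in order."
    ), call = call)
  }
  invisible(TRUE)
}

# Deterministic per-stream seeds derived from one global seed; kept inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + 104729 * stream) %% 2147483647)
}
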