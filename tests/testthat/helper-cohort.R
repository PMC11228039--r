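# Small deterministic cohorts used across test files.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_stage = 5, n_background_genes = 10, seed = 42),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Expression tibble built by hand: genes x named sample values.
make_expr <- function(values, scale = "log2") {
  tbl <- tibble::as_tibble(as.data.frame(values))
  tbl <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(values)), tbl)
  set_expr_scale(tbl, scale)
}

make_annot <- function(expr, region = "HC", stage = "Normal", nft = 1,
                       subject_id = NULL) {
  ids <- names(expr)[-1]
  n <- length(ids)
  tibble::tibble(
    sample_id = ids,
    subject_id = subject_id %||% paste0("SUBJ", seq_len(n)),
    region = rep_len(region, n),
    stage = rep_len(stage, n),
    NFT = rep_len(nft, n),
    Braak = NA_real_, CDR = NA_real_, MMSE = NA_real_
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
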