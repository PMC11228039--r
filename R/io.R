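#' Write a cohort to disk
#'
#' Writes the expression matrix and sample annotation either as a
#' round-trippable TSV pair (`<prefix>_expression.tsv`,
#' `<prefix>_annotation.tsv`) or as a single GEO series-matrix-style file
#' (`<prefix>_series_matrix.txt`: "!"-prefixed metadata lines carrying the
#' sample characteristics, then the expression table between
#' `!series_matrix_table_begin` / `!series_matrix_table_end`).
#'
#' @param expr Expression tibble (`gene_id` plus sample columns), or a
#'   `"hemo_cohort"` in which case `annot` is taken from it.
#' @param annot Sample annotation tibble aligned with `expr`'s columns.
#' @param prefix Output path prefix (directories must exist).
#' @param dialect `"tsv"` or `"geo"`.
#' @return Invisibly, the paths written.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(expr, annot = NULL, prefix,
                         dialect = c("tsv", "geo")) {
  dialect <- match.arg(dialect)
  if (inherits(expr, "hemo_cohort")) {
    annot <- expr$annot
    expr <- expr$expr
  }
  check_expr(expr)
  check_alignment(expr, annot)

  if (dialect == "tsv") {
    paths <- paste0(prefix, c("_expression.tsv", "_annotation.tsv"))
    readr::write_tsv(expr, paths[1])
    readr::write_tsv(annot, paths[2])
  } else {
    paths <- paste0(prefix, "_series_matrix.txt")
    con <- file(paths, open = "wt")
    on.exit(close(con))
    meta_fields <- setdiff(names(annot), "sample_id")
    writeLines(sprintf("!Series_title\t\"synthetic multi-region cohort\""), con)
    for (f in meta_fields) {
      vals <- annot[[f]]
      vals <- if (is.numeric(vals)) sprintf("%.17g", vals) else as.character(vals)
      vals[is.na(annot[[f]])] <- "NA"
      writeLines(paste0("!Sample_characteristics_ch1\t",
                        paste0("\"", f, ": ", vals, "\"", collapse = "\t")),
                 con)
    }
    writeLines("!series_matrix_table_begin", con)
    tab <- expr
    names(tab)[1] <- "ID_REF"
    cat(readr::format_tsv(tab), file = con, sep = "")
    writeLines("!series_matrix_table_end", con)
  }
  invisible(paths)
}

# Base-R TSV parser: strtod is correctly rounded, so doubles written with a
# shortest-round-trip representation come back bit-identical.
read_tsv_exact <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE))
}

#' Read a cohort from disk
#'
#' Reads what [write_cohort()] writes: a TSV pair, or a GEO
#' series-matrix-style file in which "!"-prefixed metadata lines are parsed
#' for `Sample_characteristics` fields (`"key: value"`) and the expression
#' table is taken from the `!series_matrix_table_begin` block. A plain
#' series-matrix file without characteristics lines yields an annotation
#' with sample identifiers only.
#'
#' @param prefix Path prefix used when writing (or the series-matrix file
#'   path itself for `dialect = "geo"`).
#' @param dialect `"tsv"` or `"geo"`.
#' @param scale Measurement scale to tag on the expression table.
#' @return A list of class `"hemo_cohort"` with `expr` and `annot`.
#' @export
read_cohort <- function(prefix, dialect = c("tsv", "geo"), scale = "log2") {
  dialect <- match.arg(dialect)

  if (dialect == "tsv") {
    paths <- paste0(prefix, c("_expression.tsv", "_annotation.tsv"))
    if (!all(file.exists(paths))) {
      abort(paste0("Missing cohort files: ",
                   paste(paths[!file.exists(paths)], collapse = ", ")))
    }
    expr <- read_tsv_exact(paths[1])
    names(expr)[1] <- "gene_id"
    annot <- readr::read_tsv(paths[2], show_col_types = FALSE)
    annot$NFT <- read_tsv_exact(paths[2])$NFT  # bit-exact doubles
  } else {
    path <- if (file.exists(prefix)) prefix else paste0(prefix, "_series_matrix.txt")
    if (!file.exists(path)) abort(paste0("File not found: ", path))
    lines <- readLines(path)
    meta <- lines[startsWith(lines, "!")]
    tb <- which(lines == "!series_matrix_table_begin")
    te <- which(lines == "!series_matrix_table_end")
    if (length(tb) != 1 || length(te) != 1 || te <= tb + 1) {
      abort("No series-matrix table block found.")
    }
    expr <- read_tsv_exact(textConnection(lines[(tb + 1):(te - 1)]))
    names(expr)[1] <- "gene_id"
    annot <- tibble::tibble(sample_id = names(expr)[-1])
    char_lines <- meta[startsWith(meta, "!Sample_characteristics_ch1")]
    for (ln in char_lines) {
      fields <- strsplit(sub("^!Sample_characteristics_ch1\t", "", ln), "\t")[[1]]
      fields <- gsub("^\"|\"$", "", fields)
      key <- unique(sub(":.*$", "", fields))
      if (length(key) != 1) next
      vals <- sub("^[^:]*: ?", "", fields)
      if (length(vals) != nrow(annot)) next
      num <- suppressWarnings(as.numeric(vals))
      annot[[key]] <- if (all(is.na(num) == (vals == "NA"))) num else vals
    }
  }

  expr <- set_expr_scale(expr, scale)
  if (!identical(sample_ids(expr), annot$sample_id)) {
    abort("Expression sample columns and annotation sample_id do not match.")
  }
  structure(list(expr = expr, annot = annot), class = "hemo_cohort")
}
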