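# Tab-delimited dialects used throughout: UTF-8, no quoting, no missing
# values. Expression/signature tables put gene symbols in a first column
# headed "GeneSymbol"; numbers are written with format(..., digits = 15)
# so that write(read(x)) reproduces a file byte for byte.

fmt_num <- function(x) format(x, digits = 15, trim = TRUE,
                              scientific = FALSE)

check_file <- function(path) {
  if (!file.exists(path)) stop(path, ": no such file")
  invisible(path)
}

write_tsv_frame <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

#' Write a genes-by-samples expression table
#'
#' Tab-delimited, header `GeneSymbol` then sample/type ids, one row per
#' gene; the dialect shared by expression, mixture and signature tables.
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @param id_col header of the first column.
#' @export
write_expression_tsv <- function(mat, path, id_col = "GeneSymbol") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_frame(df, path)
}

#' Read a genes-by-samples expression table
#'
#' @param path tab-delimited file written by [write_expression_tsv()].
#' @param id_col expected header of the first column.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path, id_col = "GeneSymbol") {
  check_file(path)
  first <- readLines(path, n = 1)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2 || fields[1] != id_col)
    stop(path, ": line 1: expected a tab-delimited header starting with '",
         id_col, "'")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop(path, ": non-numeric or missing expression values")
  rownames(m) <- df[[1]]
  m
}

#' Write a signature matrix as TSV
#' @param signature a `signature_matrix` or plain genes x types matrix.
#' @param path output file.
#' @export
write_signature_tsv <- function(signature, path) {
  mat <- if (inherits(signature, "signature_matrix")) signature$expr
         else signature
  write_expression_tsv(mat, path)
}

#' Read a signature matrix TSV
#' @param path file written by [write_signature_tsv()].
#' @return a `signature_matrix` (mode and condition number recomputed
#'   from the file contents; mode is recorded as written if present).
#' @export
read_signature_tsv <- function(path) {
  expr <- read_expression_tsv(path)
  structure(list(expr = expr, mode = NA_character_,
                 condition_number = kappa2(expr), g = NA_integer_,
                 markers_by_type = NULL),
            class = "signature_matrix")
}

#' Write estimated fractions (samples x types)
#' @param fractions samples x types matrix, e.g. `coef()` of a
#'   `deconv_fit`.
#' @param path output file.
#' @export
write_fractions_tsv <- function(fractions, path) {
  df <- data.frame(Sample = rownames(fractions), fractions,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_frame(df, path)
}

#' Read a fractions table
#' @param path file written by [write_fractions_tsv()].
#' @return samples x types numeric matrix.
#' @export
read_fractions_tsv <- function(path) {
  check_file(path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "Sample")
    stop(path, ": line 1: expected header starting with 'Sample'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a survival table (sample_id, time, event)
#' @param surv data.frame with sample_id, time, event.
#' @param path output file.
#' @export
write_survival_tsv <- function(surv, path) {
  surv$event <- as.integer(as.logical(surv$event))
  write_tsv_frame(surv, path)
}

#' Read a survival table
#' @param path tab-delimited file with columns sample_id, time, event
#'   (0/1); an optional `unit` column (days/months/years) is converted to
#'   months.
#' @return data.frame with sample_id, time (months), event (logical).
#' @export
read_survival_tsv <- function(path) {
  check_file(path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop(path, ": line 1: expected columns ", paste(need, collapse = ", "))
  if ("unit" %in% names(df)) {
    df$time <- mapply(to_months, df$time, df$unit)
    df$unit <- NULL
  }
  df$event <- as.logical(as.integer(df$event))
  df[, need]
}

#' Write a cell-type tree (child TAB parent per line, no header)
#' @param tree data.frame with columns child, parent.
#' @param path output file.
#' @export
write_tree_tsv <- function(tree, path) {
  writeLines(paste(tree$child, tree$parent, sep = "\t"), path)
}

#' Read a cell-type tree file
#' @param path child TAB parent per line, no header.
#' @return data.frame with columns child, parent.
#' @export
read_tree_tsv <- function(path) {
  check_file(path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2)
    stop(path, ": line 1: expected two tab-separated columns ",
         "(child, parent)")
  names(df) <- c("child", "parent")
  df
}

#' Write an atlas as a TSV bundle
#'
#' Writes `<prefix>_expr.tsv` (dense expression),
#' `<prefix>_annotation.tsv` (cell_id, type_label) and
#' `<prefix>_tree.tsv` (child TAB parent).
#'
#' @param atlas a `tme_atlas`.
#' @param prefix path prefix for the three files.
#' @return the three file paths, invisibly.
#' @export
write_atlas <- function(atlas, prefix) {
  paths <- paste0(prefix, c("_expr.tsv", "_annotation.tsv", "_tree.tsv"))
  write_expression_tsv(atlas$expr, paths[1])
  write_tsv_frame(data.frame(cell_id = colnames(atlas$expr),
                             type_label = unname(atlas$labels),
                             stringsAsFactors = FALSE), paths[2])
  write_tree_tsv(atlas$tree, paths[3])
  invisible(paths)
}

#' Read an atlas from a TSV bundle or sparse MTX triplet
#'
#' Dense form: the three files written by [write_atlas()]. Sparse form:
#' pass `mtx`, `genes` and `barcodes` files instead of the expression
#' TSV; the annotation and tree files are shared between forms.
#'
#' @param prefix prefix of a dense bundle (ignored when `mtx` is given).
#' @param mtx,genes,barcodes MatrixMarket triplet plus one-symbol-per-line
#'   gene file and one-id-per-line barcode file.
#' @param annotation,tree override the annotation / tree paths.
#' @return a `tme_atlas`.
#' @export
read_atlas <- function(prefix = NULL, mtx = NULL, genes = NULL,
                       barcodes = NULL, annotation = NULL, tree = NULL) {
  if (is.null(mtx)) {
    stopifnot(!is.null(prefix))
    expr <- read_expression_tsv(paste0(prefix, "_expr.tsv"))
    annotation <- annotation %||% paste0(prefix, "_annotation.tsv")
    tree <- tree %||% paste0(prefix, "_tree.tsv")
  } else {
    stopifnot(!is.null(genes), !is.null(barcodes), !is.null(annotation),
              !is.null(tree))
    expr <- as.matrix(Matrix::readMM(mtx))
    rownames(expr) <- readLines(genes)
    colnames(expr) <- readLines(barcodes)
  }
  ann <- read.delim(annotation, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "type_label") %in% names(ann)))
    stop(annotation, ": line 1: expected columns cell_id, type_label")
  labels <- setNames(ann$type_label, ann$cell_id)
  new_atlas(expr, labels, read_tree_tsv(tree))
}

#' Write a sparse atlas expression matrix as an MTX triplet
#' @param atlas a `tme_atlas`.
#' @param mtx,genes,barcodes output paths.
#' @export
write_atlas_mtx <- function(atlas, mtx, genes, barcodes) {
  Matrix::writeMM(Matrix::Matrix(atlas$expr, sparse = TRUE), mtx)
  writeLines(rownames(atlas$expr), genes)
  writeLines(colnames(atlas$expr), barcodes)
  invisible(c(mtx, genes, barcodes))
}

#' Write a split report and Kaplan–Meier coordinates
#'
#' Writes `<prefix>_split.tsv` (strategy, cut rank, p-value, group
#' sizes) and `<prefix>_km_<group>.tsv` coordinate tables (time,
#' survival, at-risk) for external plotting.
#'
#' @param split a `split_result`.
#' @param cohort the cohort the split was computed on.
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
write_split_report <- function(split, cohort, prefix) {
  paths <- paste0(prefix, "_split.tsv")
  rep_df <- data.frame(strategy = split$strategy,
                       cut_rank = split$cut_rank,
                       p_value = split$p_value,
                       n_high = split$cut_rank,
                       n_low = split$n - split$cut_rank,
                       small_group = split$small_group,
                       stringsAsFactors = FALSE)
  write_tsv_frame(rep_df, paths)
  grp <- split$group_assignment[as.character(cohort$sample_id)]
  for (g in c("high", "low")) {
    km <- km_curve(cohort[grp == g, , drop = FALSE])
    p <- paste0(prefix, "_km_", g, ".tsv")
    write_tsv_frame(km, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
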