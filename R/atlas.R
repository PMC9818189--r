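#' Construct an annotated single-cell atlas
#'
#' An atlas bundles a genes-by-cells expression matrix with per-cell type
#' labels and a cell-type tree. The tree encodes subtype structure (e.g.
#' inflammatory and non-inflammatory macrophages under a macrophage parent)
#' and is what [collapse_tree()] operates on.
#'
#' @param expr numeric genes x cells matrix, non-negative, with unique
#'   rownames (gene symbols) and colnames (cell ids).
#' @param labels character vector of cell-type labels, one per cell
#'   (column of `expr`), or named by cell id.
#' @param tree data.frame with columns `child`, `parent`; leaves must be
#'   exactly the labels in use. `NULL` builds the trivial tree
#'   (root -> each label).
#' @param markers optional named list, type -> character vector of marker
#'   gene symbols (carried as metadata, e.g. planted ground truth from
#'   [simulate_atlas()]).
#' @return An object of class `tme_atlas`: a list with elements `expr`,
#'   `labels`, `tree`, `markers`.
#' @export
new_atlas <- function(expr, labels, tree = NULL, markers = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` must have rownames (genes) and colnames (cells)")
  if (anyDuplicated(rownames(expr)))
    stop("gene ids must be unique; run collapse_duplicates() first")
  if (min(expr) < 0) stop("expression matrix has negative entries")
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  if (length(labels) != ncol(expr) || anyNA(labels))
    stop("`labels` must cover every cell of the atlas")
  labels <- as.character(labels)
  names(labels) <- colnames(expr)
  if (is.null(tree)) {
    tree <- data.frame(child = sort(unique(labels)), parent = "root",
                       stringsAsFactors = FALSE)
  }
  tree <- as.data.frame(tree, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(tree)))
    stop("`tree` needs columns child and parent")
  lv <- tree_leaves(tree)
  missing <- setdiff(unique(labels), lv)
  if (length(missing))
    stop("labels not present as tree leaves: ", paste(missing, collapse = ", "))
  structure(list(expr = expr, labels = labels, tree = tree, markers = markers),
            class = "tme_atlas")
}

tree_leaves <- function(tree) setdiff(tree$child, tree$parent)

#' @export
print.tme_atlas <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("tme_atlas: %d genes x %d cells, %d cell types\n",
              nrow(x$expr), ncol(x$expr), length(tab)))
  cat("types:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cell-type labels of an atlas
#' @param atlas a `tme_atlas`.
#' @return character vector of unique leaf-type labels, sorted.
#' @export
atlas_types <- function(atlas) sort(unique(atlas$labels))

#' Per-type mean expression profiles
#'
#' Column-wise mean of the expression matrix within each cell type; the
#' genes x types matrix that collapsed ("bulk-mode") references and the
#' synthetic bulk mixer are built from.
#'
#' @param atlas a `tme_atlas`.
#' @return numeric genes x types matrix.
#' @export
type_profiles <- function(atlas) {
  types <- atlas_types(atlas)
  out <- vapply(types, function(t)
    rowMeans(atlas$expr[, atlas$labels == t, drop = FALSE]),
    numeric(nrow(atlas$expr)))
  dimnames(out) <- list(rownames(atlas$expr), types)
  out
}

#' Depth-normalise counts to a fixed total per cell
#'
#' Rescales every cell (column) so that it sums to `target` counts
#' (default 10,000), preserving within-cell relative gene proportions.
#' Idempotent.
#'
#' @param x a genes x cells matrix or a `tme_atlas`.
#' @param target positive total count per cell after scaling.
#' @return object of the same class as `x`.
#' @export
normalize_counts <- function(x, target = 10000) UseMethod("normalize_counts")

#' @export
normalize_counts.matrix <- function(x, target = 10000) {
  stopifnot(target > 0)
  cs <- colSums(x)
  if (any(cs <= 0)) {
    bad <- colnames(x)[cs <= 0] %||% which(cs <= 0)
    stop("cell(s) with zero total counts: ", paste(bad[1:min(5, length(bad))],
         collapse = ", "))
  }
  sweep(x, 2, cs / target, "/")
}

#' @export
normalize_counts.tme_atlas <- function(x, target = 10000) {
  x$expr <- normalize_counts(x$expr, target)
  x
}

#' Rename expression rows to harmonised gene symbols
#'
#' Translates row identifiers (probe or Ensembl ids) to gene symbols via a
#' precomputed two-column mapping. Rows without a mapping are dropped and
#' the drop count reported via a message and the `"n_dropped"` attribute.
#' Many-to-one mappings produce duplicated symbols on purpose; resolve
#' them afterwards with [collapse_duplicates()].
#'
#' @param matrix genes x samples numeric matrix with rownames.
#' @param id_map data.frame (or 2-column matrix) mapping old id -> symbol.
#' @param uppercase match ids case-insensitively by uppercasing both sides
#'   (default FALSE: exact, case-sensitive).
#' @return the renamed matrix (possibly with duplicated rownames), with
#'   attribute `n_dropped`.
#' @export
map_genes <- function(matrix, id_map, uppercase = FALSE) {
  id_map <- as.data.frame(id_map, stringsAsFactors = FALSE)
  if (ncol(id_map) < 2) stop("`id_map` must have two columns: old id, symbol")
  old <- as.character(id_map[[1]]); new <- as.character(id_map[[2]])
  ids <- rownames(matrix)
  if (uppercase) { old <- toupper(old); ids <- toupper(ids) }
  idx <- match(ids, old)
  if (all(is.na(idx)))
    stop("no row ids of the matrix occur in the id map (",
         nrow(matrix), " matrix rows vs ", length(old), " map entries)")
  keep <- !is.na(idx)
  n_dropped <- sum(!keep)
  out <- matrix[keep, , drop = FALSE]
  rownames(out) <- new[idx[keep]]
  if (n_dropped > 0)
    message("map_genes: dropped ", n_dropped, " unmapped row(s)")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Collapse duplicated gene rows
#'
#' Resolves duplicated row symbols either by keeping the single row with
#' the largest mean (`maxmean`, the convention for microarray probes) or
#' by element-wise summation (`sum`, the convention for RNA-seq features).
#' MaxMean ties keep the first-occurring row.
#'
#' @param matrix genes x samples numeric matrix with rownames.
#' @param strategy `"maxmean"` or `"sum"`.
#' @return matrix with unique rownames, row order of first occurrence.
#' @export
collapse_duplicates <- function(matrix, strategy = c("maxmean", "sum")) {
  strategy <- tryCatch(match.arg(strategy), error = function(e)
    stop("unknown strategy; valid strategies: maxmean, sum"))
  ids <- rownames(matrix)
  if (is.null(ids)) stop("matrix must have rownames")
  if (!anyDuplicated(ids)) return(matrix)
  first <- !duplicated(ids)
  if (strategy == "sum") {
    out <- rowsum(matrix, group = ids, reorder = FALSE)
    # rowsum orders groups by first occurrence when reorder = FALSE
    return(out[ids[first], , drop = FALSE])
  }
  rm_all <- rowMeans(matrix)
  pick <- vapply(split(seq_along(ids), factor(ids, levels = ids[first])),
                 function(ix) ix[which.max(rm_all[ix])], integer(1))
  out <- matrix[pick, , drop = FALSE]
  rownames(out) <- ids[first]
  out
}

#' Merge cell subtypes along the type tree
#'
#' Relabels cells according to `merge_map` (subtype -> merged type) and
#' updates the type tree so the merged types become leaves, e.g.
#' macrophage = inflammatory macrophage + non-inflammatory macrophage.
#' Expression values are untouched, so total expression mass is conserved.
#'
#' @param atlas a `tme_atlas`.
#' @param merge_map named character vector or list: names are existing
#'   subtype labels, values the merged type they map to.
#' @return the relabelled `tme_atlas`.
#' @export
collapse_tree <- function(atlas, merge_map) {
  merge_map <- unlist(merge_map)
  keys <- names(merge_map)
  if (is.null(keys) || any(keys == ""))
    stop("`merge_map` must be named: subtype -> merged type")
  absent <- setdiff(keys, unique(atlas$labels))
  if (length(absent))
    stop("merge_map key(s) not atlas labels: ", paste(absent, collapse = ", "))
  labels <- atlas$labels
  hit <- labels %in% keys
  labels[hit] <- unname(merge_map[labels[hit]])
  tree <- atlas$tree
  # parent lookup before edges are removed, for merged types new to the tree
  parent_of <- setNames(tree$parent, tree$child)
  tree <- tree[!(tree$child %in% keys), , drop = FALSE]
  for (m in unique(unname(merge_map))) {
    if (!(m %in% tree$child) && !(m %in% tree$parent)) {
      k1 <- keys[merge_map == m][1]
      tree <- rbind(tree, data.frame(child = m,
                                     parent = unname(parent_of[k1]),
                                     stringsAsFactors = FALSE))
    }
  }
  # prune leaves that no longer carry cells (e.g. fully-merged orphans)
  repeat {
    lv <- tree_leaves(tree)
    dead <- setdiff(lv, unique(labels))
    if (!length(dead)) break
    tree <- tree[!(tree$child %in% dead), , drop = FALSE]
  }
  markers <- atlas$markers
  if (!is.null(markers)) {
    for (m in unique(unname(merge_map))) {
      ks <- keys[merge_map == m]
      merged <- unique(unlist(markers[c(m, ks)]))
      markers[ks] <- NULL
      markers[[m]] <- merged
    }
  }
  new_atlas(atlas$expr, labels, tree, markers)
}
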