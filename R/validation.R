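#' Generate one pseudo-bulk mixture with a preset proportion
#'
#' Splits the atlas cells into the target type and an "others" group
#' (all remaining types collapsed), subsamples a fraction `cell_frac` of
#' each group without replacement, averages each subsample per gene into
#' representative vectors `V_celltype` and `V_others`, and mixes them as
#'
#'   `expr = V_celltype * f + V_others * (100 - f)`
#'
#' with `f` on the 0–100 scale. Uses the current RNG state; seed the
#' session (or use [run_validation()]) for reproducibility.
#'
#' @param atlas a `tme_atlas` (normalise first for comparability with a
#'   signature built from the same atlas).
#' @param target_type label of the cell type of interest.
#' @param f preset proportion in `[0, 100]`.
#' @param cell_frac fraction of cells subsampled per group (default 0.10).
#' @return list of class `mixture_sample`: `expr` (per-gene vector),
#'   `true_f`, `target_type`.
#' @export
make_pseudobulk <- function(atlas, target_type, f, cell_frac = 0.10) {
  stopifnot(inherits(atlas, "tme_atlas"))
  if (!(target_type %in% atlas$labels))
    stop("unknown target_type '", target_type, "'; available: ",
         paste(atlas_types(atlas), collapse = ", "))
  if (f < 0 || f > 100) stop("f must be in [0, 100]")
  in_t <- which(atlas$labels == target_type)
  in_o <- which(atlas$labels != target_type)
  if (!length(in_o)) stop("the 'others' group is empty")
  n_t <- floor(cell_frac * length(in_t))
  n_o <- floor(cell_frac * length(in_o))
  if (n_t == 0 || n_o == 0)
    stop("subsample of size 0 at cell_frac = ", cell_frac,
         "; increase cell_frac")
  v_t <- rowMeans(atlas$expr[, sample(in_t, n_t), drop = FALSE])
  v_o <- rowMeans(atlas$expr[, sample(in_o, n_o), drop = FALSE])
  structure(list(expr = v_t * f + v_o * (100 - f), true_f = f,
                 target_type = target_type),
            class = "mixture_sample")
}

#' Benchmark metrics for proportion estimates
#'
#' Pearson correlation, mean absolute error and mean signed error
#' (positive = overestimation) between preset proportions `f` and
#' estimates `f_hat`, both on the 0–100 scale.
#'
#' @param f preset proportions.
#' @param f_hat estimated proportions.
#' @return list with `pcc`, `mae`, `mean_signed_error`, `n`.
#' @export
validation_metrics <- function(f, f_hat) {
  stopifnot(length(f) == length(f_hat))
  n <- length(f)
  list(pcc = if (n >= 2) safe_cor(f, f_hat) else NA_real_,
       mae = mean(abs(f_hat - f)),
       mean_signed_error = mean(f_hat - f),
       n = n)
}

#' Score the deconvolution engine on pseudo-bulk mixtures
#'
#' Generates `n_mixtures` pseudo-bulk samples for one target type with
#' independent uniform `f` in `[0, 100]`, estimates fractions with a
#' signature built from the reference atlas, and scores the estimated
#' `f' = 100 * fraction(target_type)` against the preset `f`. In
#' `"intra"` mode the signature and the mixtures come from the same
#' atlas (full type coverage); in `"cross"` mode they come from different
#' atlases, exercising partial deconvolution.
#'
#' @param ref_atlas atlas providing the signature.
#' @param test_atlas atlas providing the mixtures (defaults to
#'   `ref_atlas`, i.e. intra mode).
#' @param target_type cell-type label scored.
#' @param n_mixtures number of pseudo-bulk samples.
#' @param mode `"intra"` or `"cross"`.
#' @param method deconvolution engine, see [deconvolute()].
#' @param signature optional precomputed [build_signature()] result for
#'   `ref_atlas`, to reuse across target types.
#' @param cell_frac per-group subsampling fraction, see
#'   [make_pseudobulk()].
#' @param seed optional seed for the mixture draws.
#' @param ... further arguments to [build_signature()].
#' @return list of class `validation_result`: `target_type`, `mode`,
#'   `n`, `pcc`, `mae`, `mean_signed_error`, plus the raw `f` and
#'   `f_hat` vectors for audit.
#' @export
run_validation <- function(ref_atlas, test_atlas = ref_atlas, target_type,
                           n_mixtures = 50, mode = c("intra", "cross"),
                           method = "nu-svr", signature = NULL,
                           cell_frac = 0.10, seed = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "cross") {
    shared <- intersect(atlas_types(ref_atlas), atlas_types(test_atlas))
    if (!(target_type %in% shared))
      stop("target_type '", target_type, "' must be present in both ",
           "atlases; shared labels: ", paste(shared, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  ref_atlas <- normalize_counts(ref_atlas)
  test_atlas <- normalize_counts(test_atlas)
  if (is.null(signature)) signature <- build_signature(ref_atlas, ...)
  if (!(target_type %in% colnames(signature$expr)))
    stop("target_type '", target_type, "' is not a signature column")
  f <- runif(n_mixtures, 0, 100)
  mixes <- vapply(f, function(fi)
    make_pseudobulk(test_atlas, target_type, fi, cell_frac)$expr,
    numeric(nrow(test_atlas$expr)))
  colnames(mixes) <- sprintf("mix_%03d", seq_len(n_mixtures))
  est <- deconvolute(signature, mixes, method = method)
  f_hat <- 100 * est$fractions[, target_type]
  m <- validation_metrics(f, f_hat)
  structure(list(target_type = target_type, mode = mode, n = n_mixtures,
                 pcc = m$pcc, mae = m$mae,
                 mean_signed_error = m$mean_signed_error,
                 f = f, f_hat = unname(f_hat), method = method),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(
    "validation (%s, %s, n=%d) %s: PCC %.4f, MAE %.2f, signed error %+.2f\n",
    x$mode, x$method, x$n, x$target_type, x$pcc, x$mae,
    x$mean_signed_error))
  invisible(x)
}

#' Combine validation results into a report table
#' @param results list of `validation_result` objects.
#' @return data.frame, one row per result.
#' @export
validation_report <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(target_type = r$target_type, mode = r$mode, n = r$n,
               pcc = r$pcc, mae = r$mae,
               mean_signed_error = r$mean_signed_error,
               stringsAsFactors = FALSE)))
}
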