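# Vectorised one-vs-rest Wilcoxon rank-sum across all genes.
# Normal approximation with tie correction, no continuity correction;
# equivalent to stats::wilcox.test(exact = FALSE, correct = FALSE) per gene
# but computed from one shared rank matrix, which is what makes
# atlas-scale marker testing feasible.
ovr_wilcoxon <- function(expr, labels) {
  n_genes <- nrow(expr)
  N <- ncol(expr)
  ranks <- matrix(0, n_genes, N)
  tie_term <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    r <- rank(expr[g, ])
    ranks[g, ] <- r
    tab <- table(r)
    tab <- tab[tab > 1]
    tie_term[g] <- sum(tab^3 - tab)
  }
  types <- sort(unique(labels))
  p <- matrix(NA_real_, n_genes, length(types),
              dimnames = list(rownames(expr), types))
  lfc <- p
  for (tp in types) {
    in_grp <- labels == tp
    n1 <- sum(in_grp); n2 <- N - n1
    U <- rowSums(ranks[, in_grp, drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    z <- (U - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
    p[, tp] <- 2 * pnorm(-abs(z))
    m_in <- rowMeans(expr[, in_grp, drop = FALSE])
    m_out <- rowMeans(expr[, !in_grp, drop = FALSE])
    lfc[, tp] <- log2((m_in + 1) / (m_out + 1))
  }
  list(p = p, lfc = lfc)
}

kappa2 <- function(x) {
  d <- svd(x, nu = 0, nv = 0)$d
  d <- d[d > d[1] * .Machine$double.eps]
  if (length(d) < ncol(x)) return(Inf)
  d[1] / d[length(d)]
}

#' Build a signature matrix from an annotated atlas
#'
#' Selects cell-type marker genes and returns per-type reference profiles
#' over the selected set — the design matrix for [deconvolute()].
#'
#' In `"S"` (single-cell) mode, each gene is tested per type with a
#' one-vs-rest Wilcoxon rank-sum test across cells; genes with
#' Benjamini–Hochberg q below `q_max` become candidate markers for the
#' type where their log fold change is largest. In `"B"` (bulk-collapsed)
#' mode the matrix is first collapsed to per-type mean profiles over all
#' genes and candidates are ranked by the fold change of those collapsed
#' profiles (top type vs the mean of the rest, `min_fc` threshold) — the
#' variant used when the reference must mimic a bulk profile.
#'
#' In both modes, per-type candidates are ranked by log fold change and
#' the number of markers per type `G` is swept over `g_range`; the `G`
#' minimising the 2-norm condition number of the resulting signature is
#' kept, so the reference stays well conditioned for regression.
#' Profiles are arithmetic means of depth-normalised expression.
#'
#' @param atlas a `tme_atlas` with at least two leaf types.
#' @param mode `"S"` (test on cells) or `"B"` (test on collapsed
#'   profiles).
#' @param q_max BH-adjusted significance threshold qualifying a candidate
#'   marker (S mode).
#' @param g_range integer vector of markers-per-type values swept for
#'   condition-number minimisation (clipped per type to the candidates
#'   available).
#' @param min_cells minimum cells required per type.
#' @param min_fc minimum collapsed-profile fold change qualifying a B-mode
#'   candidate.
#' @param normalize depth-normalise the atlas to `target` counts per cell
#'   first (idempotent; keep TRUE unless already normalised).
#' @param target normalisation target, counts per cell.
#' @return object of class `signature_matrix`: list with `expr`
#'   (marker genes x types), `mode`, `condition_number`, `g` (chosen
#'   markers per type) and `markers_by_type`.
#' @export
build_signature <- function(atlas, mode = c("S", "B"), q_max = 0.3,
                            g_range = 50:150, min_cells = 20,
                            min_fc = 2, normalize = TRUE, target = 10000) {
  mode <- match.arg(mode)
  stopifnot(inherits(atlas, "tme_atlas"))
  types <- atlas_types(atlas)
  if (length(types) < 2)
    stop("signature construction needs at least 2 cell types")
  counts <- table(atlas$labels)
  low <- names(counts)[counts < min_cells]
  if (length(low))
    stop("cell type(s) below min_cells (", min_cells, "): ",
         paste(low, collapse = ", "))
  if (normalize) atlas <- normalize_counts(atlas, target)
  profiles <- type_profiles(atlas)

  if (mode == "S") {
    w <- ovr_wilcoxon(atlas$expr, atlas$labels)
    q <- apply(w$p, 2, p.adjust, method = "BH")
    best <- max.col(w$lfc, ties.method = "first")
    cand <- lapply(seq_along(types), function(j) {
      sel <- which(best == j & q[cbind(seq_len(nrow(q)), best)] < q_max &
                     w$lfc[cbind(seq_len(nrow(q)), best)] > 0)
      sel[order(w$lfc[sel, j], decreasing = TRUE)]
    })
  } else {
    lp <- log2(profiles + 1)
    best <- max.col(lp, ties.method = "first")
    k <- ncol(profiles)
    rest_mean <- (rowSums(profiles) -
                    profiles[cbind(seq_len(nrow(profiles)), best)]) / (k - 1)
    fcv <- (profiles[cbind(seq_len(nrow(profiles)), best)] + 1) /
      (rest_mean + 1)
    cand <- lapply(seq_len(k), function(j) {
      sel <- which(best == j & fcv >= min_fc)
      sel[order(fcv[sel], decreasing = TRUE)]
    })
  }
  names(cand) <- types
  n_cand <- lengths(cand)
  if (any(n_cand == 0)) {
    warning("no qualifying markers for type(s) ",
            paste(types[n_cand == 0], collapse = ", "),
            "; falling back to top genes by fold change")
    rank_src <- if (mode == "S") w$lfc else log2(profiles + 1)
    for (j in which(n_cand == 0))
      cand[[j]] <- order(rank_src[, j], decreasing = TRUE)[1:max(g_range)]
  }
  gs <- unique(pmin(g_range, max(lengths(cand))))
  best_kappa <- Inf; best_rows <- NULL; best_g <- NA_integer_
  for (G in gs) {
    rows <- sort(unique(unlist(lapply(cand, function(ix)
      ix[seq_len(min(G, length(ix)))]))))
    k2 <- kappa2(profiles[rows, , drop = FALSE])
    if (k2 < best_kappa) {
      best_kappa <- k2; best_rows <- rows; best_g <- G
    }
  }
  expr <- profiles[best_rows, , drop = FALSE]
  structure(list(
    expr = expr, mode = mode, condition_number = best_kappa, g = best_g,
    markers_by_type = lapply(cand, function(ix)
      rownames(atlas$expr)[ix[seq_len(min(best_g, length(ix)))]])),
    class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf(
    "signature_matrix (mode %s): %d marker genes x %d cell types\n",
    x$mode, nrow(x$expr), ncol(x$expr)))
  cat(sprintf("  markers/type G = %d, condition number = %.3g\n",
              x$g, x$condition_number))
  invisible(x)
}
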