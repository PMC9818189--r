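# Lawson-Hanson active-set non-negative least squares.
# Solves min ||A x - b|| s.t. x >= 0 exactly (to numerical precision) on
# the final passive set; the gradient tolerance is relative to the
# initial gradient so exactly-representable right-hand sides (zero
# residual) terminate cleanly.
nnls_fit <- function(A, b, maxit = 30 * ncol(A)) {
  n <- ncol(A)
  P <- logical(n)
  x <- numeric(n)
  tol <- 10 * .Machine$double.eps * max(abs(crossprod(A, b)), 1)
  for (it in seq_len(maxit)) {
    w <- as.vector(crossprod(A, b - A %*% x))
    if (all(P) || max(w[!P]) <= tol) break
    idx_free <- which(!P)
    P[idx_free[which.max(w[idx_free])]] <- TRUE
    repeat {
      z <- numeric(n)
      zp <- qr.coef(qr(A[, P, drop = FALSE]), b)
      zp[is.na(zp)] <- 0
      z[P] <- zp
      if (all(z[P] > 0)) { x <- z; break }
      ix <- which(P & z <= 0)
      ratio <- x[ix] / (x[ix] - z[ix])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      P <- P & (x > tol)
      x[!P] <- 0
    }
  }
  pmax(x, 0)
}

#' Estimate cell-type fractions in bulk samples
#'
#' Fits each bulk expression column as a non-negative combination of the
#' signature's per-type reference profiles and reports both the
#' sum-to-one fractions and the raw (clipped, un-normalised) abundance
#' scores. Genes are intersected between signature and bulk; negative
#' regression coefficients are clipped to zero; fractions are the clipped
#' coefficients divided by their sum, so every row of `coef()` sums to 1.
#' Abundance scores skip that division and remain comparable between
#' samples for one cell type.
#'
#' Engines: `"nnls"` solves the non-negative least-squares problem
#' exactly (Lawson–Hanson active set); `"nu-svr"` fits a linear-kernel
#' nu-support-vector regression on z-scored signature columns and bulk
#' vector, sweeping `nu` and keeping, per sample, the fit with the lowest
#' reconstruction RMSE; coefficients are mapped back to the original
#' scale before clipping.
#'
#' @param signature a [build_signature()] result, or a genes x types
#'   reference matrix.
#' @param bulk genes x samples numeric matrix (a single named vector is
#'   accepted as one sample).
#' @param method `"nnls"` or `"nu-svr"`.
#' @param nu nu values swept for the SVR engine.
#' @return object of class `deconv_fit` with elements `fractions`
#'   (samples x types), `abundance` (samples x types), `method`, `fit`
#'   (per-sample data.frame: rmse, pcc, and chosen nu for the SVR
#'   engine), `signature` (the intersected reference used) and
#'   `n_shared_genes`.
#' @seealso [svr_abundance()], [run_validation()]
#' @export
deconvolute <- function(signature, bulk, method = c("nnls", "nu-svr"),
                        nu = c(0.25, 0.5, 0.75)) {
  method <- match.arg(method)
  sig <- if (inherits(signature, "signature_matrix")) signature$expr
         else as.matrix(signature)
  if (is.null(dim(bulk))) bulk <- cbind(sample_1 = bulk)
  bulk <- as.matrix(bulk)
  if (is.null(rownames(sig)) || is.null(rownames(bulk)))
    stop("signature and bulk must carry gene symbols as rownames")
  shared <- intersect(rownames(sig), rownames(bulk))
  if (length(shared) == 0)
    stop("no shared genes between signature (", nrow(sig),
         " genes) and bulk (", nrow(bulk), " genes)")
  if (length(shared) < ncol(sig))
    stop("only ", length(shared), " shared gene(s) for ", ncol(sig),
         " cell types; deconvolution is underdetermined")
  X <- sig[shared, , drop = FALSE]
  Y <- bulk[shared, , drop = FALSE]
  zero <- colSums(Y) == 0
  if (any(zero))
    stop("all-zero bulk sample(s) on the shared genes: ",
         paste(colnames(Y)[zero], collapse = ", "))
  k <- ncol(X); ns <- ncol(Y)
  types <- colnames(X)
  samples <- colnames(Y) %||% sprintf("sample_%d", seq_len(ns))
  abundance <- matrix(0, ns, k, dimnames = list(samples, types))
  fit <- data.frame(sample = samples, rmse = NA_real_, pcc = NA_real_,
                    stringsAsFactors = FALSE)
  if (method == "nu-svr") fit$nu <- NA_real_
  x_mean <- colMeans(X)
  x_sd <- pmax(apply(X, 2, sd), .Machine$double.eps)
  Xz <- scale(X, center = x_mean, scale = x_sd)
  for (j in seq_len(ns)) {
    y <- Y[, j]
    if (method == "nnls") {
      b <- nnls_fit(X, y)
      yhat <- as.vector(X %*% b)
      fit$rmse[j] <- sqrt(mean((yhat - y)^2))
      fit$pcc[j] <- safe_cor(yhat, y)
      abundance[j, ] <- b
    } else {
      y_sd <- sd(y)
      if (y_sd == 0) stop("bulk sample ", samples[j],
                          " is constant over the shared genes")
      yz <- (y - mean(y)) / y_sd
      best <- NULL
      for (v in nu) {
        m <- e1071::svm(x = Xz, y = yz, type = "nu-regression",
                        kernel = "linear", nu = v, scale = FALSE)
        res <- yz - as.vector(m$fitted)
        rmse <- sqrt(mean(res^2))
        if (is.null(best) || rmse < best$rmse)
          best <- list(m = m, rmse = rmse, nu = v)
      }
      w <- as.vector(t(best$m$coefs) %*% best$m$SV)
      b_raw <- w * y_sd / x_sd          # back to the original scale
      b <- pmax(b_raw, 0)
      yhat_z <- as.vector(best$m$fitted)
      fit$rmse[j] <- best$rmse
      fit$pcc[j] <- safe_cor(yhat_z, yz)
      fit$nu[j] <- best$nu
      abundance[j, ] <- b
    }
  }
  tot <- rowSums(abundance)
  fractions <- abundance
  ok <- tot > 0
  fractions[ok, ] <- abundance[ok, , drop = FALSE] / tot[ok]
  if (any(!ok))
    warning("sample(s) with no positive coefficient, fractions set to 0: ",
            paste(samples[!ok], collapse = ", "))
  structure(list(fractions = fractions, abundance = abundance,
                 method = method, fit = fit, signature = X,
                 n_shared_genes = length(shared)),
            class = "deconv_fit")
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Un-normalised SVR abundance scores
#'
#' Runs the nu-SVR engine and returns the clipped, un-normalised
#' coefficients. Unlike fractions, abundance scores scale with the
#' overall signal of a sample, so they track the absolute amount of a
#' cell type across samples rather than its share of the mixture.
#'
#' @inheritParams deconvolute
#' @return samples x types numeric matrix of non-negative scores.
#' @export
svr_abundance <- function(signature, bulk, nu = c(0.25, 0.5, 0.75)) {
  deconvolute(signature, bulk, method = "nu-svr", nu = nu)$abundance
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("deconv_fit (%s): %d sample(s) x %d cell types, %d shared genes\n",
              x$method, nrow(x$fractions), ncol(x$fractions),
              x$n_shared_genes))
  cat(sprintf("  fit: median RMSE %.4g, median PCC %.4f\n",
              median(x$fit$rmse), median(x$fit$pcc)))
  invisible(x)
}

#' @export
summary.deconv_fit <- function(object, ...) {
  out <- list(method = object$method,
              n_samples = nrow(object$fractions),
              n_types = ncol(object$fractions),
              n_shared_genes = object$n_shared_genes,
              mean_fractions = colMeans(object$fractions),
              fit = object$fit)
  class(out) <- "summary.deconv_fit"
  out
}

#' @export
print.summary.deconv_fit <- function(x, ...) {
  cat(sprintf("Deconvolution by %s on %d sample(s), %d cell types (%d genes)\n",
              x$method, x$n_samples, x$n_types, x$n_shared_genes))
  cat("Mean estimated fractions:\n")
  print(round(x$mean_fractions, 4))
  cat("Per-sample goodness of fit:\n")
  print(x$fit, row.names = FALSE)
  invisible(x)
}

#' @export
coef.deconv_fit <- function(object, ...) object$fractions

#' @export
fitted.deconv_fit <- function(object, ...) {
  object$signature %*% t(object$abundance)
}

#' @export
residuals.deconv_fit <- function(object, bulk, ...) {
  if (missing(bulk))
    stop("supply the bulk matrix the fit was computed from")
  bulk <- as.matrix(bulk)
  shared <- rownames(object$signature)
  bulk[shared, colnames(fitted(object)), drop = FALSE] - fitted(object)
}

#' @export
predict.deconv_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fractions)
  refit <- deconvolute(object$signature, newdata, method = object$method)
  refit$fractions
}

#' Stacked-bar plot of estimated fractions
#' @param x a `deconv_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.deconv_fit <- function(x, ...) {
  graphics::barplot(t(x$fractions), col = seq_len(ncol(x$fractions)) + 1,
                    legend.text = colnames(x$fractions),
                    ylab = "estimated fraction", las = 2, ...)
  invisible(x)
}
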