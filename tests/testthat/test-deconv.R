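test_that("a bulk sample equal to a signature column deconvolutes to that type", {
  at <- small_atlas(seed = 2)
  sig <- build_signature(at, normalize = FALSE)
  b <- cbind(s1 = sig$expr[, "type_02"])
  rownames(b) <- rownames(sig$expr)
  for (m in c("nnls", "nu-svr")) {
    fr <- coef(deconvolute(sig, b, method = m))
    expect_equal(unname(fr["s1", "type_02"]), 1, tolerance = 1e-3)
    expect_lt(max(fr["s1", colnames(fr) != "type_02"]), 1e-3)
  }
})

test_that("NNLS on an orthogonal two-gene design gives the closed-form fractions", {
  X <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  fr <- coef(deconvolute(X, c(g1 = 30, g2 = 70), method = "nnls"))
  expect_equal(unname(fr[1, ]), c(0.3, 0.7))
})

test_that("noiseless mixtures are recovered exactly by NNLS, sum-to-one to 1e-9", {
  at <- small_atlas(seed = 4)
  co <- simulate_cohort(cohort_spec(n_patients = 30, effect_type = "type_01",
                                    noise_scale = 0, seed = 17), at)
  fit <- deconvolute(build_signature(at, normalize = FALSE), co$bulk,
                     method = "nnls")
  fr <- coef(fit)
  expect_lt(max(abs(fr - co$fractions[, colnames(fr)])), 1e-6)
  expect_lt(max(abs(rowSums(fr) - 1)), 1e-9)
  expect_true(all(fr >= 0))
})

test_that("fractions are invariant to positive rescaling of the bulk sample", {
  at <- small_atlas(n_types = 4, n_genes = 500, n_cells = 30, seed = 6)
  sig <- build_signature(at, normalize = FALSE)
  co <- simulate_cohort(cohort_spec(n_patients = 3, effect_type = "type_01",
                                    seed = 23), at)
  scaled <- co$bulk * 3.7
  f1 <- coef(deconvolute(sig, co$bulk, method = "nnls"))
  f2 <- coef(deconvolute(sig, scaled, method = "nnls"))
  expect_equal(f1, f2, tolerance = 1e-10)
  # the SVR engine is invariant up to its SMO solver tolerance
  s1 <- coef(deconvolute(sig, co$bulk, method = "nu-svr"))
  s2 <- coef(deconvolute(sig, scaled, method = "nu-svr"))
  expect_lt(max(abs(s1 - s2)), 0.01)
})

test_that("nu-SVR and NNLS agree on noiseless mixtures within 0.02", {
  at <- small_atlas(dispersion = 0, seed = 2)
  sig <- build_signature(at, normalize = FALSE)
  co <- simulate_cohort(cohort_spec(n_patients = 15, effect_type = "type_01",
                                    noise_scale = 0, seed = 29), at)
  fn <- coef(deconvolute(sig, co$bulk, method = "nnls"))
  fs <- coef(deconvolute(sig, co$bulk, method = "nu-svr"))
  expect_lt(max(abs(fn - fs)), 0.02)
})

test_that("SVR abundance is monotone in the true proportion and scales with signal", {
  at <- small_atlas(dispersion = 0, seed = 2)
  sig <- build_signature(at, normalize = FALSE)
  fgrid <- c(0, 25, 50, 75, 100)
  set.seed(33)
  mix <- vapply(fgrid, function(f)
    make_pseudobulk(at, "type_03", f, cell_frac = 1)$expr,
    numeric(nrow(at$expr)))
  colnames(mix) <- paste0("f", fgrid)
  ab <- svr_abundance(sig, mix)
  expect_true(all(diff(ab[, "type_03"]) > 0))
  expect_gte(cor(fgrid, ab[, "type_03"], method = "spearman"), 0.99)
  # doubling the bulk doubles abundance but leaves fractions unchanged
  b <- sig$expr[, "type_02"]
  two <- cbind(x1 = b, x2 = 2 * b)
  rownames(two) <- rownames(sig$expr)
  fit <- deconvolute(sig, two, method = "nu-svr")
  expect_equal(unname(fit$abundance["x2", "type_02"] /
                        fit$abundance["x1", "type_02"]), 2,
               tolerance = 1e-6)
  expect_equal(coef(fit)["x1", ], coef(fit)["x2", ], tolerance = 1e-8)
})

test_that("a bulk sample orthogonal to the signature gets near-zero scores", {
  set.seed(41)
  X <- matrix(0, 40, 3, dimnames = list(paste0("g", 1:40), c("A", "B", "C")))
  X[1:30, ] <- matrix(rpois(90, 20), 30, 3)
  y <- setNames(numeric(40), rownames(X))
  y[31:40] <- 50   # signal only on genes absent from every reference type
  expect_warning(fit <- deconvolute(X, cbind(s = y), method = "nnls"),
                 "no positive coefficient")
  expect_true(all(fit$abundance == 0))
  # SVR finds no positive support either; scores are (near) zero
  ab <- suppressWarnings(svr_abundance(X, cbind(s = y)))
  expect_lt(max(ab) * 40 / sum(y), 0.05)
})

test_that("gene intersection contracts are enforced with informative errors", {
  at <- small_atlas(n_types = 3, n_genes = 300, n_cells = 25, seed = 1)
  sig <- build_signature(at, normalize = FALSE)
  b <- matrix(1:4, 2, dimnames = list(c("foo", "bar"), c("s1", "s2")))
  expect_error(deconvolute(sig, b), "no shared genes")
  few <- sig$expr[1:2, , drop = FALSE]
  b2 <- matrix(1:2, 2, dimnames = list(rownames(few), "s1"))
  expect_error(deconvolute(sig$expr[, , drop = FALSE], b2), "underdetermined")
  bz <- matrix(0, nrow(sig$expr), 1,
               dimnames = list(rownames(sig$expr), "deadsample"))
  expect_error(deconvolute(sig, bz), "deadsample")
})

test_that("deconv_fit methods are coherent", {
  at <- small_atlas(n_types = 3, n_genes = 300, n_cells = 25, seed = 1)
  sig <- build_signature(at, normalize = FALSE)
  co <- simulate_cohort(cohort_spec(n_patients = 4, effect_type = "type_01",
                                    seed = 3), at)
  fit <- deconvolute(sig, co$bulk, method = "nnls")
  expect_s3_class(fit, "deconv_fit")
  expect_equal(dim(coef(fit)), c(4, 3))
  expect_equal(dim(fitted(fit)), c(fit$n_shared_genes, 4))
  res <- residuals(fit, co$bulk)
  expect_equal(fitted(fit) + res,
               co$bulk[rownames(fit$signature), ], tolerance = 1e-9)
  expect_equal(predict(fit), coef(fit))
  expect_equal(predict(fit, co$bulk), coef(fit), tolerance = 1e-9)
  expect_output(print(fit), "deconv_fit")
  expect_output(print(summary(fit)), "goodness of fit")
  expect_true(all(fit$fit$pcc > 0.9))
})
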