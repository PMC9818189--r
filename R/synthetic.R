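#' Specification of a synthetic single-cell atlas
#'
#' Describes the generative model for [simulate_atlas()]: a fixed set of
#' cell types (optionally refined into subtypes), per-type planted marker
#' genes with a known fold change over background, negative-binomial
#' counts with a shared overdispersion, and log-normal library-size
#' variation. The defaults define the simulation conditions used
#' throughout the package's validation.
#'
#' @param n_types number of top-level cell types (>= 2).
#' @param subtype_map named list, top-level type -> character vector of
#'   subtype labels (may be empty; subtypes replace their parent as
#'   leaves of the type tree). Subtypes inherit the parent's markers and
#'   gain a small private marker set, so tree collapsing has measurable
#'   consequences.
#' @param n_cells_per_type cells generated per leaf type.
#' @param n_genes total genes.
#' @param n_markers_per_type planted markers per top-level type.
#' @param marker_fold_change expected expression ratio of a marker in its
#'   own type versus background (> 1).
#' @param dispersion negative-binomial overdispersion shared by all genes
#'   (`size = 1/dispersion`); `0` is the noiseless limit where every cell
#'   equals its expected profile exactly.
#' @param library_size_mean mean total counts per cell.
#' @param seed integer RNG seed.
#' @param type_names optional labels for the top-level types.
#' @return an `atlas_spec` list.
#' @export
atlas_spec <- function(n_types = 8, subtype_map = list(),
                       n_cells_per_type = 100, n_genes = 2000,
                       n_markers_per_type = 20, marker_fold_change = 8,
                       dispersion = 0.5, library_size_mean = 2000,
                       seed = 1, type_names = NULL) {
  if (n_types < 2) stop("invalid atlas_spec: n_types >= 2 is required")
  if (marker_fold_change <= 1)
    stop("invalid atlas_spec: marker_fold_change > 1 is required")
  if (n_markers_per_type * n_types > n_genes)
    stop("invalid atlas_spec: n_markers_per_type * n_types <= n_genes ",
         "is required")
  if (dispersion < 0) stop("invalid atlas_spec: dispersion must be >= 0")
  if (library_size_mean <= 0)
    stop("invalid atlas_spec: library_size_mean must be positive")
  type_names <- type_names %||% sprintf("type_%02d", seq_len(n_types))
  if (length(type_names) != n_types) stop("need one name per type")
  bad <- setdiff(names(subtype_map), type_names)
  if (length(bad))
    stop("subtype_map keys are not top-level types: ",
         paste(bad, collapse = ", "))
  structure(list(n_types = n_types, subtype_map = subtype_map,
                 n_cells_per_type = n_cells_per_type, n_genes = n_genes,
                 n_markers_per_type = n_markers_per_type,
                 marker_fold_change = marker_fold_change,
                 dispersion = dispersion,
                 library_size_mean = library_size_mean,
                 seed = as.integer(seed), type_names = type_names),
            class = "atlas_spec")
}

#' Simulate an annotated single-cell atlas with planted markers
#'
#' Draws a baseline log-normal expression profile shared by all types,
#' plants `n_markers_per_type` marker genes per top-level type whose
#' expected expression is `marker_fold_change` times background in that
#' type, and samples negative-binomial counts per cell with log-normal
#' library sizes. Subtypes inherit the parent markers plus a private
#' marker set of about a quarter of the parent's size. The planted truth
#' is returned in `$markers` for benchmarking marker selection.
#'
#' @param spec an [atlas_spec()].
#' @return a [new_atlas()] object of raw counts; same seed gives a
#'   bit-identical atlas.
#' @export
simulate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  set.seed(spec$seed)
  genes <- sprintf("gene_%05d", seq_len(spec$n_genes))
  # leaves: subtypes replace their parent where a subtype_map entry exists
  leaves <- list(); tree <- data.frame(child = character(),
                                       parent = character())
  for (tp in spec$type_names) {
    subs <- spec$subtype_map[[tp]]
    if (length(subs)) {
      leaves[[tp]] <- subs
      tree <- rbind(tree, data.frame(child = tp, parent = "root"),
                    data.frame(child = subs, parent = tp))
    } else {
      leaves[[tp]] <- tp
      tree <- rbind(tree, data.frame(child = tp, parent = "root"))
    }
  }
  leaf_names <- unlist(leaves, use.names = FALSE)
  n_private <- max(3L, spec$n_markers_per_type %/% 4L)
  n_sub <- sum(lengths(spec$subtype_map))
  need <- spec$n_markers_per_type * spec$n_types + n_private * n_sub
  if (need > spec$n_genes)
    stop("invalid atlas_spec: marker blocks (", need,
         " genes incl. subtype-private markers) exceed n_genes")
  pool <- sample.int(spec$n_genes, need)
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }

  base <- rlnorm(spec$n_genes, meanlog = log(5), sdlog = 1)
  fc <- matrix(1, spec$n_genes, length(leaf_names),
               dimnames = list(genes, leaf_names))
  markers <- list()
  for (tp in spec$type_names) {
    block <- take(spec$n_markers_per_type)
    for (lf in leaves[[tp]]) {
      fc[block, lf] <- spec$marker_fold_change
      markers[[lf]] <- genes[block]
    }
    if (!identical(leaves[[tp]], tp)) {
      for (lf in leaves[[tp]]) {
        priv <- take(n_private)
        fc[priv, lf] <- spec$marker_fold_change
        markers[[lf]] <- c(markers[[lf]], genes[priv])
      }
    }
  }
  base_mass <- sum(base)
  n_cells <- spec$n_cells_per_type * length(leaf_names)
  labels <- rep(leaf_names, each = spec$n_cells_per_type)
  cell_ids <- sprintf("cell_%05d", seq_len(n_cells))
  libs <- rlnorm(n_cells, meanlog = log(spec$library_size_mean) - 0.3^2 / 2,
                 sdlog = 0.3)
  expr <- matrix(0, spec$n_genes, n_cells, dimnames = list(genes, cell_ids))
  for (lf in leaf_names) {
    cols <- which(labels == lf)
    # per-gene rate relative to the baseline mass, so a marker's expected
    # expression is exactly fold_change x background in its own type
    p <- base * fc[, lf] / base_mass
    mu <- outer(p, libs[cols])
    if (spec$dispersion > 0) {
      expr[, cols] <- matrix(rnbinom(length(mu), mu = mu,
                                     size = 1 / spec$dispersion),
                             nrow = spec$n_genes)
    } else {
      expr[, cols] <- mu
    }
  }
  new_atlas(expr, setNames(labels, cell_ids), tree, markers)
}

#' Specification of a synthetic bulk + survival cohort
#'
#' Describes [simulate_cohort()]: per-patient cell-type fractions drawn
#' from a Dirichlet prior, bulk expression as the fraction-weighted
#' combination of per-type atlas profiles with multiplicative log-normal
#' noise, and exponential survival whose log hazard is linear in one
#' chosen cell-type fraction.
#'
#' @param n_patients cohort size.
#' @param effect_type cell-type label whose fraction drives the hazard.
#' @param fraction_prior Dirichlet concentration vector over the atlas
#'   leaf types (default flat, all 1).
#' @param log_hazard_ratio log hazard ratio per unit fraction of
#'   `effect_type` (0 = null cohort).
#' @param baseline_hazard events per month at fraction 0.
#' @param censoring_rate probability in `[0, 1)` that a patient is
#'   censored (uniformly before their event time).
#' @param noise_scale sd of the multiplicative log-normal noise on the
#'   mixed bulk profile; 0 gives exact convex combinations.
#' @param seed integer RNG seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 100, effect_type,
                        fraction_prior = NULL, log_hazard_ratio = 0,
                        baseline_hazard = 0.02, censoring_rate = 0.2,
                        noise_scale = 0.1, seed = 1) {
  if (!is.null(fraction_prior) && any(fraction_prior <= 0))
    stop("invalid cohort_spec: fraction_prior must be strictly positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("invalid cohort_spec: censoring_rate must be in [0, 1)")
  if (baseline_hazard <= 0)
    stop("invalid cohort_spec: baseline_hazard must be positive")
  structure(list(n_patients = n_patients, effect_type = effect_type,
                 fraction_prior = fraction_prior,
                 log_hazard_ratio = log_hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a bulk cohort with known fractions and linked survival
#'
#' Each bulk sample is the fraction-weighted convex combination of the
#' atlas per-type mean profiles, with multiplicative log-normal noise.
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio * fraction(effect_type))`,
#' in months; censored patients get a uniform time before their event.
#'
#' @param spec a [cohort_spec()].
#' @param atlas a `tme_atlas` providing the per-type profiles.
#' @return list with `bulk` (genes x patients matrix), `fractions`
#'   (patients x types, rows sum to 1) and `survival`
#'   (data.frame sample_id, time, event).
#' @export
simulate_cohort <- function(spec, atlas) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(atlas, "tme_atlas"))
  types <- atlas_types(atlas)
  if (!(spec$effect_type %in% types))
    stop("unknown effect_type '", spec$effect_type, "'; available types: ",
         paste(types, collapse = ", "))
  prior <- spec$fraction_prior %||% rep(1, length(types))
  if (length(prior) != length(types))
    stop("fraction_prior must have one entry per atlas type (",
         length(types), ")")
  set.seed(spec$seed)
  n <- spec$n_patients
  g <- matrix(rgamma(n * length(types), shape = rep(prior, each = n)),
              nrow = n)
  fractions <- g / rowSums(g)
  dimnames(fractions) <- list(sprintf("sample_%04d", seq_len(n)), types)
  profiles <- type_profiles(atlas)
  bulk <- profiles %*% t(fractions)
  if (spec$noise_scale > 0)
    bulk <- bulk * exp(matrix(rnorm(length(bulk), 0, spec$noise_scale),
                              nrow = nrow(bulk)))
  hazard <- spec$baseline_hazard *
    exp(spec$log_hazard_ratio * fractions[, spec$effect_type])
  t_event <- rexp(n, rate = hazard)
  censored <- runif(n) < spec$censoring_rate
  time <- ifelse(censored, runif(n, 0, t_event), t_event)
  surv <- data.frame(sample_id = rownames(fractions), time = time,
                     event = !censored, stringsAsFactors = FALSE)
  list(bulk = bulk, fractions = fractions, survival = surv)
}
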