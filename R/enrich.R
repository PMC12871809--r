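# ---------------------------------------------------------------------------
# Negative-binomial differential abundance, VST surrogate, PCA/RDA under
# diet models, enrichment designation, Kendall-correlation grouping.
# ---------------------------------------------------------------------------

#' Median-of-ratios size factors
#'
#' `s_j = median_i(K_ij / geomean_i)` over features with all-positive
#' counts. When no feature is positive everywhere, geometric means are
#' taken over the positive entries of each feature (with a warning) and the
#' per-sample median runs over features positive in that sample.
#'
#' @param counts feature x sample matrix of raw (possibly fractional)
#'   counts.
#' @return positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  all_pos <- rowSums(counts <= 0) == 0
  if (any(all_pos)) {
    logg <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2, function(k)
      exp(median(log(k) - logg)))
  } else {
    warning("no feature with all-positive counts; ",
            "falling back to positive-subset geometric means")
    logg <- apply(counts, 1, function(k) mean(log(k[k > 0])))
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      k <- counts[, j]
      use <- k > 0 & is.finite(logg)
      exp(median(log(k[use]) - logg[use]))
    }, numeric(1))
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  setNames(sf, colnames(counts))
}

# method-of-moments NB dispersion from normalized counts, within groups so
# that true group differences do not inflate the estimate
mom_dispersion <- function(norm, condition, floor = 1e-8) {
  ests <- vapply(levels(condition), function(g) {
    k <- norm[condition == g]
    m <- mean(k)
    if (m <= 0 || length(k) < 2) return(NA_real_)
    (var(k) - m) / m^2
  }, numeric(1))
  est <- mean(ests, na.rm = TRUE)
  if (!is.finite(est)) est <- floor
  max(est, floor)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' A transparent approximation of the standard NB differential-abundance
#' workflow: median-of-ratios normalisation, per-feature method-of-moments
#' dispersion on normalised counts (estimated within groups, floored at
#' 1e-8), an NB log-link GLM fitted by iteratively reweighted least squares
#' with the size factors as offsets, a Wald z test on the group
#' coefficient, and Benjamini-Hochberg adjustment across features. No
#' empirical-Bayes dispersion shrinkage, no fold-change shrinkage and no
#' independent filtering are applied; see the methods vignette.
#'
#' `log2FC` is the log2 fold change of the second factor level relative to
#' the first. `baseMean` is the mean of size-factor-normalised counts over
#' all samples.
#'
#' @param counts feature x sample matrix (integer-valued; weighted counts
#'   are rounded).
#' @param condition two-level factor, one level per sample, each level with
#'   at least two samples.
#' @param sf optional size factors; computed from `counts` when missing.
#' @return `data.frame` of class `enrichment_table`: `feature_id`,
#'   `baseMean`, `log2FC`, `lfcSE`, `stat`, `pvalue`, `padj`; the contrast
#'   levels are stored in `attr(, "contrast")` as `c(reference, level)`.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL) {
  condition <- droplevels(as.factor(condition))
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 2)) stop("each group needs >= 2 samples")
  stopifnot(ncol(counts) == length(condition))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  y_all <- round(counts)
  off <- log(sf)
  x <- condition

  res <- matrix(NA_real_, nrow(counts), 5,
                dimnames = list(rownames(counts),
                                c("baseMean", "log2FC", "lfcSE", "stat",
                                  "pvalue")))
  res[, "baseMean"] <- rowMeans(norm)
  for (i in seq_len(nrow(counts))) {
    y <- y_all[i, ]
    if (all(y == 0)) next
    disp <- mom_dispersion(norm[i, ], condition)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        y ~ x + offset(off),
        family = MASS::negative.binomial(theta = 1 / disp, link = "log"),
        control = list(maxit = 50, epsilon = 1e-8))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2 || anyNA(sm[2, 1:2])) next
    beta <- sm[2, 1]; se <- sm[2, 2]
    res[i, "log2FC"] <- beta / log(2)
    res[i, "lfcSE"] <- se / log(2)
    res[i, "stat"] <- beta / se
    # t reference with residual df: the dispersion is estimated from the
    # same few samples, so the normal reference is anticonservative here
    res[i, "pvalue"] <- 2 * stats::pt(-abs(beta / se), df = length(y) - 2)
  }
  out <- data.frame(feature_id = rownames(counts), res,
                    padj = p.adjust(res[, "pvalue"], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- levels(condition)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' All pairwise diet contrasts of a count table
#'
#' Runs [nb_wald_test()] for every unordered diet pair; size factors are
#' computed once on the full table.
#'
#' @param counts feature x sample matrix.
#' @param design diet design covering the samples.
#' @return named list of `enrichment_table`s (`"A_vs_B"`).
#' @export
pairwise_diet_tests <- function(counts, design) {
  design <- design[match(colnames(counts), design$sample_id), ]
  diets <- unique(design$diet_label)
  sf <- size_factors(counts)
  out <- list()
  for (i in seq_along(diets)) for (j in seq_along(diets)) if (i < j) {
    keep <- design$diet_label %in% diets[c(i, j)]
    tab <- nb_wald_test(counts[, keep, drop = FALSE],
                        factor(design$diet_label[keep],
                               levels = diets[c(i, j)]),
                        sf = sf[keep])
    out[[paste0(diets[i], "_vs_", diets[j])]] <- tab
  }
  out
}

#' Designate features by the diet(s) that enrich them
#'
#' A feature counts as enriched in diet D if, in at least one pairwise
#' contrast involving D, its adjusted p is below `alpha`, its baseMean
#' exceeds `base_mean_min`, and the fold change favors D. Features enriched
#' in any ratio (mixed-fiber) diet are designated mixed-fiber; the result
#' partitions features over \{xylan, cellulose, mixed\} and their
#' intersections.
#'
#' @param tables named list of `enrichment_table`s from
#'   [pairwise_diet_tests()].
#' @param design diet design (used to classify diets: 0% xylan = cellulose,
#'   100% = xylan, anything else = mixed).
#' @param alpha adjusted-p threshold.
#' @param base_mean_min baseMean filter.
#' @return `data.frame` with `feature_id`, logical `xylan`, `cellulose`,
#'   `mixed`, and a combined `category` label (`"unlabeled"` when the
#'   filters exclude the feature everywhere).
#' @export
designate_enrichment <- function(tables, design, alpha = 0.05,
                                 base_mean_min = 100) {
  diet_class <- function(d) {
    xp <- design$xylan_percent[match(d, design$diet_label)]
    ifelse(xp == 100, "xylan", ifelse(xp == 0, "cellulose", "mixed"))
  }
  enriched <- list()  # feature -> set of diets
  for (tab in tables) {
    con <- attr(tab, "contrast")
    sig <- !is.na(tab$padj) & tab$padj < alpha & tab$baseMean > base_mean_min
    up <- sig & tab$log2FC > 0    # favors second level
    dn <- sig & tab$log2FC < 0    # favors first level
    for (f in tab$feature_id[up])
      enriched[[f]] <- union(enriched[[f]], con[2])
    for (f in tab$feature_id[dn])
      enriched[[f]] <- union(enriched[[f]], con[1])
  }
  feats <- sort(unique(unlist(lapply(tables, `[[`, "feature_id"))))
  flags <- t(vapply(feats, function(f) {
    cls <- unique(diet_class(enriched[[f]]))
    c(xylan = "xylan" %in% cls, cellulose = "cellulose" %in% cls,
      mixed = "mixed" %in% cls)
  }, logical(3)))
  category <- apply(flags, 1, function(v)
    if (!any(v)) "unlabeled" else paste(names(v)[v], collapse = "&"))
  data.frame(feature_id = feats, flags, category = unname(category),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance-stabilising transform (log surrogate)
#'
#' `log2(count / size_factor + 1)`: monotone in counts, approximately
#' removes library-size differences, and maps zeros to zero. A deliberate,
#' documented surrogate for dispersion-trend-based transforms, which
#' require a fitted mean-dispersion relationship.
#'
#' @param counts feature x sample matrix.
#' @param sf optional size factors.
#' @return transformed matrix, same shape.
#' @export
vst_counts <- function(counts, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Principal component analysis of a transformed table
#'
#' Column-centred SVD over samples; variance fractions are the per-axis
#' shares of total variance. Axis signs are fixed so the largest-magnitude
#' loading of each axis is positive.
#'
#' @param transformed feature x sample matrix (e.g. from [vst_counts()]).
#' @return list with `scores` (samples x axes), `loadings`,
#'   `var_fraction`.
#' @export
pca_counts <- function(transformed) {
  x <- t(transformed)
  if (nrow(x) < 2) stop("need >= 2 samples")
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    l <- fit$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(fit$x, 2, flip, "*")
  loadings <- sweep(fit$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       var_fraction = fit$sdev^2 / sum(fit$sdev^2))
}

#' Redundancy analysis under a constraining model
#'
#' Regresses the centred sample x feature response matrix on the centred
#' model matrix by least squares. The constrained variance fraction is
#' `||fitted||^2 / ||Y||^2`; constrained axes are the PCA of the fitted
#' values, with per-axis fractions on the total-variance scale. Model
#' significance uses a permutation pseudo-F (rows of the model matrix
#' permuted, add-one p).
#'
#' @param transformed feature x sample matrix.
#' @param model numeric vector, factor, or data.frame of constraints (one
#'   row/value per sample).
#' @param n_perm permutations for the F test.
#' @param seed integer seed.
#' @param label model label carried into the result.
#' @return list of class `rda_result`: `label`, `constrained_fraction`,
#'   `axis_fractions`, `F`, `p`, `df`.
#' @export
rda_counts <- function(transformed, model, n_perm = 199, seed = 1L,
                       label = NULL) {
  y <- t(transformed)
  y <- sweep(y, 2, colMeans(y))
  n <- nrow(y)
  mm <- stats::model.matrix(~ ., data = if (is.data.frame(model)) model
                            else data.frame(model = model))
  x <- mm[, -1, drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  q <- qr(x)
  if (q$rank < ncol(x)) stop("rank-deficient constraint matrix")
  qdf <- q$rank
  if (n - qdf - 1 <= 0) stop("too few residual degrees of freedom")
  ss_tot <- sum(y^2)
  frac_of <- function(xp) {
    fit <- qr.fitted(qr(xp), y)
    sum(fit^2) / ss_tot
  }
  frac <- frac_of(x)
  fitted <- qr.fitted(q, y)
  pca <- prcomp(fitted, center = FALSE)
  axis_frac <- (pca$sdev^2 * (n - 1)) / ss_tot
  axis_frac <- axis_frac[seq_len(min(qdf, length(axis_frac)))]
  F_of <- function(fr) (fr / qdf) / ((1 - fr) / (n - qdf - 1))
  F_obs <- F_of(frac)
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(i)
    F_of(frac_of(x[sample.int(n), , drop = FALSE])), numeric(1))
  structure(list(label = if (is.null(label)) "model" else label,
                 constrained_fraction = frac,
                 axis_fractions = axis_frac,
                 F = F_obs, p = (1 + sum(F_perm >= F_obs)) / (1 + n_perm),
                 df = c(model = qdf, residual = n - qdf - 1)),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA [%s]: constrained %.1f%%, F = %.2f, p = %.4g\n",
              x$label, 100 * x$constrained_fraction, x$F, x$p))
  invisible(x)
}

#' RDA under the four diet models
#'
#' Fits the constrained models Diet (factor), percent xylan (numeric),
#' contains-xylan and contains-cellulose (presence/absence), plus the
#' unconstrained PCA, and tabulates constrained variance fractions with
#' permutation p-values — the standard model-comparison table. Because
#' percent xylan is constant within a diet, its column lies in the span of
#' the Diet factor, so the Diet fraction is always at least the percent-
#' xylan fraction.
#'
#' @param transformed feature x sample matrix.
#' @param design diet design covering the samples (column order must
#'   match).
#' @param n_perm,seed permutation settings.
#' @return `data.frame` with one row per model: `model`, `fraction`, `F`,
#'   `p` (the unconstrained row reports the PC1 fraction with NA test).
#' @export
rda_diet_models <- function(transformed, design, n_perm = 199, seed = 1L) {
  design <- design[match(colnames(transformed), design$sample_id), ]
  models <- list(
    Diet = factor(design$diet_label),
    percent_xylan = design$xylan_percent,
    contains_xylan = factor(design$contains_xylan),
    contains_cellulose = factor(design$contains_cellulose))
  rows <- lapply(names(models), function(nm) {
    r <- rda_counts(transformed, models[[nm]], n_perm = n_perm,
                    seed = seed, label = nm)
    data.frame(model = nm, fraction = r$constrained_fraction,
               F = r$F, p = r$p, stringsAsFactors = FALSE)
  })
  pc1 <- pca_counts(transformed)$var_fraction[1]
  rows[[length(rows) + 1L]] <- data.frame(
    model = "unconstrained_PC1", fraction = pc1, F = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kendall-correlation grouping of genera
#'
#' Pairwise Kendall tau-b over samples between genera whose mean relative
#' abundance exceeds `min_mean_pct` percent, followed by single-linkage
#' clustering: genera joined whenever tau >= `threshold`. Deterministic.
#'
#' @param abundance genus x sample abundance matrix (absolute or relative).
#' @param threshold tau threshold for linkage.
#' @param min_mean_pct mean relative-abundance filter, in percent.
#' @return list with `tau` (correlation matrix of retained genera) and
#'   `groups` (named integer group memberships).
#' @export
kendall_grouping <- function(abundance, threshold = 0.5, min_mean_pct = 1) {
  rel <- sweep(abundance, 2, colSums(abundance), "/")
  keep <- rowMeans(rel) * 100 > min_mean_pct
  m <- abundance[keep, , drop = FALSE]
  if (nrow(m) < 2) {
    warning("fewer than two genera pass the abundance filter")
    return(list(tau = NULL,
                groups = setNames(rep(1L, nrow(m)), rownames(m))))
  }
  tau <- stats::cor(t(m), method = "kendall")
  hc <- stats::hclust(stats::as.dist(1 - tau), method = "single")
  groups <- stats::cutree(hc, h = 1 - threshold + 1e-12)
  list(tau = tau, groups = groups)
}
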