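test_that("size factors follow the median-of-ratios definition", {
  set.seed(71)
  m <- matrix(rpois(50 * 4, 40) + 1, 50,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:4)))
  # identical samples give equal factors; doubling doubles the factor
  eq <- cbind(m[, 1], m[, 1], m[, 1] * 2)
  colnames(eq) <- paste0("s", 1:3); rownames(eq) <- rownames(m)
  sf <- size_factors(eq)
  expect_equal(sf[[1]], sf[[2]])
  expect_equal(sf[[3]], 2 * sf[[1]])
  # direct formula on a random table
  logg <- rowMeans(log(m))
  want <- apply(m, 2, function(k) exp(median(log(k) - logg)))
  expect_equal(size_factors(m), want, tolerance = 1e-12)
  # fallback when no feature is positive everywhere
  m0 <- m; m0[cbind(1:50, rep_len(1:4, 50))] <- 0
  expect_warning(sf0 <- size_factors(m0), "positive")
  expect_true(all(sf0 > 0))
})

test_that("the NB Wald test is symmetric, null-safe and recovers signals", {
  set.seed(72)
  n <- 5
  cond <- factor(rep(c("a", "b"), each = n))
  y <- matrix(rnbinom(100 * 2 * n, mu = 150, size = 10), 100,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:(2 * n))))
  # identical counts in both groups: log2FC exactly 0
  y[1, ] <- rep(c(10, 20, 30, 40, 50), 2)
  sf1 <- setNames(rep(1, 2 * n), colnames(y))
  res <- nb_wald_test(y, cond, sf = sf1)
  expect_equal(res$log2FC[1], 0, tolerance = 1e-6)
  # all-zero feature reported missing
  y[2, ] <- 0
  res <- nb_wald_test(y, cond, sf = sf1)
  expect_true(is.na(res$pvalue[2]))
  expect_equal(res$baseMean[2], 0)
  # sign flips exactly under group-label swap
  flipped <- nb_wald_test(y, factor(cond, levels = c("b", "a")), sf = sf1)
  ok <- !is.na(res$log2FC)
  expect_equal(res$log2FC[ok], -flipped$log2FC[ok], tolerance = 1e-8)
  # BH adjustment is monotone in p and within [0, 1]
  ordp <- order(res$pvalue[ok])
  expect_true(all(diff(res$padj[ok][ordp]) >= -1e-12))
  expect_true(all(res$padj[ok] >= 0 & res$padj[ok] <= 1))
  # a strong planted change is found with the right sign
  y[3, cond == "b"] <- rnbinom(n, mu = 1200, size = 10)
  res <- nb_wald_test(y, cond, sf = sf1)
  expect_lt(res$padj[3], 0.05)
  expect_gt(res$log2FC[3], 1)
})

test_that("enrichment designation partitions diets into the fiber classes", {
  mk <- function(features, lfc, padj, base, contrast) {
    t <- data.frame(feature_id = features, baseMean = base, log2FC = lfc,
                    lfcSE = 1, stat = lfc, pvalue = padj, padj = padj)
    attr(t, "contrast") <- contrast
    class(t) <- c("enrichment_table", "data.frame")
    t
  }
  design <- diet_design(paste0("s", 1:6),
                        rep(c("MCC", "50% mix", "xylan"), 2),
                        rep(c(0, 50, 100), 2))
  tables <- list(
    mk("f1", lfc = 3, padj = 0.01, base = 500, c("MCC", "50% mix")),
    mk("f1", lfc = 0, padj = 0.9, base = 500, c("MCC", "xylan")),
    mk("f2", lfc = -2, padj = 0.01, base = 50, c("MCC", "xylan")))
  lab <- designate_enrichment(tables, design)
  # enriched only in the 50% diet -> mixed-only
  expect_equal(lab$category[lab$feature_id == "f1"], "mixed")
  # below the baseMean filter everywhere -> unlabeled
  expect_equal(lab$category[lab$feature_id == "f2"], "unlabeled")
  # negative fold change favors the first contrast level
  tables2 <- list(mk("f3", lfc = -4, padj = 0.001, base = 900,
                     c("xylan", "MCC")))
  lab2 <- designate_enrichment(tables2, design)
  expect_equal(lab2$category, "xylan")
})

test_that("planted diet responders are recovered with bounded FDR", {
  set.seed(73)
  diets <- c("MCC", "50% mix", "xylan")
  design <- diet_design(sprintf("s%02d", 1:18), rep(diets, each = 6),
                        rep(c(0, 50, 100), each = 6))
  nfeat <- 300
  mu <- matrix(100, nfeat, 18)
  responders <- 1:30   # xylan-enriched truth
  mu[responders, design$xylan_percent == 100] <- 600
  y <- matrix(rnbinom(nfeat * 18, mu = mu, size = 10), nfeat,
              dimnames = list(paste0("f", 1:nfeat), design$sample_id))
  tabs <- pairwise_diet_tests(y, design)
  lab <- designate_enrichment(tabs, design)
  called <- lab$feature_id[lab$xylan]
  truth <- paste0("f", responders)
  fdr <- if (length(called)) mean(!called %in% truth) else 0
  expect_lte(fdr, 0.1)
  expect_gt(length(intersect(called, truth)) / length(truth), 0.8)
})

test_that("the VST surrogate is monotone and library-size invariant", {
  set.seed(74)
  m <- matrix(rpois(60 * 4, 80) + 50, 60,
              dimnames = list(paste0("f", 1:60), paste0("s", 1:4)))
  doubled <- m; doubled[, 2] <- m[, 1] * 2; doubled[, 1] <- m[, 1]
  v <- vst_counts(doubled)
  expect_lt(max(abs(v[, 1] - v[, 2])), 0.1)
  expect_equal(vst_counts(matrix(0, 1, 2, dimnames = list("f", c("a", "b"))),
                          sf = c(a = 1, b = 1))[1, 1], 0)
  # monotone over random pairs within a sample
  vm <- vst_counts(m)
  j <- sample(4, 1)
  ord <- order(m[, j])
  expect_true(all(diff(vm[ord, j]) >= 0))
})

test_that("PCA matches the eigendecomposition with fixed signs", {
  set.seed(75)
  x <- matrix(rnorm(100), 10, 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  p <- pca_counts(x)
  expect_true(all(diff(p$var_fraction) <= 1e-12))
  cmat <- cov(t(x))
  ev <- eigen(cmat, symmetric = TRUE)$values
  expect_equal(p$var_fraction[1:9], (ev / sum(ev))[1:9], tolerance = 1e-9)
  # collinear data loads entirely on PC1
  line <- outer(c(1, 2, 3), seq(0, 1, length.out = 6))
  dimnames(line) <- list(paste0("f", 1:3), paste0("s", 1:6))
  expect_equal(pca_counts(line)$var_fraction[1], 1, tolerance = 1e-9)
})

test_that("RDA is self-consistent, nested, and null-calibrated", {
  set.seed(76)
  x <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:12)))
  p <- pca_counts(x)
  # constraining on the PC1 scores recovers exactly the PC1 fraction
  r1 <- rda_counts(x, p$scores[, 1], n_perm = 9, seed = 1)
  expect_equal(r1$constrained_fraction, p$var_fraction[1], tolerance = 1e-9)
  # the Diet factor always explains at least the numeric percent (nesting)
  design <- diet_design(colnames(x), rep(c("MCC", "50% mix", "xylan"), 4),
                        rep(c(0, 50, 100), 4))
  tab <- rda_diet_models(x, design, n_perm = 19, seed = 1)
  expect_gte(tab$fraction[tab$model == "Diet"],
             tab$fraction[tab$model == "percent_xylan"] - 1e-12)
  expect_error(rda_counts(x, cbind(1:12, (1:12) * 2), n_perm = 9),
               "rank-deficient")
  # independent cross-check against vegan's constrained fraction
  v <- vegan::rda(t(x) ~ design$xylan_percent)
  expect_equal(r_frac <- rda_counts(x, design$xylan_percent,
                                    n_perm = 9)$constrained_fraction,
               unname(v$CCA$tot.chi / v$tot.chi), tolerance = 1e-9)
})

test_that("Kendall grouping reproduces tau-b and single-linkage groups", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- rbind(g1 = x, g2 = x + rnorm(6, 0, 1e-9), g3 = rev(x))
  colnames(m) <- paste0("s", 1:6)
  kg <- kendall_grouping(m, threshold = 0.5, min_mean_pct = 0)
  expect_equal(kg$tau["g1", "g2"], 1, tolerance = 1e-9)
  expect_equal(kg$tau["g1", "g3"], -1, tolerance = 1e-9)
  expect_equal(kg$groups[["g1"]], kg$groups[["g2"]])
  expect_false(kg$groups[["g1"]] == kg$groups[["g3"]])
  # tau-b with ties against exhaustive pair enumeration on n=6
  set.seed(77)
  a <- sample(1:3, 6, replace = TRUE); b <- sample(1:3, 6, replace = TRUE)
  m2 <- rbind(a = a, b = b, filler = 1:6)
  colnames(m2) <- paste0("s", 1:6)
  kg2 <- kendall_grouping(m2, min_mean_pct = 0)
  expect_equal(kg2$tau["a", "b"], oracle_tau_b(a, b), tolerance = 1e-9)
  # abundance filter: rare genera excluded
  m3 <- rbind(big = c(100, 90, 80), tiny = c(0.1, 0.2, 0.1))
  colnames(m3) <- paste0("s", 1:3)
  expect_warning(kg3 <- kendall_grouping(m3), "filter")
  expect_equal(names(kg3$groups), "big")
})
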