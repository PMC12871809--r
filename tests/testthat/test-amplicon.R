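test_that("contaminant filtering drops exactly the blocklisted lineages", {
  run <- small_amplicon_run()
  asv <- run$asv
  fl <- filter_contaminants(asv$counts, asv$taxonomy)
  expect_setequal(fl$dropped_asvs,
                  asv$asv_truth$asv_id[asv$asv_truth$contaminant])
  expect_equal(length(fl$dropped_asvs), 12L)
  # empty blocklist is the identity
  fl0 <- filter_contaminants(asv$counts, asv$taxonomy, blocklist = character())
  expect_identical(fl0$counts, asv$counts)
  # substring matching is case-insensitive at any rank
  tax <- data.frame(asv_id = "a1", lineage = "Bacteria;X;Y;CHLOROPLAST;Z;W")
  m <- matrix(5, 1, 1, dimnames = list("a1", "s1"))
  expect_equal(nrow(filter_contaminants(m, tax)$counts), 0L)
})

test_that("rarefaction hits the target depth and preserves proportions", {
  set.seed(61)
  m <- matrix(rpois(40 * 6, 30), 40,
              dimnames = list(paste0("f", 1:40), paste0("s", 1:6)))
  r <- rarefy_counts(m, 500, seed = 1)
  expect_true(all(colSums(r) == 500))
  expect_true(all(r <= m))
  # depth equal to a sample's total leaves that sample unchanged
  one <- m[, 1, drop = FALSE]
  expect_equal(rarefy_counts(one, sum(one), seed = 1), one)
  expect_warning(rarefy_counts(m, sum(m[, 1]) + 1e6, seed = 1), "dropping")
  # hypergeometric expectation: mean rarefied count ~ depth * proportion
  p <- m[5, 2] / sum(m[, 2])
  draws <- vapply(1:200, function(s)
    rarefy_counts(m[, 2, drop = FALSE], 500, seed = s)[5, 1], numeric(1))
  se <- sd(draws) / sqrt(200)
  expect_lt(abs(mean(draws) - 500 * p), 3 * se + 0.5)
})

test_that("alpha diversity matches the closed-form definitions", {
  m <- cbind(u = c(1, 1, 1, 1), d = c(10, 0, 0, 0))
  rownames(m) <- paste0("f", 1:4)
  a <- alpha_diversity(m)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$evenness[1], 1, tolerance = 1e-12)
  expect_equal(a$richness[2], 1)
  expect_equal(a$shannon[2], 0)
  expect_true(is.na(a$evenness[2]))
  # random vector against the direct formula
  set.seed(62)
  v <- matrix(rpois(30, 8), 30, 1, dimnames = list(paste0("f", 1:30), "s"))
  expect_equal(alpha_diversity(v)$shannon, oracle_shannon(v), tolerance = 1e-12)
  expect_warning(alpha_diversity(cbind(m, z = c(0, 0, 0, 0))), "all-zero")
})

test_that("dissimilarities equal the brute-force pairwise loops", {
  set.seed(63)
  m <- matrix(rpois(5 * 8, 6), 5, 8,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  for (metric in c("bray_curtis", "sorensen")) {
    d <- beta_diversity(m, metric)
    fun <- if (metric == "bray_curtis") oracle_bray else oracle_sorensen
    want <- oracle_dist_matrix(m, fun)
    expect_equal(unname(d), want, tolerance = 1e-9)
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))
  }
  # identical samples -> 0; disjoint samples -> 1
  two <- cbind(a = c(3, 2, 0), b = c(3, 2, 0))
  rownames(two) <- paste0("f", 1:3)
  expect_equal(beta_diversity(two)["a", "b"], 0)
  disj <- cbind(a = c(3, 0), b = c(0, 5)); rownames(disj) <- c("f1", "f2")
  expect_equal(beta_diversity(disj)["a", "b"], 1)
})

test_that("NMDS embeds embeddable configurations at near-zero stress", {
  # three equidistant points embed exactly in 2D
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  fit3 <- suppressWarnings(nmds_ordination(d3, seed = 1, n_restarts = 5))
  expect_lt(fit3$stress, 1e-3)
  # points already in 2D with Euclidean distances
  set.seed(64)
  xy <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(xy))
  fit <- suppressWarnings(nmds_ordination(d, seed = 2, n_restarts = 10))
  expect_lt(fit$stress, 0.01)
  # determinism under a fixed seed
  fit2 <- suppressWarnings(nmds_ordination(d, seed = 2, n_restarts = 10))
  expect_identical(fit$scores, fit2$scores)
})

test_that("PERMANOVA matches its oracle, adonis2, and exhaustive permutations", {
  set.seed(65)
  m <- matrix(rpois(8 * 6, 10), 8, 6,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:6)))
  d <- beta_diversity(m)
  g <- factor(rep(c("a", "b"), each = 3))
  res <- permanova(d, g, n_perm = 99, seed = 1)
  want <- oracle_permanova_F(d, g)
  expect_equal(res$F, want$F, tolerance = 1e-9)
  expect_equal(res$R2, want$R2, tolerance = 1e-9)
  # independent cross-check against vegan's implementation
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$F, ad$F[1], tolerance = 1e-9)
  expect_equal(res$R2, ad$R2[1], tolerance = 1e-9)
  # exhaustive n=6 permutation set vs a large Monte-Carlo estimate
  ex <- permanova(d, g, permutations = all_perms(6))
  mc <- permanova(d, g, n_perm = 4999, seed = 7)
  expect_lt(abs(ex$p - mc$p), 0.05)
  # R2 invariant to relabeling within groups
  idx <- c(2, 1, 3, 6, 5, 4)
  res_perm <- permanova(d[idx, idx], g, n_perm = 9, seed = 1)
  expect_equal(res_perm$R2, res$R2, tolerance = 1e-9)
  expect_error(permanova(d, factor(c("a", "a", "a", "a", "a", "b"))), "groups")
})

test_that("PERMANOVA separates well-separated clusters decisively", {
  set.seed(66)
  base <- matrix(rpois(10 * 10, 20), 10, 10)
  base[1:5, 1:5] <- base[1:5, 1:5] + 200   # cluster signature
  dimnames(base) <- list(paste0("f", 1:10), paste0("s", 1:10))
  d <- beta_diversity(base)
  g <- factor(rep(c("a", "b"), each = 5))
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_gt(res$R2, 0.5)
  # only permutations reproducing the group partition can match F_obs
  expect_lte(res$p, 0.05)
})

test_that("envfit recovers axis-aligned variables and matches least squares", {
  set.seed(67)
  scores <- matrix(rnorm(24), 12, 2)
  v <- scores[, 1]
  fit <- envfit_vector(scores, v, n_perm = 99, seed = 1)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  # hand least-squares on a 2D toy
  v2 <- rnorm(12)
  fit2 <- envfit_vector(scores, v2, n_perm = 99, seed = 1)
  want <- summary(lm(v2 ~ scores))$r.squared
  expect_equal(fit2$r2, want, tolerance = 1e-9)
  # vegan cross-check of the squared correlation
  ef <- vegan::envfit(scores, data.frame(v = v2), permutations = 0)
  expect_equal(fit2$r2, unname(ef$vectors$r), tolerance = 1e-9)
  expect_equal(envfit_vector(scores, rep(1, 12))$r, 0)
})

test_that("rank tests behave on identical, shifted and tiny groups", {
  set.seed(68)
  same <- c(1:10, 1:10)   # identical rank profiles in both groups
  g <- rep(c("a", "b"), each = 10)
  res_same <- group_tests(same, g)
  expect_gt(res_same$kruskal$p, 0.99)
  shifted <- c(rnorm(10), rnorm(10, 3))
  res_sh <- group_tests(shifted, g)
  expect_lt(res_sh$kruskal$p, 0.01)
  expect_lt(res_sh$pairwise["b", "a"], 0.01)
  expect_warning(group_tests(c(shifted, 1), c(g, "tiny")), "excluding")
  # exact small-sample agreement with the reference implementation
  v <- c(1.2, 3.4, 2.2, 4.1, 0.5, 2.9, 3.3, 1.1)
  g2 <- rep(c("a", "b"), 4)
  res <- group_tests(v, g2)
  want <- kruskal.test(v, factor(g2))
  expect_equal(res$kruskal$statistic, unname(want$statistic), tolerance = 1e-12)
})

test_that("taxonomic rollup aggregates lineages with unassigned fallback", {
  tax <- data.frame(
    asv_id = paste0("a", 1:6),
    lineage = c("B;P1;C1;O1;F1;G1", "B;P1;C1;O1;F2;G2", "B;P1;C2;O2;F3;G3",
                "B;P2;C3;O2;F4;G4", "B;P2;C3;;F5;G5", "B;P2"))
  m <- matrix(1:12, 6, 2, dimnames = list(paste0("a", 1:6), c("s1", "s2")))
  ro <- taxonomic_rollup(m, tax, "order")
  expect_equal(ro$counts["O1", "s1"], 1 + 2)
  expect_equal(ro$counts["O2", "s1"], 3 + 4)
  expect_equal(ro$counts["unassigned", "s1"], 5 + 6)
  expect_true(all(abs(colSums(ro$relative) - 1) < 1e-12))
  single <- taxonomic_rollup(m[1:2, , drop = FALSE], tax, "order")
  expect_equal(nrow(single$counts), 1L)
  expect_error(taxonomic_rollup(m, tax, "kingdom"), "rank")
})

test_that("the diet gradient is recovered from simulated 16S data", {
  run <- small_amplicon_run()
  asv <- run$asv
  fl <- filter_contaminants(asv$counts, asv$taxonomy)
  depth <- min(colSums(fl$counts))
  rar <- rarefy_counts(fl$counts, depth, seed = 5)
  d <- beta_diversity(rar)
  dsn <- run$truth$design[match(colnames(rar), run$truth$design$sample_id), ]
  pm <- permanova(d, dsn$diet_label, n_perm = 199, seed = 5)
  expect_lt(pm$p, 0.05)
  ord <- suppressWarnings(nmds_ordination(d, seed = 5, n_restarts = 10))
  ef <- envfit_vector(ord$scores, dsn$xylan_percent, n_perm = 199, seed = 5)
  expect_lt(ef$p, 0.05)
  expect_gt(ef$r, 0)
})
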