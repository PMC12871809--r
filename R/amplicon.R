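# ---------------------------------------------------------------------------
# 16S amplicon community analysis: contaminant filtering, rarefaction,
# alpha/beta diversity, NMDS, PERMANOVA, envfit, rank tests, rollups.
# ---------------------------------------------------------------------------

#' Remove contaminant lineages from an ASV table
#'
#' Drops ASVs whose taxonomy lineage contains any blocklist term as a
#' case-insensitive substring at any rank (the classic
#' chloroplast/mitochondria/endosymbiont filter).
#'
#' @param counts ASV x sample count matrix.
#' @param taxonomy `data.frame` with `asv_id` and `lineage`
#'   (semicolon-separated ranks).
#' @param blocklist character terms to drop.
#' @return list with the filtered `counts`, `dropped_asvs` and
#'   `dropped_reads` (per-sample).
#' @export
filter_contaminants <- function(counts, taxonomy,
                                blocklist = c("chloroplast", "mitochondria",
                                              "blattabacterium")) {
  lin <- tolower(taxonomy$lineage[match(rownames(counts), taxonomy$asv_id)])
  if (anyNA(lin)) stop("taxonomy does not cover all ASVs")
  drop <- rep(FALSE, nrow(counts))
  for (term in tolower(blocklist))
    drop <- drop | grepl(term, lin, fixed = TRUE)
  list(counts = counts[!drop, , drop = FALSE],
       dropped_asvs = rownames(counts)[drop],
       dropped_reads = colSums(counts[drop, , drop = FALSE]))
}

#' Rarefy a count table to fixed depth
#'
#' Hypergeometric (without-replacement) subsampling of every sample to
#' exactly `depth` reads; samples shallower than `depth` are dropped with a
#' warning.
#'
#' @param counts feature x sample integer matrix.
#' @param depth target depth.
#' @param seed integer seed.
#' @return rarefied feature x sample matrix (column sums all `depth`).
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  shallow <- colSums(counts) < depth
  if (any(shallow)) {
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[shallow], collapse = ", "))
    counts <- counts[, !shallow, drop = FALSE]
  }
  if (ncol(counts) == 0L) return(counts)
  set.seed(seed)
  # vegan's advisory "observed counts" heuristic misfires on tables whose
  # smallest nonzero count exceeds 1; the input here is always raw counts
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  dimnames(out) <- dimnames(counts)
  out
}

#' Alpha diversity: Shannon, richness, Pielou's evenness
#'
#' Shannon uses the natural logarithm; evenness is `H / ln(S)` and is
#' reported missing for samples with one or zero observed features.
#'
#' @param counts feature x sample matrix.
#' @return `data.frame` with `sample_id`, `shannon`, `richness`, `evenness`.
#' @export
alpha_diversity <- function(counts) {
  empty <- colSums(counts) == 0
  if (any(empty))
    warning("all-zero sample(s): ",
            paste(colnames(counts)[empty], collapse = ", "))
  H <- vegan::diversity(t(counts), index = "shannon")
  S <- colSums(counts > 0)
  J <- ifelse(S > 1, H / log(S), NA_real_)
  H[empty] <- NA_real_
  data.frame(sample_id = colnames(counts), shannon = unname(H),
             richness = unname(S), evenness = unname(J),
             stringsAsFactors = FALSE)
}

#' Pairwise dissimilarity matrix
#'
#' Bray-Curtis on abundances, or the Sorensen index computed as binary
#' Bray-Curtis (identical to `1 - 2a/(2a+b+c)` on presence/absence).
#'
#' @param counts feature x sample matrix.
#' @param metric `"bray_curtis"` or `"sorensen"`.
#' @return symmetric sample x sample dissimilarity matrix, zero diagonal.
#' @export
beta_diversity <- function(counts, metric = c("bray_curtis", "sorensen")) {
  metric <- match.arg(metric)
  if (ncol(counts) < 2) stop("need at least two samples")
  d <- vegan::vegdist(t(counts), method = "bray",
                      binary = metric == "sorensen")
  as.matrix(d)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS with monotone regression, run over random
#' restarts; the best solution is returned. Seeded, so identical seeds give
#' identical scores.
#'
#' @param dissimilarity symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension.
#' @param n_restarts random restarts.
#' @param max_iter iterations per restart.
#' @param seed integer seed.
#' @return list with `scores` (samples x k), `stress` (Kruskal stress-1 in
#'   \[0, 1\]) and `converged`.
#' @export
nmds_ordination <- function(dissimilarity, k = 2, n_restarts = 20,
                            max_iter = 200, seed = 1L) {
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(dissimilarity), k = k,
                        try = n_restarts, trymax = n_restarts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  if (!fit$converged)
    warning("NMDS did not converge within ", n_restarts,
            " restarts; best solution returned")
  list(scores = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged))
}

#' Permutational multivariate analysis of variance
#'
#' Pseudo-F from the squared-dissimilarity partition: total sum of squares
#' is `sum(d_ij^2)/n` over all pairs, within-group analogously per group,
#' between = total - within. The p-value permutes group labels with the
#' add-one estimator `p = (1 + #(F* >= F)) / (1 + n_perm)`.
#'
#' @param dissimilarity sample x sample matrix (or `dist`).
#' @param groups factor of group labels, one per sample; every group needs
#'   at least two members.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param permutations optional integer matrix (rows = index permutations)
#'   for exact/exhaustive tests; overrides `n_perm`.
#' @return list with `F`, `R2`, `p`, and the degrees of freedom.
#' @export
permanova <- function(dissimilarity, groups, n_perm = 999, seed = 1L,
                      permutations = NULL) {
  d <- as.matrix(dissimilarity)
  groups <- as.factor(groups)
  n <- nrow(d)
  stopifnot(length(groups) == n)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  a <- nlevels(droplevels(groups))
  d2 <- d^2

  ss <- function(g) {
    tot <- sum(d2[upper.tri(d2)]) / n
    within <- sum(vapply(split(seq_len(n), g), function(i) {
      sub <- d2[i, i, drop = FALSE]
      sum(sub[upper.tri(sub)]) / length(i)
    }, numeric(1)))
    c(total = tot, within = within)
  }
  obs <- ss(groups)
  ss_b <- obs["total"] - obs["within"]
  f_stat <- function(sw) ((obs["total"] - sw) / (a - 1)) / (sw / (n - a))
  F_obs <- unname(f_stat(obs["within"]))
  R2 <- unname(ss_b / obs["total"])

  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  }
  F_perm <- apply(permutations, 1, function(idx)
    unname(f_stat(ss(groups[idx])["within"])))
  p <- (1 + sum(F_perm >= F_obs)) / (1 + length(F_perm))
  list(F = F_obs, R2 = R2, p = p, df = c(between = a - 1, within = n - a),
       n_perm = length(F_perm))
}

#' Fit an external variable onto ordination scores
#'
#' Regresses the centred variable on the ordination scores; the reported
#' correlation is `r = sqrt(R^2)` of that regression and the p-value
#' permutes the variable (add-one estimator). A constant variable returns
#' `r = 0, p = 1`.
#'
#' @param scores samples x k ordination score matrix.
#' @param variable numeric, one value per sample.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `r`, `r2`, `p`.
#' @export
envfit_vector <- function(scores, variable, n_perm = 999, seed = 1L) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(variable))
  v <- variable - mean(variable)
  if (all(abs(v) < 1e-12)) return(list(r = 0, r2 = 0, p = 1))
  r2_of <- function(v) {
    fit <- stats::lm.fit(cbind(1, scores), v)
    1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  }
  r2 <- r2_of(v)
  set.seed(seed)
  r2_perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(v)), numeric(1))
  list(r = sqrt(r2), r2 = r2,
       p = (1 + sum(r2_perm >= r2)) / (1 + n_perm))
}

#' Kruskal-Wallis and pairwise Wilcoxon rank-sum tests
#'
#' Standard rank statistics with mid-rank ties; pairwise p-values adjusted
#' by Holm (configurable). Groups with fewer than two members are excluded
#' with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param adjust multiplicity adjustment for the pairwise tests.
#' @return list with `kruskal` (statistic, df, p) and `pairwise`
#'   (adjusted p-value matrix).
#' @export
group_tests <- function(values, groups, adjust = "holm") {
  groups <- as.factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  kw <- stats::kruskal.test(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, groups, p.adjust.method = adjust,
                                exact = FALSE))
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p = kw$p.value),
       pairwise = pw$p.value)
}

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

#' Aggregate an ASV table at a taxonomic rank
#'
#' Sums counts by the rank's label in each ASV's lineage; ASVs without a
#' label at that rank go to `"unassigned"`. Relative abundances divide by
#' per-sample totals.
#'
#' @param counts ASV x sample matrix.
#' @param taxonomy `data.frame` with `asv_id`, `lineage`.
#' @param rank rank name (`"domain"` ... `"species"`) or index.
#' @return list with `counts` (rank x sample) and `relative` (columns sum
#'   to 1).
#' @export
taxonomic_rollup <- function(counts, taxonomy, rank = "order") {
  if (is.character(rank)) rank <- match(rank, TAXONOMIC_RANKS)
  if (is.na(rank) || rank < 1 || rank > length(TAXONOMIC_RANKS))
    stop("unknown taxonomic rank")
  lin <- taxonomy$lineage[match(rownames(counts), taxonomy$asv_id)]
  if (anyNA(lin)) stop("taxonomy does not cover all ASVs")
  parts <- strsplit(lin, ";", fixed = TRUE)
  lab <- vapply(parts, function(p)
    if (length(p) >= rank && nzchar(p[rank])) p[rank] else "unassigned",
    character(1))
  m <- rowsum(counts, lab)
  rel <- sweep(m, 2, colSums(m), "/")
  list(counts = m, relative = rel)
}
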