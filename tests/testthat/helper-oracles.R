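# Independent brute-force oracles. These deliberately share no code with
# the package: plain double loops over the definitions.

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
oracle_sorensen <- function(x, y) oracle_bray(as.numeric(x > 0), as.numeric(y > 0))

oracle_dist_matrix <- function(counts, fun) {
  n <- ncol(counts)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- fun(counts[, i], counts[, j])
  d
}

oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
    if (a == 0 && b == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_top_hits <- function(hits) {
  out <- list()
  for (r in sort(unique(hits$read_id))) {
    sub <- hits[hits$read_id == r, ]
    m <- max(sub$bitscore)
    out[[r]] <- sort(unique(sub$subject_accession[sub$bitscore == m]))
  }
  out
}

oracle_weighted_counts <- function(tophits, acc2tax, read_samples) {
  acc <- list()
  for (i in seq_len(nrow(tophits))) {
    taxa <- unique(ifelse(is.na(acc2tax[tophits$subjects[[i]]]),
                          "unclassified",
                          acc2tax[tophits$subjects[[i]]]))
    s <- read_samples$sample_id[read_samples$read_id == tophits$read_id[i]]
    for (tx in taxa) {
      k <- paste(tx, s, sep = "\r")
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + 1 / length(taxa)
    }
  }
  acc
}

oracle_cazyme <- function(counts, catalog) {
  cl <- catalog_clusters(catalog)
  fam <- list()
  for (i in seq_len(nrow(cl))) for (f in cl$cazyme_families[[i]])
    for (s in colnames(counts)) {
      k <- paste(f, s, sep = "\r")
      w <- if (cl$cluster_id[i] %in% rownames(counts))
        counts[cl$cluster_id[i], s] else 0
      fam[[k]] <- (if (is.null(fam[[k]])) 0 else fam[[k]]) + w
    }
  fam
}

oracle_pathways <- function(counts, catalog, map) {
  cl <- catalog_clusters(catalog)
  out <- list()
  for (p in unique(map$pathway)) {
    kos <- map$ko[map$pathway == p]
    for (s in colnames(counts)) {
      tot <- 0
      for (i in seq_len(nrow(cl)))
        if (any(cl$ko_ids[[i]] %in% kos) &&
            cl$cluster_id[i] %in% rownames(counts))
          tot <- tot + counts[cl$cluster_id[i], s]
      out[[paste(p, s, sep = "\r")]] <- tot
    }
  }
  out
}

oracle_pangenome_summary <- function(counts, catalog) {
  cl <- catalog_clusters(catalog)
  total <- sum(counts)
  w_ko <- w_caz <- 0
  kos <- caz <- character()
  for (i in seq_len(nrow(cl))) {
    id <- cl$cluster_id[i]
    w <- if (id %in% rownames(counts)) sum(counts[id, ]) else 0
    if (length(cl$ko_ids[[i]]) > 0) w_ko <- w_ko + w
    if (length(cl$cazyme_families[[i]]) > 0) w_caz <- w_caz + w
    if (w > 0) {
      kos <- c(kos, cl$ko_ids[[i]])
      caz <- c(caz, cl$cazyme_families[[i]])
    }
  }
  list(reads_mapped = total,
       pct_ko = 100 * w_ko / total, unique_ko = length(unique(kos)),
       pct_caz = 100 * w_caz / total, unique_caz = length(unique(caz)))
}

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# pseudo-F / R2 by direct evaluation of the squared-dissimilarity partition
oracle_permanova_F <- function(d, groups) {
  n <- nrow(d)
  sstot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) sstot <- sstot + d[i, j]^2
  sstot <- sstot / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b)
      ssw <- ssw + d[idx[a], idx[b]]^2 / length(idx)
  }
  a <- length(unique(groups))
  list(F = ((sstot - ssw) / (a - 1)) / (ssw / (n - a)),
       R2 = (sstot - ssw) / sstot)
}
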