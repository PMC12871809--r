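# ---------------------------------------------------------------------------
# Pangenome mapping: assigning tied top hits to gene clusters and building
# per-pangenome count tables plus annotation summaries.
# ---------------------------------------------------------------------------

#' Inverted accession index over a set of catalogs
#'
#' Maps each member accession to the (pangenome, cluster) pair(s) it belongs
#' to. An accession may legitimately appear in clusters of several
#' pangenomes (shared reference proteins); within one catalog that is an
#' error caught at catalog validation.
#'
#' @param catalogs list of [pangenome_catalog()] objects.
#' @return `data.frame` with columns `accession`, `pangenome`, `cluster_id`.
#' @export
build_accession_index <- function(catalogs) {
  out <- do.call(rbind, lapply(catalogs, function(ct) {
    validate_catalog(ct)
    data.frame(accession = ct$members$accession,
               pangenome = ct$pangenome_name,
               cluster_id = ct$members$cluster_id,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assign tied top hits to pangenome gene clusters
#'
#' For each read, the targets are the distinct (pangenome, cluster) pairs
#' reachable from its top-hit subjects; each target receives `1/|targets|`,
#' mirroring the taxon-level weighted split. Reads whose subjects are all
#' absent from the index are tallied as unassigned, so per sample
#' `sum(assigned weights) + unassigned` equals the number of reads with
#' hits.
#'
#' @param tophits output of [top_hits()].
#' @param index accession index from [build_accession_index()].
#' @param read_samples read to sample map.
#' @return list of class `pangenome_assignment` with `counts` (named list of
#'   clusters x samples matrices, rows covering every catalog cluster),
#'   `unassigned` and `total_reads` (per-sample vectors).
#' @export
assign_reads <- function(tophits, index, read_samples) {
  n_subj <- lengths(tophits$subjects)
  long <- data.table::data.table(
    read_id = rep(tophits$read_id, n_subj),
    accession = unlist(tophits$subjects, use.names = FALSE))
  idx <- data.table::as.data.table(index)
  read_id <- accession <- weight <- sample_id <- pangenome <- cluster_id <- NULL
  hitsx <- merge(long, idx, by = "accession", allow.cartesian = TRUE)
  hitsx <- unique(hitsx[, list(read_id, pangenome, cluster_id)])
  hitsx[, weight := 1 / .N, by = read_id]
  smap <- data.table::data.table(read_id = read_samples$read_id,
                                 sample_id = read_samples$sample_id)
  hitsx <- merge(hitsx, smap, by = "read_id", all.x = TRUE)
  agg <- hitsx[, list(w = sum(weight)),
               by = list(pangenome, cluster_id, sample_id)]

  samples <- unique(read_samples$sample_id)
  reads_per_sample <- table(factor(
    read_samples$sample_id[read_samples$read_id %in% tophits$read_id],
    levels = samples))
  assigned_reads <- unique(hitsx$read_id)
  una_tab <- read_samples[!read_samples$read_id %in% assigned_reads &
                            read_samples$read_id %in% tophits$read_id, ]
  unassigned <- table(factor(una_tab$sample_id, levels = samples))

  counts <- lapply(split(seq_len(nrow(idx)), idx$pangenome), function(rows) {
    clusters <- sort(unique(idx$cluster_id[rows]))
    m <- matrix(0, length(clusters), length(samples),
                dimnames = list(clusters, samples))
    sub <- agg[agg$pangenome == idx$pangenome[rows[1]], ]
    if (nrow(sub))
      m[cbind(match(sub$cluster_id, clusters),
              match(sub$sample_id, samples))] <- sub$w
    m
  })
  structure(list(counts = counts,
                 unassigned = setNames(as.numeric(unassigned), samples),
                 total_reads = setNames(as.numeric(reads_per_sample), samples),
                 samples = samples),
            class = "pangenome_assignment")
}

#' @export
print.pangenome_assignment <- function(x, ...) {
  tot <- vapply(x$counts, sum, numeric(1))
  cat("Pangenome assignment:", length(x$counts), "pangenomes,",
      length(x$samples), "samples\n")
  frac <- assigned_fraction(x)
  cat("  assigned fraction per sample:",
      sprintf("%.1f%%-%.1f%%", 100 * min(frac), 100 * max(frac)), "\n")
  cat("  largest pangenome:", names(tot)[which.max(tot)], "\n")
  invisible(x)
}

#' Per-sample fraction of reads assigned to any pangenome
#'
#' @param assignment a `pangenome_assignment`.
#' @return numeric vector in \[0, 1\], one entry per sample.
#' @export
assigned_fraction <- function(assignment) {
  setNames(1 - assignment$unassigned / assignment$total_reads,
           assignment$samples)
}

#' Annotation summary of one pangenome's expression
#'
#' Computes the Table-1-style summary: total weighted reads mapped, the
#' percent of that weight on clusters carrying at least one KO (resp.
#' CAZyme) annotation, and the number of distinct KO (resp. CAZyme) terms on
#' clusters with nonzero weight in any sample.
#'
#' @param counts clusters x samples matrix for one pangenome (from
#'   [assign_reads()]).
#' @param catalog the matching [pangenome_catalog()].
#' @return one-row `data.frame` with `pangenome`, `reads_mapped`,
#'   `pct_reads_with_KO`, `unique_KO`, `pct_reads_with_CAZyme`,
#'   `unique_CAZyme`.
#' @export
summarize_pangenome <- function(counts, catalog) {
  cl <- catalog_clusters(catalog)
  total <- sum(counts)
  if (total == 0) {
    warning("no reads mapped to pangenome ", catalog$pangenome_name)
    return(data.frame(pangenome = catalog$pangenome_name, reads_mapped = 0,
                      pct_reads_with_KO = 0, unique_KO = 0L,
                      pct_reads_with_CAZyme = 0, unique_CAZyme = 0L,
                      stringsAsFactors = FALSE))
  }
  w <- rowSums(counts)[cl$cluster_id]
  w[is.na(w)] <- 0
  has_ko <- lengths(cl$ko_ids) > 0
  has_caz <- lengths(cl$cazyme_families) > 0
  expressed <- w > 0
  data.frame(
    pangenome = catalog$pangenome_name,
    reads_mapped = total,
    pct_reads_with_KO = 100 * sum(w[has_ko]) / total,
    unique_KO = length(unique(unlist(cl$ko_ids[expressed]))),
    pct_reads_with_CAZyme = 100 * sum(w[has_caz]) / total,
    unique_CAZyme = length(unique(unlist(cl$cazyme_families[expressed]))),
    stringsAsFactors = FALSE
  )
}

#' Table-1-style summary across all pangenomes
#'
#' @param assignment a `pangenome_assignment`.
#' @param catalogs named list of catalogs matching `assignment$counts`.
#' @return `data.frame`, one row per pangenome, with the phylum attached.
#' @export
summarize_pangenomes <- function(assignment, catalogs) {
  out <- do.call(rbind, lapply(names(assignment$counts), function(nm) {
    s <- summarize_pangenome(assignment$counts[[nm]], catalogs[[nm]])
    s$phylum <- catalogs[[nm]]$phylum
    s
  }))
  rownames(out) <- NULL
  out[, c("pangenome", "phylum", "reads_mapped", "pct_reads_with_KO",
          "unique_KO", "pct_reads_with_CAZyme", "unique_CAZyme")]
}
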