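# ---------------------------------------------------------------------------
# Hit resolution: combining the two alignment runs per read, extracting tied
# top hits, and building weighted taxonomic count tables.
# ---------------------------------------------------------------------------

#' @import data.table
NULL

canonical_hit_order <- function(hits) {
  hits[order(hits$read_id, -hits$bitscore, hits$subject_accession,
             hits$source_db), , drop = FALSE]
}

#' Combine two alignment runs, keeping the higher-scoring hits per read
#'
#' Merges the primary-database and custom-database hit tables. For each read
#' only the hits whose bitscore equals the maximum across both runs are
#' retained (exact equality; tied hits from both runs are kept as a union).
#' Reads present in only one run pass through. Exact duplicate rows are
#' dropped, making the operation idempotent, and the output is in a
#' canonical row order so it is invariant to input row order.
#'
#' @param hits_primary,hits_custom hit tables (see [read_hit_table()]);
#'   either may be empty.
#' @return a combined hit table containing only per-read top-scoring hits.
#' @export
combine_runs <- function(hits_primary, hits_custom = NULL) {
  validate_hit_table(hits_primary)
  if (!is.null(hits_custom)) validate_hit_table(hits_custom)
  dt <- data.table::as.data.table(rbind(hits_primary, hits_custom))
  if (!nrow(dt)) return(empty_hit_table())
  bitscore <- read_id <- NULL  # NSE notes
  dt <- dt[dt[, .I[bitscore == max(bitscore)], by = read_id]$V1]
  dt <- unique(dt)
  out <- canonical_hit_order(as.data.frame(dt))
  rownames(out) <- NULL
  out
}

#' Per-read tied top-hit sets
#'
#' For every read, the set of subject accessions whose bitscore equals the
#' read's maximum. Deterministic regardless of input row order (subjects are
#' sorted, reads are sorted).
#'
#' @param hits a (combined) hit table.
#' @return `data.frame` with `read_id`, `max_bitscore` and a list-column
#'   `subjects` of character vectors.
#' @export
top_hits <- function(hits) {
  validate_hit_table(hits)
  if (!nrow(hits))
    return(data.frame(read_id = character(), max_bitscore = numeric(),
                      subjects = I(list())))
  dt <- data.table::as.data.table(hits)
  bitscore <- subject_accession <- read_id <- max_bitscore <- NULL
  mx <- dt[, list(max_bitscore = max(bitscore)), by = read_id]
  dt <- merge(dt[, list(read_id, subject_accession, bitscore)], mx,
              by = "read_id")
  top <- unique(dt[bitscore == max_bitscore,
                   list(read_id, subject_accession, max_bitscore)])
  data.table::setorder(top, read_id, subject_accession)
  first <- !duplicated(top$read_id)
  out <- data.frame(read_id = top$read_id[first],
                    max_bitscore = top$max_bitscore[first],
                    stringsAsFactors = FALSE)
  out$subjects <- I(unname(split(top$subject_accession,
                                 factor(top$read_id, levels = out$read_id))))
  out
}

#' Persist / load per-read top-hit sets
#'
#' Three-column TSV: `read_id`, subjects joined by `";"`, `max_bitscore`.
#'
#' @param tophits output of [top_hits()].
#' @param path file path.
#' @export
write_top_hits <- function(tophits, path) {
  out <- data.frame(read_id = tophits$read_id,
                    subjects = vapply(tophits$subjects, paste,
                                      character(1), collapse = ";"),
                    max_bitscore = fmt_num(tophits$max_bitscore),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_top_hits
#' @export
read_top_hits <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
  data.frame(read_id = tab$read_id,
             max_bitscore = tab$max_bitscore,
             subjects = I(strsplit(tab$subjects, ";", fixed = TRUE)))
}

#' Weighted taxonomic count table from tied top hits
#'
#' Implements the weighted split rule: for each read, let T be the set of
#' distinct taxa among its top-hit subjects (two accessions of the same
#' taxon do not dilute its weight); each taxon in T receives `1/|T|`.
#' Subjects that cannot be resolved to a taxon are treated as the
#' `"unclassified"` taxon, so mass is conserved: per sample the column sum
#' equals the number of reads with at least one top hit.
#'
#' @param tophits output of [top_hits()].
#' @param acc2tax named character vector mapping accession to taxon.
#' @param read_samples `data.frame` with `read_id`, `sample_id`.
#' @param unclassified label for unresolvable subjects.
#' @return taxa x samples numeric matrix of fractional counts.
#' @export
weighted_taxon_counts <- function(tophits, acc2tax, read_samples,
                                  unclassified = "unclassified") {
  if (!nrow(tophits))
    stop("no top hits to count")
  n_subj <- lengths(tophits$subjects)
  long <- data.table::data.table(
    read_id = rep(tophits$read_id, n_subj),
    taxon = {
      acc <- unlist(tophits$subjects, use.names = FALSE)
      tx <- unname(acc2tax[acc])
      tx[is.na(tx)] <- unclassified
      tx
    })
  taxon <- read_id <- weight <- sample_id <- NULL
  long <- unique(long)                      # distinct taxa per read
  long[, weight := 1 / .N, by = read_id]
  smap <- data.table::data.table(read_id = read_samples$read_id,
                                 sample_id = read_samples$sample_id)
  long <- merge(long, smap, by = "read_id", all.x = TRUE)
  if (anyNA(long$sample_id))
    stop("read(s) missing from the read-sample map: ",
         long$read_id[is.na(long$sample_id)][1])
  agg <- long[, list(w = sum(weight)), by = list(taxon, sample_id)]
  samples <- unique(read_samples$sample_id)
  taxa <- sort(unique(agg$taxon))
  m <- matrix(0, length(taxa), length(samples),
              dimnames = list(taxa, samples))
  m[cbind(match(agg$taxon, taxa), match(agg$sample_id, samples))] <- agg$w
  m
}

#' Rarefy weighted counts at the read level
#'
#' Weighted (fractional) counts have no direct urn model, so rarefaction is
#' performed on the retained per-read structure: `depth` reads are
#' subsampled without replacement per sample, then the weighted split is
#' rebuilt from the surviving reads. Per-sample totals after rarefaction
#' equal `depth` exactly.
#'
#' @param tophits output of [top_hits()].
#' @param acc2tax accession to taxon map.
#' @param read_samples read to sample map.
#' @param depth target reads per sample; must not exceed any sample's read
#'   count.
#' @param seed integer seed.
#' @inheritParams weighted_taxon_counts
#' @return taxa x samples weighted count matrix with column sums `depth`.
#' @export
rarefy_weighted <- function(tophits, acc2tax, read_samples, depth, seed = 1L,
                            unclassified = "unclassified") {
  set.seed(seed)
  keep_reads <- read_samples[read_samples$read_id %in% tophits$read_id, ]
  by_sample <- split(keep_reads$read_id, keep_reads$sample_id)
  short <- names(by_sample)[lengths(by_sample) < depth]
  if (length(short))
    stop("rarefaction depth ", depth, " exceeds read count in sample(s): ",
         paste(short, collapse = ", "))
  kept <- unlist(lapply(by_sample, function(r)
    if (length(r) == depth) r else sample(r, depth)), use.names = FALSE)
  sub <- tophits[tophits$read_id %in% kept, , drop = FALSE]
  weighted_taxon_counts(sub, acc2tax, keep_reads, unclassified)
}
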