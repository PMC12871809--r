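#' @importFrom stats median na.omit p.adjust prcomp setNames var aggregate
#' @importFrom utils read.delim write.table head
NULL

# canonical 12-column BLAST/DIAMOND outfmt-6 header
OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                  "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a tabular protein-alignment hit file
#'
#' Parses a BLAST/DIAMOND tabular (outfmt 6) file into a hit table. Only the
#' read id, subject accession, percent identity, e-value and bitscore are
#' retained; extra columns beyond the canonical twelve are ignored.
#'
#' @param path path to a tab-separated hit file without header, 12+ columns in
#'   the standard outfmt-6 order.
#' @param source_db label stamped on every record, one of `"primary_db"` or
#'   `"custom_db"` (which alignment database produced the hits).
#' @return a `data.frame` with columns `read_id`, `subject_accession`,
#'   `percent_identity`, `evalue`, `bitscore`, `source_db`.
#' @export
read_hit_table <- function(path, source_db = c("primary_db", "custom_db")) {
  source_db <- match.arg(source_db)
  if (!file.exists(path)) stop("hit file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty hit file: ", path)
    return(empty_hit_table(source_db))
  }
  raw <- read.delim(path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 12L)
    stop("expected >= 12 tab-separated columns (outfmt 6), got ", ncol(raw))
  names(raw)[1:12] <- OUTFMT6_COLS
  bits <- suppressWarnings(as.numeric(raw$bitscore))
  bad <- which(is.na(bits) | !is.finite(bits))
  if (length(bad))
    stop("non-numeric bitscore at line(s): ", paste(head(bad, 10L), collapse = ", "))
  out <- data.frame(
    read_id           = raw$qseqid,
    subject_accession = raw$sseqid,
    percent_identity  = as.numeric(raw$pident),
    evalue            = as.numeric(raw$evalue),
    bitscore          = bits,
    source_db         = source_db,
    stringsAsFactors  = FALSE
  )
  validate_hit_table(out)
  out
}

empty_hit_table <- function(source_db = "primary_db") {
  data.frame(read_id = character(), subject_accession = character(),
             percent_identity = numeric(), evalue = numeric(),
             bitscore = numeric(), source_db = character(),
             stringsAsFactors = FALSE)
}

validate_hit_table <- function(hits) {
  stopifnot(is.data.frame(hits))
  need <- c("read_id", "subject_accession", "bitscore", "source_db")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(hits)) {
    if (any(!nzchar(hits$read_id)) || any(!nzchar(hits$subject_accession)))
      stop("empty read_id or subject_accession in hit table")
    if (any(!is.finite(hits$bitscore)) || any(hits$bitscore < 0))
      stop("bitscores must be finite and nonnegative")
  }
  invisible(hits)
}

#' Write a hit table as 12-column outfmt-6
#'
#' Columns not carried by the in-memory table (alignment coordinates,
#' mismatches) are written as zeros; round-trips through [read_hit_table()]
#' preserve the retained fields.
#'
#' @param hits hit table as returned by [read_hit_table()].
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  validate_hit_table(hits)
  out <- data.frame(
    qseqid = hits$read_id, sseqid = hits$subject_accession,
    pident = fmt_num(hits$percent_identity), length = 0L, mismatch = 0L,
    gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
    evalue = fmt_num(hits$evalue), bitscore = fmt_num(hits$bitscore),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# 6 significant digits, plain (non-scientific where possible) formatting
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", format(signif(x, 6), scientific = FALSE, trim = TRUE))
}

CAZYME_CLASSES <- c("GH", "GT", "PL", "CE", "AA", "CBM", "SLH")

#' Class prefix of a CAZyme family label
#'
#' @param family character vector of family labels such as `"GH43"` or `"CBM6"`.
#' @return character vector of class prefixes (`GH`, `GT`, `PL`, `CE`, `AA`,
#'   `CBM`, `SLH`).
#' @export
cazyme_class <- function(family) {
  cls <- sub("^(GH|GT|PL|CE|AA|CBM|SLH).*$", "\\1", family)
  bad <- !cls %in% CAZYME_CLASSES | !nzchar(family)
  if (any(bad))
    stop("unparseable CAZyme family label(s): ",
         paste(unique(family[bad]), collapse = ", "))
  cls
}

split_multi <- function(x, delim = "|") {
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), delim, fixed = TRUE)
  lapply(out, function(v) unique(v[nzchar(v)]))
}

join_multi <- function(x, delim = "|") {
  vapply(x, function(v) paste(v, collapse = delim), character(1))
}

#' Construct a pangenome catalog
#'
#' A catalog holds the gene clusters of one (approximately genus-level)
#' pangenome: which protein accessions belong to each cluster and the
#' cluster-level COG/KO/CAZyme annotations, as exported by a pangenome
#' summary table.
#'
#' @param pangenome_name name of the pangenome (e.g. `"Bacteroides"`).
#' @param phylum phylum label used for phylum-level rollups.
#' @param members `data.frame` with columns `cluster_id`, `genome`,
#'   `accession`; one row per member protein.
#' @param annotations `data.frame` with columns `cluster_id`, `cog`, `ko`,
#'   `cazyme`; one row per cluster, multi-valued cells `"|"`-delimited,
#'   empty string for none.
#' @return an object of class `pangenome_catalog`.
#' @export
pangenome_catalog <- function(pangenome_name, phylum, members, annotations) {
  stopifnot(is.data.frame(members), is.data.frame(annotations))
  members <- members[, c("cluster_id", "genome", "accession")]
  annotations <- annotations[, c("cluster_id", "cog", "ko", "cazyme")]
  for (j in names(annotations)) annotations[[j]][is.na(annotations[[j]])] <- ""
  obj <- structure(
    list(pangenome_name = pangenome_name, phylum = phylum,
         members = members, annotations = annotations),
    class = "pangenome_catalog")
  validate_catalog(obj)
}

validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "pangenome_catalog"))
  m <- catalog$members
  a <- catalog$annotations
  if (anyDuplicated(a$cluster_id))
    stop("duplicate cluster_id in catalog ", catalog$pangenome_name)
  dup <- duplicated(paste(m$cluster_id, m$accession))
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate (cluster_id, accession) row(s) in ",
            catalog$pangenome_name)
    catalog$members <- m <- m[!dup, ]
  }
  two <- tapply(m$cluster_id, m$accession, function(x) length(unique(x)))
  if (any(two > 1L))
    stop("accession(s) mapped to more than one cluster in ", catalog$pangenome_name,
         ": ", paste(head(names(two)[two > 1L], 5L), collapse = ", "))
  if (!all(a$cluster_id %in% unique(m$cluster_id)))
    stop("annotation rows reference unknown cluster ids")
  fams <- unlist(split_multi(a$cazyme))
  if (length(fams)) cazyme_class(fams)  # errors on malformed labels
  catalog
}

#' Read a pangenome catalog summary TSV
#'
#' Expects the gene-cluster summary dialect: one row per (cluster, member
#' protein) with columns `cluster_id`, `genome`, `accession`, `cog`, `ko`,
#' `cazyme`; annotation cells may be empty or `"|"`-delimited multi-values.
#' Annotation sets are deduplicated per cluster. Duplicate (cluster,
#' accession) rows are collapsed with a warning; an accession appearing in
#' two clusters of one catalog is an error.
#'
#' @param path TSV path with header.
#' @param pangenome_name,phylum labels attached to the catalog.
#' @param delim delimiter inside multi-valued annotation cells.
#' @return a `pangenome_catalog`.
#' @export
read_pangenome_catalog <- function(path, pangenome_name, phylum = "unknown",
                                   delim = "|") {
  tab <- read.delim(path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("cluster_id", "genome", "accession", "cog", "ko", "cazyme")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("catalog missing column(s): ", paste(miss, collapse = ", "))
  ann <- tab[!duplicated(tab$cluster_id), c("cluster_id", "cog", "ko", "cazyme")]
  # deduplicate multi-valued cells (and normalise the delimiter to "|")
  for (j in c("cog", "ko", "cazyme"))
    ann[[j]] <- join_multi(split_multi(ann[[j]], delim))
  pangenome_catalog(pangenome_name, phylum,
                    members = tab[, c("cluster_id", "genome", "accession")],
                    annotations = ann)
}

#' Write a pangenome catalog summary TSV
#'
#' @param catalog a `pangenome_catalog`.
#' @param path output path.
#' @export
write_pangenome_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  a <- catalog$annotations
  i <- match(catalog$members$cluster_id, a$cluster_id)
  out <- cbind(catalog$members, a[i, c("cog", "ko", "cazyme")])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster annotation sets of a catalog
#'
#' @param catalog a `pangenome_catalog`.
#' @return `data.frame` with `cluster_id` and list-columns `accessions`,
#'   `cog_ids`, `ko_ids`, `cazyme_families`.
#' @export
catalog_clusters <- function(catalog) {
  a <- catalog$annotations
  acc <- split(catalog$members$accession, catalog$members$cluster_id)
  data.frame(
    cluster_id = a$cluster_id,
    accessions = I(unname(acc[a$cluster_id])),
    cog_ids = I(split_multi(a$cog)),
    ko_ids = I(split_multi(a$ko)),
    cazyme_families = I(split_multi(a$cazyme)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.pangenome_catalog <- function(x, ...) {
  cat("Pangenome catalog:", x$pangenome_name, "(", x$phylum, ")\n")
  cat("  clusters:", nrow(x$annotations),
      " member proteins:", nrow(x$members), "\n")
  nko <- sum(nzchar(x$annotations$ko))
  ncaz <- sum(nzchar(x$annotations$cazyme))
  cat("  clusters with KO:", nko, " with CAZyme:", ncaz, "\n")
  invisible(x)
}

#' Read / write a count matrix TSV
#'
#' Count matrices are features x samples, nonnegative, fractional values
#' allowed (weighted counts). On disk: TSV with header, first column
#' `feature_id`.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  validate_count_matrix(m)
}

#' @rdname read_count_matrix
#' @param counts numeric matrix, features x samples.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  out <- data.frame(feature_id = rownames(counts),
                    apply(counts, 2, fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("feature_id", colnames(counts))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count matrix must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs feature rownames and sample colnames")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("count matrix entries must be finite and nonnegative")
  counts
}

#' Build a per-sample diet design table
#'
#' Encodes the diet treatment of each sample: the diet label, the percent of
#' the fiber fraction that is xylan (the remainder is microcrystalline
#' cellulose), and the derived presence/absence flags used by the constrained
#' ordination models. `contains_xylan` is true iff `xylan_percent > 0`;
#' `contains_cellulose` is true iff `xylan_percent < 100`.
#'
#' @param sample_id character sample ids.
#' @param diet_label diet name per sample.
#' @param xylan_percent numeric in \[0, 100\].
#' @return `data.frame` with the flag columns added.
#' @export
diet_design <- function(sample_id, diet_label, xylan_percent) {
  stopifnot(length(sample_id) == length(diet_label),
            length(sample_id) == length(xylan_percent))
  if (any(xylan_percent < 0 | xylan_percent > 100))
    stop("xylan_percent must lie in [0, 100]")
  data.frame(sample_id = as.character(sample_id),
             diet_label = as.character(diet_label),
             xylan_percent = as.numeric(xylan_percent),
             contains_xylan = xylan_percent > 0,
             contains_cellulose = xylan_percent < 100,
             stringsAsFactors = FALSE)
}

#' @rdname diet_design
#' @param path TSV path (columns as produced by [write_design()]).
#' @export
read_design <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  d <- diet_design(tab$sample_id, tab$diet_label, tab$xylan_percent)
  if (!is.null(tab$contains_xylan) &&
      !identical(as.logical(tab$contains_xylan), d$contains_xylan))
    stop("contains_xylan flags inconsistent with xylan_percent in ", path)
  d
}

#' @rdname diet_design
#' @param design a design `data.frame`.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a CAZyme family to substrate mapping
#'
#' The dbCAN-sub style mapping from CAZyme family to the substrate(s) its
#' characterised members act on, used to tag family-level expression with
#' fiber substrates.
#'
#' @param path TSV with columns `cazyme_family`, `substrate`
#'   (`"|"`-delimited multi-values).
#' @return named list: family -> character vector of substrates.
#' @export
read_substrate_map <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab$cazyme_family)) stop("duplicate families in substrate map")
  subs <- split_multi(tab$substrate)
  if (any(lengths(subs) == 0L)) stop("empty substrate set in substrate map")
  setNames(subs, tab$cazyme_family)
}

#' @rdname read_substrate_map
#' @param map named list, family -> substrates.
#' @export
write_substrate_map <- function(map, path) {
  out <- data.frame(cazyme_family = names(map), substrate = join_multi(map),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Percent label of a two-fiber ratio diet
#'
#' Diets mixing the two fibers in a w:w ratio are referred to by the rounded
#' percentage of the majority fiber, e.g. a 6:1 mix is the "86%" diet and a
#' 3:1 mix the "75%" diet.
#'
#' @param ratio_major,ratio_minor positive parts of the mixing ratio.
#' @return integer percent, `round(100 * major / (major + minor))`.
#' @export
diet_percent_label <- function(ratio_major, ratio_minor) {
  if (any(ratio_major <= 0) || any(ratio_minor <= 0))
    stop("ratio parts must be positive")
  as.integer(round(100 * ratio_major / (ratio_major + ratio_minor)))
}

#' Validate a design against a count matrix
#'
#' Report-only consistency check: sample agreement between metadata and
#' matrix, and the internal flag invariants of the design.
#'
#' @param design diet design `data.frame`.
#' @param counts features x samples count matrix.
#' @return list with `ok` (logical) and `messages` (character).
#' @export
validate_design <- function(design, counts) {
  msgs <- character()
  miss <- setdiff(colnames(counts), design$sample_id)
  if (length(miss))
    msgs <- c(msgs, paste("sample(s) in matrix missing from metadata:",
                          paste(miss, collapse = ", ")))
  extra <- setdiff(design$sample_id, colnames(counts))
  if (length(extra))
    msgs <- c(msgs, paste("metadata sample(s) absent from matrix:",
                          paste(extra, collapse = ", ")))
  if (anyDuplicated(design$sample_id))
    msgs <- c(msgs, "duplicate sample ids in metadata")
  bad_x <- design$contains_xylan != (design$xylan_percent > 0)
  if (any(bad_x))
    msgs <- c(msgs, paste("contains_xylan flag inconsistent for:",
                          paste(design$sample_id[bad_x], collapse = ", ")))
  bad_c <- design$contains_cellulose != (design$xylan_percent < 100)
  if (any(bad_c))
    msgs <- c(msgs, paste("contains_cellulose flag inconsistent for:",
                          paste(design$sample_id[bad_c], collapse = ", ")))
  list(ok = length(msgs) == 0L, messages = msgs)
}

#' Reporting arithmetic helpers
#'
#' Small helpers for the summary numbers quoted in sequencing reports.
#' `annotated_fraction()` is the percentage of consensus read pairs whose
#' translation received a protein annotation. `mean_read_depth()` is the
#' average per-sample read depth, reported as whole reads (truncated, the
#' convention of sequencing summaries). `remaining_fraction()` is the percent
#' dry weight left for the fiber source once the fixed base ingredients of a
#' synthetic diet are accounted for.
#'
#' @param n_annotated,n_total annotated and total read(-pair) counts.
#' @return a single number on the percent (or read) scale.
#' @export
annotated_fraction <- function(n_annotated, n_total) {
  stopifnot(n_total > 0, n_annotated >= 0, n_annotated <= n_total)
  100 * n_annotated / n_total
}

#' @rdname annotated_fraction
#' @param total_reads summed reads across samples.
#' @param n_samples number of samples.
#' @export
mean_read_depth <- function(total_reads, n_samples) {
  stopifnot(n_samples > 0)
  floor(total_reads / n_samples)
}

#' @rdname annotated_fraction
#' @param base_percents percent dry weight of each non-fiber ingredient.
#' @export
remaining_fraction <- function(base_percents) {
  out <- 100 - sum(base_percents)
  if (out < 0) stop("base ingredients exceed 100%")
  out
}
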