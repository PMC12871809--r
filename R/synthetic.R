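# ---------------------------------------------------------------------------
# Synthetic community generator
#
# Emulates the statistical structure the downstream analysis assumes: a
# diet gradient from pure microcrystalline cellulose (MCC) to pure xylan,
# taxa whose (log) abundance responds linearly or saturatingly to the xylan
# fraction, two-database alignment hits with tied top scores, gene clusters
# carrying 0-2 CAZyme families and 0-1 KEGG ortholog, and a cross-feeding
# coupling in which the xylosidase output of secondary fermenters tracks the
# realised endo-xylanase output of the primary degraders.
# ---------------------------------------------------------------------------

# 17 pangenomes with phylum groupings; baseline log-abundance and xylan
# response chosen to mirror the qualitative ranking of activity and the
# direction of the diet response reported for each organism.
PANGENOME_INFO <- data.frame(
  taxon_id = c("Alistipes", "Bacteroides", "Dysgonomonas", "Odoribacter",
               "Paludibacteraceae", "Parabacteroides",
               "Clostridiaceae", "Enterococcaceae", "Lachnospiraceae A",
               "Lachnospiraceae B", "Lachnospiraceae C",
               "Oscillospiraceae 1", "Oscillospiraceae 2",
               "Desulfovibrio", "Desulfosarcina", "Fibrobacterota",
               "Fusobacterium"),
  phylum = c(rep("Bacteroidota", 6), rep("Bacillota", 7),
             "Desulfobacterota", "Desulfobacterota", "Fibrobacterota",
             "Fusobacterota"),
  base_log_abundance = c(1.6, 3.0, 1.6, 0.9, 0.6, 1.8,
                         2.4, 0.9, 2.0, 1.7, 1.4, 0.6, 1.2,
                         1.9, 0.7, 0.3, 0.5),
  xylan_slope = c(0.3, 1.5, 1.2, -0.8, -1.0, 0.8,
                  1.0, 0.8, 1.2, 1.0, 1.0, -0.6, -0.6,
                  -0.5, -0.8, -2.5, 0),
  response = c(rep("linear", 6), rep("saturating", 7),
               rep("linear", 4)),
  stringsAsFactors = FALSE
)

# CAZyme family pools and marker KOs per functional role
ROLE_FAMILIES <- list(
  endo_xylanase = c("GH43", "GH10", "GH30", "GH11", "GH98", "GH26", "GH141"),
  xylosidase    = c("GH3", "GH2", "GH120"),
  cellulase     = c("GH9", "GH94", "GH48", "GH74", "GH5"),
  sidechain     = c("GH115", "GH67", "GH51", "GH95", "GH4"),
  glycosyl_mod  = c("GT2", "GT4", "GT35", "CE1", "SLH")
)
ROLE_KOS <- list(
  endo_xylanase = c("K01181", "K15924", "K01198"),
  xylosidase    = "K01811",
  cellulase     = c("K01179", "K00702", "K05349", "K05350"),
  sidechain     = c("K01235", "K01209", "K15921"),
  xylose_util   = c("K01805", "K00854", "K01804", "K00853", "K03077"),
  glycosyl_mod  = c("K00963", "K00975", "K00688"),
  housekeeping  = c("K00844", "K01810", "K00850", "K01623", "K00134",
                    "K00927", "K01689", "K00873", "K01915", "K00265",
                    "K01586", "K00290", "K01955", "K00812", "K01714",
                    "K00003", "K00133", "K01738", "K00928", "K00600")
)
# log-rate slope per unit xylan fraction, by role (MCC-responding roles
# negative; the Bacillota xylosidase slope is 0 because its diet response
# comes entirely from the cross-feeding coupling)
ROLE_SLOPES <- c(endo_xylanase = 1.5, xylosidase = 1.0, cellulase = -2.0,
                 sidechain = 1.2, xylose_util = 1.5, glycosyl_mod = 0,
                 housekeeping = 0, unannotated = 0)

xylan_response <- function(xylan_percent, response) {
  n <- max(length(xylan_percent), length(response))
  x <- rep_len(xylan_percent, n)
  r <- rep_len(response, n)
  ifelse(r == "saturating", (1 - exp(-x / 20)) / (1 - exp(-5)), x / 100)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode
#' the study conditions emulated throughout: a 16S experiment of 6 diets x
#' 10 insects spanning xylan percentages \{0, 14, 25, 75, 86, 100\} and a
#' metatranscriptome experiment of 5 diets x 6 insects spanning
#' \{0, 14, 50, 86, 100\}, log-normal read depths, a 30% chance of a tied
#' second top hit per read, 30% of reads best-resolved by the custom
#' single-cell-genome database, and 20% of transcripts originating outside
#' the 17 catalogued pangenomes.
#'
#' @param meta_xylan_percents,meta_replicates metatranscriptome design.
#' @param amplicon_xylan_percents,amplicon_replicates 16S design.
#' @param depth_meanlog,depth_sdlog log-normal read depth of a
#'   metatranscriptome sample (desk-scale).
#' @param amplicon_depth_meanlog,amplicon_depth_sdlog log-normal 16S depth
#'   (mean about 45,000 reads).
#' @param tie_probability probability a read carries a tied-bitscore second
#'   top hit.
#' @param custom_db_fraction fraction of reads whose best hit lives in the
#'   custom database at a higher bitscore than their primary-database hit.
#' @param offcatalog_rate fraction of reads from organisms outside all
#'   catalogs (drives the unassigned tally).
#' @param contaminant_fraction expected read share of contaminant lineages
#'   (chloroplast/mitochondria/endosymbiont) in the 16S table.
#' @param abundance_sigma per-sample log-abundance noise sd.
#' @param nb_dispersion negative-binomial dispersion used where counts are
#'   overdispersed.
#' @param n_clusters gene clusters per pangenome catalog.
#' @param asvs_per_taxon range of ASVs owned by one taxon.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(meta_xylan_percents = c(0, 14, 50, 86, 100),
                              meta_replicates = 6,
                              amplicon_xylan_percents = c(0, 14, 25, 75, 86, 100),
                              amplicon_replicates = 10,
                              depth_meanlog = log(20000), depth_sdlog = 0.4,
                              amplicon_depth_meanlog = log(40000),
                              amplicon_depth_sdlog = 0.5,
                              tie_probability = 0.3,
                              custom_db_fraction = 0.3,
                              offcatalog_rate = 0.2,
                              contaminant_fraction = 0.05,
                              abundance_sigma = 0.3,
                              nb_dispersion = 0.1,
                              n_clusters = 40,
                              asvs_per_taxon = c(1L, 5L)) {
  cfg <- as.list(environment())
  probs <- c(tie_probability, custom_db_fraction, offcatalog_rate,
             contaminant_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (depth_sdlog < 0 || amplicon_depth_sdlog < 0 || abundance_sigma < 0)
    stop("spread parameters must be nonnegative")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (any(meta_xylan_percents < 0 | meta_xylan_percents > 100) ||
      any(amplicon_xylan_percents < 0 | amplicon_xylan_percents > 100))
    stop("xylan percents must lie in [0, 100]")
  structure(cfg, class = "sim_config")
}

diet_label_for <- function(xylan_percent) {
  ifelse(xylan_percent == 0, "MCC",
  ifelse(xylan_percent == 100, "xylan",
  ifelse(xylan_percent == 50, "50% mix",
  ifelse(xylan_percent < 50, paste0(100 - xylan_percent, "% MCC"),
         paste0(xylan_percent, "% xylan")))))
}

build_gradient_design <- function(xylan_percents, replicates, prefix) {
  xp <- rep(xylan_percents, each = replicates)
  id <- sprintf("%s%02d", prefix, seq_along(xp))
  diet_design(id, diet_label_for(xp), xp)
}

#' Experiment designs of the synthetic study
#'
#' @param config a [simulation_config()].
#' @return a diet design `data.frame` (see [diet_design()]).
#' @export
meta_design <- function(config = simulation_config()) {
  build_gradient_design(config$meta_xylan_percents, config$meta_replicates, "M")
}

#' @rdname meta_design
#' @export
amplicon_design <- function(config = simulation_config()) {
  build_gradient_design(config$amplicon_xylan_percents,
                        config$amplicon_replicates, "A")
}

#' Generate the default pangenome catalogs
#'
#' Builds one catalog per pangenome with `n_clusters` gene clusters each.
#' Clusters are given a functional role according to the phylum's ecology:
#' Bacteroidota catalogs are rich in endo-xylanase and side-chain-removal
#' clusters, Bacillota in xylosidase and xylose-utilisation clusters,
#' Fibrobacterota in cellulases, and the sulfate reducers plus
#' Fusobacterium mostly carry glycosyl-modification and housekeeping genes.
#' Each cluster has 2-4 member accessions, at most one KO, and 0-2 CAZyme
#' families (a second family is added with probability 0.3, exercising the
#' overcount rule).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; catalogs are deterministic given the seed.
#' @return named list of [pangenome_catalog()] objects.
#' @export
default_catalogs <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_clusters
  out <- vector("list", nrow(PANGENOME_INFO))
  names(out) <- PANGENOME_INFO$taxon_id
  for (i in seq_len(nrow(PANGENOME_INFO))) {
    name <- PANGENOME_INFO$taxon_id[i]
    phylum <- PANGENOME_INFO$phylum[i]
    roles <- catalog_roles(phylum, n)
    tag <- gsub("[^A-Za-z0-9]", "", name)
    cluster_id <- sprintf("%s_GC%03d", tag, seq_len(n))
    ko <- character(n); caz <- character(n)
    role_seen <- integer(0)
    for (k in seq_len(n)) {
      r <- roles[k]
      role_seen[r] <- if (is.na(role_seen[r])) 1L else role_seen[r] + 1L
      if (r %in% names(ROLE_KOS) && r != "unannotated") {
        pool <- ROLE_KOS[[r]]
        ko[k] <- if (r == "housekeeping") sample(pool, 1L) else
          pool[(role_seen[r] - 1L) %% length(pool) + 1L]
      }
      if (r %in% names(ROLE_FAMILIES)) {
        # cycle through the role's family pool so marker families (GH43,
        # GH94, GH3, ...) are guaranteed present in every catalog
        pool <- ROLE_FAMILIES[[r]]
        fams <- pool[(role_seen[r] - 1L) %% length(pool) + 1L]
        if (runif(1) < 0.3)
          fams <- unique(c(fams, sample(c("CBM6", "CBM22", "CBM4"), 1L)))
        caz[k] <- paste(fams, collapse = "|")
      }
    }
    n_acc <- sample(2:4, n, replace = TRUE)
    members <- data.frame(
      cluster_id = rep(cluster_id, n_acc),
      genome = paste0(tag, "_g", unlist(lapply(n_acc, sample.int, n = 5L))),
      accession = sprintf("WP_%s_%03d_%d", tag,
                          rep(seq_len(n), n_acc),
                          unlist(lapply(n_acc, seq_len))),
      stringsAsFactors = FALSE
    )
    ann <- data.frame(cluster_id = cluster_id, cog = "", ko = ko, cazyme = caz,
                      stringsAsFactors = FALSE)
    cat_obj <- pangenome_catalog(name, phylum, members, ann)
    attr(cat_obj, "roles") <- setNames(roles, cluster_id)
    out[[i]] <- cat_obj
  }
  out
}

catalog_roles <- function(phylum, n) {
  fixed <- switch(phylum,
    Bacteroidota = c(rep("endo_xylanase", 4), rep("sidechain", 3),
                     rep("xylosidase", 2), "cellulase", rep("xylose_util", 2)),
    Bacillota = c(rep("xylosidase", 4), rep("xylose_util", 3),
                  "endo_xylanase", "cellulase", "sidechain"),
    Fibrobacterota = c(rep("cellulase", 5), "endo_xylanase", "xylose_util"),
    c(rep("glycosyl_mod", 3), "xylose_util"))  # sulfate reducers, Fusobacterium
  free <- n - length(fixed)
  if (free < 0) stop("n_clusters too small for the role template")
  n_hk <- round(0.75 * free)
  c(fixed, rep("housekeeping", n_hk), rep("unannotated", free - n_hk))
}

#' Simulate the latent community truth
#'
#' Draws per-sample relative abundances for the 17 pangenome taxa and the
#' per-(taxon, cluster) expression intensities that the read simulators
#' consume. The log abundance of taxon t in sample s is
#' `base + slope * f(xylan_s) + Normal(0, sigma)` with `f` linear in the
#' xylan fraction or saturating (Bacillota default), softmax-normalised over
#' taxa. Cluster expression rates follow the cluster's functional role, and
#' the xylosidase rate of Bacillota clusters is multiplied by the realised
#' endo-xylanase output of their cross-feeding source (Bacteroides),
#' normalised to mean one across samples.
#'
#' @param config a [simulation_config()].
#' @param catalogs catalogs from [default_catalogs()] (must carry role
#'   attributes).
#' @param seed integer seed; the truth is deterministic given the seed.
#' @param design experiment design; defaults to the metatranscriptome design.
#' @param taxa taxon table (`taxon_id`, `phylum`, `base_log_abundance`,
#'   `xylan_slope`, `response`); defaults to the 17 shipped pangenome taxa.
#'   Overriding it (e.g. zeroing slopes) supports null-case checks.
#' @return list of class `community_truth` with elements `taxa`, `design`,
#'   `abundance` (taxa x samples, columns sum to 1), `rules` (expression
#'   rules) and `intensity` (rules x samples expected read intensity).
#' @export
simulate_community <- function(config = simulation_config(),
                               catalogs = default_catalogs(config, seed),
                               seed = 1L,
                               design = meta_design(config),
                               taxa = PANGENOME_INFO) {
  set.seed(seed + 1L)
  stopifnot(all(names(catalogs) %in% taxa$taxon_id))
  ns <- nrow(design)
  f <- vapply(seq_len(nrow(taxa)), function(i)
    xylan_response(design$xylan_percent, taxa$response[i]),
    numeric(ns))                       # samples x taxa
  loga <- t(taxa$base_log_abundance + t(f) * taxa$xylan_slope) +
    matrix(rnorm(ns * nrow(taxa), 0, config$abundance_sigma), ns)
  ab <- exp(loga)
  ab <- t(ab / rowSums(ab))            # taxa x samples, columns sum to 1
  dimnames(ab) <- list(taxa$taxon_id, design$sample_id)

  rules <- do.call(rbind, lapply(names(catalogs), function(nm) {
    roles <- attr(catalogs[[nm]], "roles")
    if (is.null(roles)) stop("catalog ", nm, " lacks role attributes")
    data.frame(taxon_id = nm, cluster_id = names(roles), role = unname(roles),
               stringsAsFactors = FALSE)
  }))
  rules$base_rate <- stats::rlnorm(nrow(rules), meanlog = 0, sdlog = 1)
  rules$xylan_slope <- ROLE_SLOPES[rules$role]
  phy <- taxa$phylum[match(rules$taxon_id, taxa$taxon_id)]
  rules$crossfeed_source <- ifelse(
    phy == "Bacillota" & rules$role == "xylosidase", "Bacteroides", NA)

  # Fiber-responsive expression follows a mildly saturating gradient
  # (70% linear in xylan fraction + 30% saturating): the fiber response is
  # detectable already at the lowest inclusion level, while the numeric
  # percent remains the dominant signal.
  x <- design$xylan_percent
  f_rule <- 0.7 * xylan_response(x, "linear") +
    0.3 * xylan_response(x, "saturating")
  fr <- matrix(f_rule, nrow(rules), ns, byrow = TRUE)
  rate <- rules$base_rate * exp(rules$xylan_slope * fr)   # rules x samples

  # realised endo output of the cross-feeding source scales secondary rates
  src <- "Bacteroides"
  endo <- rules$taxon_id == src & rules$role == "endo_xylanase"
  e_out <- ab[src, ] * colSums(rate[endo, , drop = FALSE])
  scale <- e_out / mean(e_out)
  cf <- !is.na(rules$crossfeed_source)
  rate[cf, ] <- rate[cf, , drop = FALSE] *
    rep(scale, each = sum(cf))
  rules$xylan_slope <- unname(rules$xylan_slope)

  intensity <- rate * ab[rules$taxon_id, , drop = FALSE]
  structure(list(taxa = taxa, design = design, abundance = ab,
                 rules = rules, intensity = intensity,
                 crossfeed_scale = scale),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("Synthetic community truth:", nrow(x$taxa), "taxa,",
      ncol(x$abundance), "samples,", nrow(x$rules), "expression rules\n")
  cat("  diets:", paste(unique(x$design$diet_label), collapse = ", "), "\n")
  invisible(x)
}

CONTAMINANT_LINEAGES <- data.frame(
  genus = c("Chloroplast", "Mitochondria", "Blattabacterium"),
  lineage = c(
    "Eukaryota;Cyanobacteria;Cyanobacteriia;Chloroplast;Chloroplast;Chloroplast",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rickettsiales;Mitochondria;Mitochondria",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Blattabacteriaceae;Blattabacterium"),
  stringsAsFactors = FALSE
)

#' Simulate a 16S ASV count table
#'
#' Each taxon owns 1-5 ASVs with fixed within-taxon proportions; per sample
#' the read depth is drawn log-normal and reads are a single multinomial
#' draw over ASVs. A configurable fraction of reads comes from contaminant
#' lineages (chloroplast, mitochondria, *Blattabacterium*) so the
#' contaminant filter can be tested against known truth.
#'
#' @param truth a `community_truth` built on the amplicon design.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `counts` (ASV x sample integer matrix), `taxonomy`
#'   (`asv_id`, `lineage` with semicolon-separated ranks), `asv_truth`
#'   (ASV to taxon map with contaminant flags) and `depths`.
#' @export
simulate_asv_table <- function(truth, config = simulation_config(), seed = 1L) {
  set.seed(seed + 2L)
  design <- truth$design
  taxa <- truth$taxa
  k <- sample(seq(config$asvs_per_taxon[1], config$asvs_per_taxon[2]),
              nrow(taxa), replace = TRUE)
  asv_tax <- rep(taxa$taxon_id, k)
  w <- unlist(lapply(k, function(m) {
    g <- stats::rgamma(m, 2); g / sum(g)
  }))
  asv_id <- sprintf("ASV%03d", seq_along(asv_tax))
  n_cont <- if (config$contaminant_fraction > 0) 12L else 0L
  cont_tax <- if (n_cont) rep(CONTAMINANT_LINEAGES$genus, length.out = n_cont)
              else character()
  cont_id <- sprintf("ASV%03d", length(asv_tax) + seq_len(n_cont))
  cont_w <- if (n_cont) { g <- stats::rgamma(n_cont, 2); g / sum(g) } else numeric()

  p_comm <- truth$abundance[asv_tax, , drop = FALSE] * w
  p_comm <- t(t(p_comm) / colSums(p_comm))
  cf <- config$contaminant_fraction
  p <- rbind(p_comm * (1 - cf), matrix(cont_w * cf, n_cont, ncol(p_comm)))
  rownames(p) <- c(asv_id, cont_id)

  depths <- pmax(50L, as.integer(round(stats::rlnorm(
    nrow(design), config$amplicon_depth_meanlog, config$amplicon_depth_sdlog))))
  counts <- vapply(seq_len(nrow(design)), function(s)
    stats::rmultinom(1, depths[s], p[, s])[, 1], integer(nrow(p)))
  dimnames(counts) <- list(rownames(p), design$sample_id)

  lineage <- c(
    sprintf("Bacteria;%s;%sia;%s;%s;%s",
            taxa$phylum[match(asv_tax, taxa$taxon_id)],
            taxa$phylum[match(asv_tax, taxa$taxon_id)],
            paste0(gsub("[^A-Za-z]", "", asv_tax), "ales"),
            paste0(gsub("[^A-Za-z]", "", asv_tax), "aceae"),
            asv_tax),
    CONTAMINANT_LINEAGES$lineage[match(cont_tax, CONTAMINANT_LINEAGES$genus)]
  )
  taxonomy <- data.frame(asv_id = rownames(p), lineage = lineage,
                         stringsAsFactors = FALSE)
  asv_truth <- data.frame(asv_id = rownames(p),
                          taxon_id = c(asv_tax, cont_tax),
                          contaminant = c(rep(FALSE, length(asv_tax)),
                                          rep(TRUE, n_cont)),
                          stringsAsFactors = FALSE)
  list(counts = counts, taxonomy = taxonomy, asv_truth = asv_truth,
       depths = setNames(depths, design$sample_id))
}

#' Simulate two-database alignment hit tables
#'
#' Per sample, reads draw a source (taxon, gene cluster) proportionally to
#' the truth's expression intensity (or an off-catalog origin at
#' `offcatalog_rate`) and emit one top hit to an accession of that cluster.
#' With probability `tie_probability` a second, tied-bitscore hit to another
#' draw from the same distribution is added. A `custom_db_fraction` of reads
#' have their top hit(s) placed in the custom-database table while the
#' primary-database table keeps a strictly lower-scoring decoy; the
#' remaining reads keep their top hit in the primary table with an optional
#' lower-scoring custom decoy.
#'
#' @param truth a `community_truth`.
#' @param catalogs the catalogs the truth was built on.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with hit tables `primary` and `custom`, `read_samples`
#'   (read to sample map), `read_truth` (read-level source truth),
#'   `acc2tax` (accession to taxon map covering decoy accessions) and
#'   `depths`.
#' @export
simulate_hits <- function(truth, catalogs, config = simulation_config(),
                          seed = 1L) {
  set.seed(seed + 3L)
  rules <- truth$rules
  all_members <- do.call(rbind, lapply(catalogs, function(ct)
    data.frame(taxon_id = ct$pangenome_name, ct$members,
               stringsAsFactors = FALSE)))
  key <- paste(all_members$taxon_id, all_members$cluster_id)
  rule_key <- paste(rules$taxon_id, rules$cluster_id)
  if (!all(rule_key %in% key))
    stop("expression rule references unknown cluster: ",
         rule_key[!rule_key %in% key][1])
  acc_by_rule <- split(all_members$accession, factor(key, levels = rule_key))

  n_off_acc <- 50L
  off_acc <- sprintf("OFF_%03d", seq_len(n_off_acc))
  off_tax <- paste0("other_", rep_len(1:5, n_off_acc))
  acc2tax <- c(setNames(all_members$taxon_id, all_members$accession),
               setNames(off_tax, off_acc))

  design <- truth$design
  depths <- pmax(200L, as.integer(round(stats::rlnorm(
    nrow(design), config$depth_meanlog, config$depth_sdlog))))

  res <- lapply(seq_len(nrow(design)), function(s) {
    n <- depths[s]
    read_id <- sprintf("%s_r%06d", design$sample_id[s], seq_len(n))
    off <- stats::runif(n) < config$offcatalog_rate
    ridx <- rep(NA_integer_, n)
    n_in <- sum(!off)
    if (n_in)
      ridx[!off] <- sample.int(nrow(rules), n_in, replace = TRUE,
                               prob = truth$intensity[, s])
    top_acc <- character(n)
    top_acc[off] <- sample(off_acc, sum(off), replace = TRUE)
    top_acc[!off] <- vapply(acc_by_rule[ridx[!off]], function(a)
      a[sample.int(length(a), 1L)], character(1))
    bit <- sample(100:300, n, replace = TRUE)

    tie <- stats::runif(n) < config$tie_probability
    tidx <- rep(NA_integer_, n)
    tie_in <- tie  # tied partner always drawn from the catalog distribution
    if (any(tie_in))
      tidx[tie_in] <- sample.int(nrow(rules), sum(tie_in), replace = TRUE,
                                 prob = truth$intensity[, s])
    tie_acc <- rep(NA_character_, n)
    tie_acc[tie_in] <- vapply(acc_by_rule[tidx[tie_in]], function(a)
      a[sample.int(length(a), 1L)], character(1))

    custom <- stats::runif(n) < config$custom_db_fraction
    decoy_acc <- sample(names(acc2tax), n, replace = TRUE)

    hit <- function(rid, acc, b, db) data.frame(
      read_id = rid, subject_accession = acc,
      percent_identity = rep(90, length(rid)),
      evalue = rep(1e-10, length(rid)), bitscore = b,
      source_db = rep(db, length.out = length(rid)),
      stringsAsFactors = FALSE)

    top_rows <- rbind(
      hit(read_id, top_acc, bit, NA),
      hit(read_id[tie], tie_acc[tie], bit[tie], NA))
    top_rows$custom <- custom[match(top_rows$read_id, read_id)]
    primary <- rbind(
      top_rows[!top_rows$custom, 1:6],
      hit(read_id[custom], decoy_acc[custom], bit[custom] - 20, NA))
    custom_tab <- rbind(
      top_rows[top_rows$custom, 1:6],
      hit(read_id[!custom][seq_len(floor(sum(!custom) / 2))],
          decoy_acc[!custom][seq_len(floor(sum(!custom) / 2))],
          bit[!custom][seq_len(floor(sum(!custom) / 2))] - 20, NA))
    primary$source_db <- "primary_db"
    custom_tab$source_db <- "custom_db"
    list(primary = primary, custom = custom_tab,
         read_samples = data.frame(read_id = read_id,
                                   sample_id = design$sample_id[s],
                                   stringsAsFactors = FALSE),
         read_truth = data.frame(
           read_id = read_id, sample_id = design$sample_id[s],
           taxon_id = ifelse(off, acc2tax[top_acc], rules$taxon_id[ridx]),
           cluster_id = ifelse(off, NA_character_, rules$cluster_id[ridx]),
           off_catalog = off, stringsAsFactors = FALSE))
  })
  list(primary = do.call(rbind, lapply(res, `[[`, "primary")),
       custom = do.call(rbind, lapply(res, `[[`, "custom")),
       read_samples = do.call(rbind, lapply(res, `[[`, "read_samples")),
       read_truth = do.call(rbind, lapply(res, `[[`, "read_truth")),
       acc2tax = acc2tax,
       depths = setNames(depths, design$sample_id))
}
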