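# ---------------------------------------------------------------------------
# Functional aggregation: CAZyme families/classes/substrates, KEGG level-3
# pathway rollups, and phylum-level enzymatic-step contributions.
# ---------------------------------------------------------------------------

#' Aggregate gene-cluster counts to CAZyme families and classes
#'
#' Family count = sum of cluster weights over clusters carrying that family.
#' A cluster with more than one associated CAZyme family is deliberately
#' overcounted: it contributes its full weight to each of its families (so
#' the family total can exceed the CAZyme-annotated cluster total). Class
#' tallies sum families by class prefix (GH, GT, PL, CE, AA, CBM, SLH).
#'
#' @param counts clusters x samples matrix for one pangenome.
#' @param catalog the matching [pangenome_catalog()].
#' @return list of class `cazyme_profile` with `family` and `class`
#'   (matrices x samples) and `annotated_total` (per-sample weight on
#'   CAZyme-annotated clusters, the overcount lower bound).
#' @export
aggregate_cazyme <- function(counts, catalog) {
  cl <- catalog_clusters(catalog)
  fams <- cl$cazyme_families
  keep <- lengths(fams) > 0
  ids <- cl$cluster_id[keep]
  fam_long <- data.frame(
    cluster_id = rep(ids, lengths(fams[keep])),
    family = unlist(fams[keep]),
    stringsAsFactors = FALSE)
  cazyme_class(unique(fam_long$family))  # errors on malformed labels
  w <- counts[fam_long$cluster_id, , drop = FALSE]
  family <- rowsum(w, fam_long$family)
  family <- family[order(rownames(family)), , drop = FALSE]
  cls <- rowsum(family, cazyme_class(rownames(family)))
  annotated <- counts[intersect(ids, rownames(counts)), , drop = FALSE]
  structure(list(family = family, class = cls,
                 annotated_total = colSums(annotated)),
            class = "cazyme_profile")
}

#' Tag family-level expression with substrates
#'
#' @param profile a `cazyme_profile`.
#' @param substrate_map named list from [read_substrate_map()].
#' @return `data.frame` with one row per (family, substrate), carrying the
#'   family's total weight; families absent from the map get substrate
#'   `"unknown"`.
#' @export
cazyme_substrates <- function(profile, substrate_map) {
  fams <- rownames(profile$family)
  subs <- substrate_map[fams]
  subs[vapply(subs, is.null, logical(1))] <- list("unknown")
  data.frame(
    cazyme_family = rep(fams, lengths(subs)),
    substrate = unlist(subs, use.names = FALSE),
    total_weight = rep(rowSums(profile$family), lengths(subs)),
    stringsAsFactors = FALSE)
}

#' Default fiber-targeting glycoside hydrolase panel
#'
#' Family groups used to chart cellulose- and xylan-active GH expression
#' across the diet gradient: cellulases, xylanases, dual-activity families,
#' side-chain removal, endo-xylanases and xylosidases.
#'
#' @return named list of character vectors of GH family labels.
#' @export
default_fiber_panel <- function() {
  list(
    cellulase      = c("GH94", "GH9", "GH74", "GH48"),
    xylanase       = c("GH98", "GH43", "GH30", "GH11", "GH10"),
    dual_activity  = c("GH8", "GH5", "GH39"),
    sidechain      = c("GH115", "GH67", "GH4", "GH51", "GH95"),
    endo_xylanase  = c("GH141", "GH98", "GH43", "GH30", "GH26", "GH11", "GH10"),
    xylosidase     = c("GH3", "GH2", "GH120")
  )
}

#' Diet-level shares of fiber-active GH families
#'
#' For each (pangenome, family, diet) cell, the share of the diet's total
#' transcripts carried by that family in that pangenome. By default counts
#' are pooled across a diet's samples before normalising
#' (`sum(family) / sum(all transcripts)`); `per_sample_mean = TRUE` instead
#' averages per-sample shares.
#'
#' @param profiles named list of `cazyme_profile` objects, one per pangenome.
#' @param design diet design covering the samples.
#' @param sample_totals named per-sample total transcript counts (all
#'   pangenomes, i.e. whole-sample denominators).
#' @param panel named list of family groups; defaults to
#'   [default_fiber_panel()].
#' @param per_sample_mean average per-sample shares instead of pooling.
#' @return long `data.frame`: `group`, `family`, `pangenome`, `diet_label`,
#'   `share` (families absent from a profile are reported with share 0).
#' @export
fiber_panel <- function(profiles, design, sample_totals,
                        panel = default_fiber_panel(),
                        per_sample_mean = FALSE) {
  diets <- unique(design$diet_label)
  rows <- list()
  for (g in names(panel)) for (fam in panel[[g]]) for (pg in names(profiles)) {
    m <- profiles[[pg]]$family
    fam_counts <- if (fam %in% rownames(m)) m[fam, ] else
      setNames(numeric(ncol(m)), colnames(m))
    for (d in diets) {
      s <- design$sample_id[design$diet_label == d]
      tot <- sample_totals[s]
      if (all(tot == 0)) {
        warning("diet ", d, " has zero transcripts; share undefined")
        share <- NA_real_
      } else if (per_sample_mean) {
        share <- mean(fam_counts[s] / tot)
      } else {
        share <- sum(fam_counts[s]) / sum(tot)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, family = fam, pangenome = pg, diet_label = d,
        share = share, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll gene-cluster counts up to KEGG level-3 pathways
#'
#' Pathway weight = sum of cluster weights over clusters whose KO set
#' intersects the pathway's KO list; a KO belonging to k pathways
#' contributes the cluster's weight to all k (deliberate multi-membership).
#' Two normalisations are attached: the pathway's share of the whole
#' sample's transcripts and its share of the pangenome's transcripts in
#' that sample.
#'
#' @param counts clusters x samples matrix for one pangenome.
#' @param catalog the matching catalog.
#' @param ko_pathway_map `data.frame` with columns `pathway`, `ko`
#'   (many-to-many).
#' @param sample_totals named per-sample whole-sample transcript totals.
#' @return list of class `pathway_profile` with `counts`,
#'   `share_of_sample`, `share_of_pangenome` (pathway x samples matrices).
#' @export
aggregate_pathways <- function(counts, catalog, ko_pathway_map,
                               sample_totals) {
  cl <- catalog_clusters(catalog)
  kos <- cl$ko_ids
  keep <- lengths(kos) > 0
  ko_long <- data.frame(cluster_id = rep(cl$cluster_id[keep],
                                         lengths(kos[keep])),
                        ko = unlist(kos[keep]), stringsAsFactors = FALSE)
  mrg <- merge(ko_long, ko_pathway_map, by = "ko")
  # a cluster whose KOs hit a pathway via several KOs still counts once
  mrg <- unique(mrg[, c("cluster_id", "pathway")])
  pw <- sort(unique(ko_pathway_map$pathway))
  m <- matrix(0, length(pw), ncol(counts),
              dimnames = list(pw, colnames(counts)))
  if (nrow(mrg)) {
    w <- counts[mrg$cluster_id, , drop = FALSE]
    agg <- rowsum(w, mrg$pathway)
    m[rownames(agg), ] <- agg
  }
  pg_tot <- colSums(counts)
  tot <- sample_totals[colnames(counts)]
  structure(list(
    counts = m,
    share_of_sample = sweep(m, 2, ifelse(tot > 0, tot, NA), "/"),
    share_of_pangenome = sweep(m, 2, ifelse(pg_tot > 0, pg_tot, NA), "/")),
    class = "pathway_profile")
}

#' Default enzymatic-step specification
#'
#' Editable KO lists for the named fiber-degradation and pentose-entry
#' steps used in phylum-level contribution charts. The KO membership is
#' provisional (curated from the activities named in the study of these
#' steps) and is meant to be replaced by a full curated table where
#' available.
#'
#' @return `data.frame` with columns `step_id`, `ko_ids` (`"|"`-delimited).
#' @export
default_step_spec <- function() {
  data.frame(
    step_id = c("endoglucanase", "beta_glucosidase", "cellobiose_phosphorylase",
                "endo_xylanase", "xylosidase", "xylose_isomerase",
                "xylulokinase", "arabinose_removal", "arabinose_conversion",
                "glucuronidase"),
    ko_ids = c("K01179", "K05349|K05350", "K00702",
               "K01181|K15924|K01198", "K01811", "K01805",
               "K00854", "K01209|K15921", "K01804|K00853|K03077",
               "K01235"),
    stringsAsFactors = FALSE)
}

#' Phylum-level enzymatic-step contributions and diet fold changes
#'
#' For each enzymatic step (a curated KO list): the step's relative
#' abundance per diet is the mean over that diet's samples of
#' (step weight / total transcripts in the sample); the phylum pie
#' fractions pool step weights over the diet's samples and divide by the
#' pooled step total; the fold change between the two diets is the larger
#' relative abundance over the smaller, with a direction flag. The two
#' summaries deliberately use the two different averaging conventions
#' (per-sample mean vs pooled weights).
#'
#' @param assignment a `pangenome_assignment` covering all pangenomes.
#' @param catalogs matching named list of catalogs (phylum labels used).
#' @param design diet design.
#' @param sample_totals named per-sample whole-sample transcript totals.
#' @param step_spec `data.frame` from [default_step_spec()] (or edited).
#' @param diet_pair length-2 character, the two diets to contrast.
#' @return list with `steps` (per-step relative abundances, fold change and
#'   direction; `fold_change` is `Inf` with `direction` flagged when one
#'   diet has zero weight, and steps absent in both diets are marked
#'   `absent`) and `phylum_fractions` (long `data.frame`: step, diet,
#'   phylum, fraction; fractions sum to 1 where the step has weight).
#' @export
step_contributions <- function(assignment, catalogs, design, sample_totals,
                               step_spec = default_step_spec(),
                               diet_pair = c("MCC", "xylan")) {
  stopifnot(length(diet_pair) == 2, all(diet_pair %in% design$diet_label))
  kos_by_step <- split_multi(step_spec$ko_ids)
  names(kos_by_step) <- step_spec$step_id

  # per (pangenome, step, sample) weight
  long <- list()
  for (nm in names(assignment$counts)) {
    cl <- catalog_clusters(catalogs[[nm]])
    counts <- assignment$counts[[nm]]
    for (st in names(kos_by_step)) {
      hit <- vapply(cl$ko_ids, function(k) any(k %in% kos_by_step[[st]]),
                    logical(1))
      ids <- intersect(cl$cluster_id[hit], rownames(counts))
      w <- if (length(ids)) colSums(counts[ids, , drop = FALSE])
           else setNames(numeric(ncol(counts)), colnames(counts))
      long[[length(long) + 1L]] <- data.frame(
        pangenome = nm, phylum = catalogs[[nm]]$phylum, step_id = st,
        sample_id = names(w), weight = unname(w), stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)

  steps <- lapply(names(kos_by_step), function(st) {
    rel <- vapply(diet_pair, function(d) {
      s <- design$sample_id[design$diet_label == d]
      per_sample <- vapply(s, function(sm)
        sum(long$weight[long$step_id == st & long$sample_id == sm]) /
          sample_totals[[sm]], numeric(1))
      mean(per_sample)
    }, numeric(1))
    if (all(rel == 0))
      return(data.frame(step_id = st, rel_a = 0, rel_b = 0,
                        fold_change = NA_real_, direction = "absent",
                        stringsAsFactors = FALSE))
    if (any(rel == 0)) {
      fold <- Inf
      dir <- diet_pair[which.max(rel)]
    } else {
      fold <- max(rel) / min(rel)
      dir <- if (rel[1] == rel[2]) "equal" else diet_pair[which.max(rel)]
    }
    data.frame(step_id = st, rel_a = rel[1], rel_b = rel[2],
               fold_change = fold, direction = dir, stringsAsFactors = FALSE)
  })
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  names(steps)[names(steps) == "rel_a"] <- paste0("rel_", diet_pair[1])
  names(steps)[names(steps) == "rel_b"] <- paste0("rel_", diet_pair[2])

  pie <- list()
  for (d in diet_pair) {
    s <- design$sample_id[design$diet_label == d]
    sub <- long[long$sample_id %in% s, ]
    pooled <- aggregate(weight ~ step_id + phylum, data = sub, FUN = sum)
    pooled <- pooled[pooled$weight > 0, ]
    for (st in names(kos_by_step)) {
      p <- pooled[pooled$step_id == st, ]
      tot <- sum(p$weight)
      if (tot > 0)
        pie[[length(pie) + 1L]] <- data.frame(
          step_id = st, diet_label = d, phylum = p$phylum,
          fraction = p$weight / tot, stringsAsFactors = FALSE)
    }
  }
  list(steps = steps,
       phylum_fractions = if (length(pie)) do.call(rbind, pie) else
         data.frame(step_id = character(), diet_label = character(),
                    phylum = character(), fraction = numeric()))
}
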