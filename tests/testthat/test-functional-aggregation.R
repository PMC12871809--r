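test_that("CAZyme aggregation overcounts multi-family clusters by design", {
  ct <- toy_catalog()  # GC1: GH43; GC2: GH43|CBM6
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("GC1", "GC2"), "s1"))
  prof <- aggregate_cazyme(counts, ct)
  expect_equal(prof$family["GH43", "s1"], 20)
  expect_equal(prof$family["CBM6", "s1"], 10)
  expect_equal(prof$class["GH", "s1"], 20)
  expect_equal(prof$class["CBM", "s1"], 10)
  # overcount inequality: family mass >= CAZyme-annotated cluster mass
  expect_gte(sum(prof$family), sum(prof$annotated_total))

  # brute-force double loop on a random 15-cluster toy
  set.seed(41)
  ct2 <- random_catalog("Cz", n_clusters = 15)
  m <- matrix(rpois(15 * 4, 6), 15,
              dimnames = list(ct2$annotations$cluster_id, paste0("s", 1:4)))
  prof2 <- aggregate_cazyme(m, ct2)
  want <- oracle_cazyme(m, ct2)
  for (k in names(want)) {
    parts <- strsplit(k, "\r")[[1]]
    expect_equal(prof2$family[parts[1], parts[2]], want[[k]],
                 tolerance = 1e-9)
  }
  # equality iff every cluster is single-family
  ct3 <- random_catalog("Sf", n_clusters = 15, single_family = TRUE)
  m3 <- matrix(rpois(15 * 2, 6), 15,
               dimnames = list(ct3$annotations$cluster_id, paste0("s", 1:2)))
  prof3 <- aggregate_cazyme(m3, ct3)
  expect_equal(colSums(prof3$family), prof3$annotated_total)
})

test_that("fiber panel shares pool counts within diets", {
  ct <- toy_catalog("P1", clusters = list(
    GC1 = list(acc = "x1", ko = "", caz = "GH43")))
  counts <- matrix(c(5, 15), 1, 2, dimnames = list("GC1", c("s1", "s2")))
  prof <- aggregate_cazyme(counts, ct)
  design <- diet_design(c("s1", "s2"), c("xylan", "xylan"), c(100, 100))
  totals <- c(s1 = 5, s2 = 15)
  # single family carrying all counts: share 1; absent families: 0
  pan <- fiber_panel(list(P1 = prof), design, totals)
  expect_equal(pan$share[pan$family == "GH43" & pan$group == "xylanase"], 1)
  expect_true(all(pan$share[pan$family == "GH94"] == 0))

  # pooled shares are invariant to splitting a sample into two half-weight
  # samples of the same diet
  counts_split <- matrix(c(5, 7.5, 7.5), 1, 3,
                         dimnames = list("GC1", c("s1", "s2a", "s2b")))
  prof_s <- aggregate_cazyme(counts_split, ct)
  design_s <- diet_design(c("s1", "s2a", "s2b"), rep("xylan", 3),
                          rep(100, 3))
  totals_s <- c(s1 = 5, s2a = 7.5, s2b = 7.5)
  pan_s <- fiber_panel(list(P1 = prof_s), design_s, totals_s)
  expect_equal(pan_s$share, pan$share)

  # per-sample-mean mode differs when shares are heterogeneous
  totals2 <- c(s1 = 10, s2 = 15)
  pooled <- fiber_panel(list(P1 = prof), design, totals2)
  bymean <- fiber_panel(list(P1 = prof), design, totals2,
                        per_sample_mean = TRUE)
  g <- pooled$family == "GH43" & pooled$group == "xylanase"
  expect_equal(pooled$share[g], 20 / 25)
  expect_equal(bymean$share[g], mean(c(0.5, 1)))
})

test_that("pathway rollup honors multi-membership and conserves 1:1 mass", {
  ct <- toy_catalog("Kp", clusters = list(
    GC1 = list(acc = "k1", ko = "K00010", caz = ""),
    GC2 = list(acc = "k2", ko = "K00020", caz = ""),
    GC3 = list(acc = "k3", ko = "", caz = "")))
  counts <- matrix(c(5, 7, 3), 3, 1,
                   dimnames = list(c("GC1", "GC2", "GC3"), "s1"))
  map <- data.frame(pathway = c("P1", "P2", "P2"),
                    ko = c("K00010", "K00010", "K00020"))
  pp <- aggregate_pathways(counts, ct, map, c(s1 = 20))
  # KO in two pathways contributes to both; no-KO cluster to none
  expect_equal(pp$counts["P1", "s1"], 5)
  expect_equal(pp$counts["P2", "s1"], 12)
  expect_equal(pp$share_of_sample["P2", "s1"], 12 / 20)
  expect_equal(pp$share_of_pangenome["P2", "s1"], 12 / 15)

  # one-to-one map conserves KO-annotated mass exactly
  map11 <- data.frame(pathway = c("A", "B"), ko = c("K00010", "K00020"))
  pp11 <- aggregate_pathways(counts, ct, map11, c(s1 = 20))
  expect_equal(sum(pp11$counts), 12)

  # random toy against the exhaustive oracle
  set.seed(51)
  ct2 <- random_catalog("Kx", n_clusters = 12)
  m <- matrix(rpois(12 * 3, 4), 12,
              dimnames = list(ct2$annotations$cluster_id, paste0("s", 1:3)))
  kos <- unique(unlist(catalog_clusters(ct2)$ko_ids))
  map2 <- data.frame(pathway = sample(c("P1", "P2", "P3"), length(kos) * 2,
                                      replace = TRUE),
                     ko = rep(kos, 2))
  map2 <- unique(map2)
  pp2 <- aggregate_pathways(m, ct2, map2, setNames(colSums(m) + 5,
                                                   colnames(m)))
  want <- oracle_pathways(m, ct2, map2)
  for (k in names(want)) {
    parts <- strsplit(k, "\r")[[1]]
    expect_equal(pp2$counts[parts[1], parts[2]], want[[k]], tolerance = 1e-9)
  }
})

test_that("step contributions compute per-diet shares, pies and folds", {
  # hand-computed toy: 2 phyla, 2 diets, printed weights
  ctA <- toy_catalog("StA", phylum = "Bacteroidota", clusters = list(
    GC1 = list(acc = "sa1", ko = "K01181", caz = ""),   # endo-xylanase
    GC2 = list(acc = "sa2", ko = "K01179", caz = "")))  # endoglucanase
  ctB <- toy_catalog("StB", phylum = "Bacillota", clusters = list(
    GC3 = list(acc = "sb1", ko = "K01811", caz = "")))  # xylosidase
  cats <- list(StA = ctA, StB = ctB)
  design <- diet_design(c("s1", "s2"), c("MCC", "xylan"), c(0, 100))
  counts <- list(
    StA = matrix(c(2, 8, 12, 4), 2, 2,
                 dimnames = list(c("GC1", "GC2"), c("s1", "s2"))),
    StB = matrix(c(4, 6), 1, 2, dimnames = list("GC3", c("s1", "s2"))))
  asg <- structure(list(counts = counts,
                        unassigned = c(s1 = 0, s2 = 0),
                        total_reads = c(s1 = 14, s2 = 22),
                        samples = c("s1", "s2")),
                   class = "pangenome_assignment")
  totals <- c(s1 = 20, s2 = 20)
  sc <- step_contributions(asg, cats, design, totals,
                           diet_pair = c("MCC", "xylan"))
  st <- sc$steps
  # endo-xylanase: rel MCC = 2/20, rel xylan = 12/20 -> fold 6 toward xylan
  ex <- st[st$step_id == "endo_xylanase", ]
  expect_equal(ex$rel_MCC, 0.1)
  expect_equal(ex$rel_xylan, 0.6)
  expect_equal(ex$fold_change, 6)
  expect_equal(ex$direction, "xylan")
  # endoglucanase: 8/20 vs 4/20 -> fold 2 toward MCC
  eg <- st[st$step_id == "endoglucanase", ]
  expect_equal(eg$fold_change, 2)
  expect_equal(eg$direction, "MCC")
  # step expressed by a single phylum: pie fraction 1
  pie <- sc$phylum_fractions
  expect_equal(pie$fraction[pie$step_id == "xylosidase" &
                              pie$diet_label == "xylan"], 1)
  # phylum fractions sum to 1 wherever a step has weight
  sums <- tapply(pie$fraction, paste(pie$step_id, pie$diet_label), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # absent step flagged; equal abundances give fold 1
  expect_equal(st$direction[st$step_id == "beta_glucosidase"], "absent")
  counts$StB <- matrix(c(4, 4), 1, 2, dimnames = list("GC3", c("s1", "s2")))
  asg$counts <- counts
  sc2 <- step_contributions(asg, cats, design, totals,
                            diet_pair = c("MCC", "xylan"))
  expect_equal(sc2$steps$fold_change[sc2$steps$step_id == "xylosidase"], 1)
  expect_equal(sc2$steps$direction[sc2$steps$step_id == "xylosidase"],
               "equal")
})
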