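# Shared fixtures built in code; heavy simulations are memoised so several
# test files can reuse one run.

hit_row <- function(read, acc, bit, db = "primary_db") {
  data.frame(read_id = read, subject_accession = acc, percent_identity = 90,
             evalue = 1e-10, bitscore = bit, source_db = db,
             stringsAsFactors = FALSE)
}

toy_catalog <- function(name = "ToyA", phylum = "Bacteroidota",
                        clusters = list(
                          GC1 = list(acc = c("a1", "a2"), ko = "K00001",
                                     caz = "GH43"),
                          GC2 = list(acc = "a3", ko = "",
                                     caz = "GH43|CBM6"))) {
  members <- do.call(rbind, lapply(names(clusters), function(id)
    data.frame(cluster_id = id, genome = paste0(name, "_g1"),
               accession = clusters[[id]]$acc, stringsAsFactors = FALSE)))
  ann <- do.call(rbind, lapply(names(clusters), function(id)
    data.frame(cluster_id = id, cog = "", ko = clusters[[id]]$ko,
               cazyme = clusters[[id]]$caz, stringsAsFactors = FALSE)))
  pangenome_catalog(name, phylum, members, ann)
}

random_catalog <- function(name, n_clusters = 10, phylum = "Bacteroidota",
                           single_family = FALSE) {
  fams <- c("GH43", "GH10", "GH3", "GH9", "GT2", "CBM6")
  clusters <- setNames(lapply(seq_len(n_clusters), function(i) {
    nf <- if (single_family) 1L else sample(0:2, 1)
    list(acc = sprintf("%s_a%d_%d", name, i, seq_len(sample(1:3, 1))),
         ko = if (runif(1) < 0.6) sprintf("K%05d", sample(1:30, 1)) else "",
         caz = paste(sample(fams, nf), collapse = "|"))
  }), sprintf("%s_GC%02d", name, seq_len(n_clusters)))
  toy_catalog(name, phylum, clusters = clusters)
}

# tiny all-defaults-but-small config used by most pipeline tests
small_config <- function(...) {
  defaults <- list(meta_replicates = 3, depth_meanlog = log(1500),
                   depth_sdlog = 0.2, amplicon_replicates = 4,
                   amplicon_depth_meanlog = log(4000),
                   amplicon_depth_sdlog = 0.3, n_clusters = 12)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

small_meta_run <- function() memo("small_meta", {
  cfg <- small_config()
  cats <- default_catalogs(cfg, seed = 7)
  truth <- simulate_community(cfg, cats, seed = 7)
  sim <- simulate_hits(truth, cats, cfg, seed = 7)
  th <- top_hits(combine_runs(sim$primary, sim$custom))
  idx <- build_accession_index(cats)
  asg <- assign_reads(th, idx, sim$read_samples)
  list(cfg = cfg, cats = cats, truth = truth, sim = sim, th = th,
       idx = idx, asg = asg)
})

small_amplicon_run <- function() memo("amplicon_small", {
  cfg <- small_config()
  cats <- default_catalogs(cfg, seed = 13)
  truth <- simulate_community(cfg, cats, seed = 13,
                              design = amplicon_design(cfg))
  asv <- simulate_asv_table(truth, cfg, seed = 13)
  list(cfg = cfg, truth = truth, asv = asv)
})

paper_shaped_run <- function() memo("paper_shaped", {
  cfg <- simulation_config()
  cats <- default_catalogs(cfg, seed = 11)
  truth <- simulate_community(cfg, cats, seed = 11)
  sim <- simulate_hits(truth, cats, cfg, seed = 11)
  th <- top_hits(combine_runs(sim$primary, sim$custom))
  idx <- build_accession_index(cats)
  asg <- assign_reads(th, idx, sim$read_samples)
  list(cfg = cfg, cats = cats, truth = truth, sim = sim, th = th,
       idx = idx, asg = asg)
})

# all permutations of 1..n (for exhaustive permutation tests; n <= 7)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
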