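# Shipped mapping tables (editable TSV copies live in inst/extdata)

#' Shipped CAZyme substrate map
#'
#' A curated subset of a dbCAN-sub style family-to-substrate mapping
#' covering the fiber-active families used by the default panel and the
#' synthetic catalogs.
#'
#' @return named list, family -> character vector of substrates.
#' @export
default_substrate_map <- function() {
  read_substrate_map(system.file("extdata", "substrate_map.tsv",
                                 package = "pangrove", mustWork = TRUE))
}

#' Shipped KO to level-3 pathway map
#'
#' A curated subset of KEGG ortholog to level-3 pathway memberships for
#' carbohydrate and amino acid metabolism; deliberately many-to-many (a KO
#' may sit in several pathways). Meant to be replaced by a full map where
#' available.
#'
#' @return `data.frame` with columns `pathway`, `ko`.
#' @export
default_ko_pathway_map <- function() {
  read.delim(system.file("extdata", "ko_pathway_map.tsv",
                         package = "pangrove", mustWork = TRUE),
             header = TRUE, stringsAsFactors = FALSE)
}

#' Shipped enzymatic-step specification (TSV copy)
#'
#' Reads the editable TSV copy of [default_step_spec()].
#'
#' @param path TSV path; defaults to the shipped copy.
#' @return `data.frame` with columns `step_id`, `ko_ids`.
#' @export
read_step_spec <- function(path = system.file("extdata", "step_spec.tsv",
                                              package = "pangrove",
                                              mustWork = TRUE)) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
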