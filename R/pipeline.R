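# One-call convenience wrapper tying the stages together.

#' Run the full neighborhood-analysis pipeline on one gene table
#'
#' Convenience wrapper: operon prediction, divergon detection, domain
#' annotation, architecture strings, TA-dyad detection, context
#' classification and the domain-context network, with the package
#' defaults at every stage.
#'
#' @param genes Gene tibble ([read_genbank()] / [generate_genome()]).
#' @param library A [domain_library()].
#' @param max_gap Operon intergenic-distance threshold (nt).
#' @param max_head_gap Divergon head-gap threshold (nt).
#' @param toxin_domains,antitoxin_domains Role sets for
#'   [detect_ta_dyads()].
#' @param rules Category rules for [classify_context()].
#' @return List: `operons`, `divergons`, `architectures`, `dyads`,
#'   `contexts`, `network`.
#' @examples
#' gnm <- generate_genome(genome_plan(seed = 3, n_background_genes = 6,
#'   elements = list(ta_dyad(gap_nt = 40))))
#' lib <- domain_library(sentinel_detector("MNT", sentinel_for("MNT")),
#'                       sentinel_detector("HEPN", sentinel_for("HEPN")))
#' res <- analyze_genome(gnm$genes, lib)
#' res$dyads
#' @export
analyze_genome <- function(genes, library, max_gap = 100, max_head_gap = 300,
                           toxin_domains = "HEPN", antitoxin_domains = "MNT",
                           rules = default_category_rules()) {
  assert_genes_df(genes)
  operons <- predict_operons(genes, max_gap = max_gap)
  divergons <- find_divergons(genes, max_head_gap = max_head_gap)
  archs <- architectures(genes, library)
  dyads <- detect_ta_dyads(operons, archs, genes,
                           toxin_domains = toxin_domains,
                           antitoxin_domains = antitoxin_domains)
  contexts <- classify_context(operons, archs, rules = rules)
  network <- build_network(archs, operons)
  list(operons = operons, divergons = divergons, architectures = archs,
       dyads = dyads, contexts = contexts, network = network)
}

#' Domain library covering a synthetic genome's planted domains
#'
#' Builds the sentinel library matching every domain label planted in a
#' generated genome's truth table, so the pipeline can be closed over the
#' generator.
#'
#' @param genome A `hepn_genome` from [generate_genome()].
#' @return A [domain_library()] of sentinel detectors.
#' @export
truth_library <- function(genome) {
  stopifnot(inherits(genome, "hepn_genome"))
  labels <- unique(unlist(strsplit(genome$truth$domains[genome$truth$domains != ""],
                                   ",", fixed = TRUE)))
  if (length(labels) == 0) stop("genome has no planted domains", call. = FALSE)
  domain_library(purrr::map(sort(labels), ~ sentinel_detector(.x, sentinel_for(.x))))
}
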