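# Context-graph construction, collapsing, export and layout.

test_that("fusion edges follow polypeptide adjacency", {
  g <- build_network(tibble::tibble(protein_id = "p1", architecture = "A+B+C"))
  e <- tidy(g)
  expect_equal(nrow(e), 2)
  expect_true(all(e$type == "fusion"))
  expect_true(all(e$weight == 1))
  expect_setequal(paste(e$from, e$to), c("A B", "B C"))  # never (A,C)
})

test_that("neighborhood edges connect domains of different genes in one operon", {
  arch <- tibble::tibble(protein_id = c("g1", "g2"), architecture = c("A", "D"))
  ops <- tibble::tibble(operon_id = "op1", contig_id = "c", strand = "+",
                        gene_ids = list(c("g1", "g2")), n_genes = 2L,
                        start = 0L, end = 100L, wraps_origin = FALSE)
  g <- build_network(arch, ops)
  e <- tidy(g)
  expect_equal(e$type, "neighborhood")
  expect_equal(paste(e$from, e$to), "A D")
  expect_equal(e$weight, 1L)
  # a single multidomain gene in a singleton operon gets no neighborhood edge
  g2 <- build_network(tibble::tibble(protein_id = "g1", architecture = "A+B"),
                      tibble::tibble(operon_id = "op1", contig_id = "c",
                                     strand = "+", gene_ids = list("g1"),
                                     n_genes = 1L, start = 0L, end = 10L,
                                     wraps_origin = FALSE))
  expect_true(all(tidy(g2)$type == "fusion"))
})

test_that("an empty input yields an empty graph", {
  g <- build_network(tibble::tibble(protein_id = character(),
                                    architecture = character()))
  expect_equal(nrow(tidy(g)), 0)
  expect_equal(nrow(g$nodes), 0)
})

test_that("edge weights equal the brute-force recount on synthetic datasets", {
  for (seed in c(41, 42, 43)) {
    gnm <- generate_genome(genome_plan(seed = seed, n_background_genes = 12,
      elements = list(ta_dyad(), operon_element(c("Methylase", "REase", "HEPN"),
                                                c(30, 60)),
                      fusion_element(c("MNT", "HEPN")),
                      fusion_element(c("AbiV", "HEPN", "TerD")))))
    res <- analyze_genome(gnm$genes, truth_library(gnm))
    e <- tidy(res$network)
    want <- oracle_network_weights(res$architectures, res$operons)
    expect_equal(sum(e$weight[e$type == "fusion"]), want$fusion)
    expect_equal(sum(e$weight[e$type == "neighborhood"]), want$neighborhood)
  }
})

test_that("collapsing by category merges weights and conserves the total", {
  arch <- tibble::tibble(protein_id = c("p1", "p2"),
                         architecture = c("Methylase+HEPN", "REase+HEPN"))
  g <- build_network(arch)
  cg <- collapse_by_category(g, c(Methylase = "R-M", REase = "R-M",
                                  HEPN = "HEPN"))
  e <- tidy(cg)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 2L)  # two R-M domains each linked once to HEPN
  expect_setequal(c(e$from, e$to), c("HEPN", "R-M"))

  idg <- collapse_by_category(g, setNames(g$nodes$name, g$nodes$name))
  expect_equal(tidy(idg), tidy(g)[names(tidy(idg))])

  allg <- collapse_by_category(g, setNames(rep("X", nrow(g$nodes)), g$nodes$name))
  ae <- tidy(allg)
  expect_equal(nrow(allg$nodes), 1)
  expect_true(all(ae$from == ae$to))  # self-loops only
  expect_equal(sum(ae$weight), sum(tidy(g)$weight))
})

test_that("graph exports round-trip and have the stated shapes", {
  arch <- tibble::tibble(protein_id = c("p1", "p2"),
                         architecture = c("A+B", "B+C"))
  g <- build_network(arch)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(ig), nrow(tidy(g)))
  ed <- igraph::as_data_frame(ig)
  expect_setequal(ed$type, "fusion")
  expect_equal(sort(ed$weight), sort(tidy(g)$weight))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_graph(g, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(tidy(g)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, tsv, "edge-tsv")
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), nrow(tidy(g)))

  empty <- build_network(tibble::tibble(protein_id = character(),
                                        architecture = character()))
  export_graph(empty, gml, "graphml")
  expect_equal(igraph::ecount(igraph::read_graph(gml, format = "graphml")), 0)
  expect_error(export_graph(g, tsv, "dot"))
})

test_that("spring layout is deterministic, centres singletons, spaces pairs", {
  single <- build_network(tibble::tibble(protein_id = "p", architecture = "A"))
  # single node, no edges
  xy <- layout_spring(single, seed = 1)
  expect_equal(unlist(xy[c("x", "y")]), c(x = 0, y = 0))

  pair <- build_network(tibble::tibble(protein_id = "p", architecture = "A+B"))
  xy2 <- layout_spring(pair, seed = 3)
  d <- sqrt(diff(xy2$x)^2 + diff(xy2$y)^2)
  expect_gte(d, 0.5)
  expect_lte(d, 2.0)  # two-node spring settles near its target length

  arch <- tibble::tibble(protein_id = c("p1", "p2", "p3"),
                         architecture = c("A+B+C", "C+D", "E+F"))
  g <- build_network(arch)
  a <- layout_spring(g, seed = 7)
  b <- layout_spring(g, seed = 7)
  expect_identical(a, b)
  # disconnected components occupy distinct grid cells
  expect_gt(max(dist(cbind(a$x, a$y))), 1)
})

test_that("autoplot returns a ggplot without evaluation errors", {
  g <- build_network(tibble::tibble(protein_id = c("p1", "p2"),
                                    architecture = c("MNT+HEPN", "HEPN+TerD")))
  p <- autoplot(g)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})
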