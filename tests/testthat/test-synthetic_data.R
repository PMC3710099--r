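# Generator determinism, planted-element geometry, motif planting and
# profile-driven families.

test_that("a ta_dyad plants two co-directional genes with the antitoxin 5'", {
  gnm <- generate_genome(genome_plan(seed = 5, n_background_genes = 0,
                                     elements = list(ta_dyad(gap_nt = 30))))
  g <- gnm$genes[order(gnm$genes$start), ]
  expect_equal(nrow(g), 2)
  expect_equal(g$strand[1], g$strand[2])
  expect_equal(g$start[2] - g$end[1], 30)
  tr <- gnm$truth
  anti <- tr$gene_id[tr$role == "antitoxin"]
  tox <- tr$gene_id[tr$role == "toxin"]
  # 5' gene in the strand frame: left on '+', right on '-'
  five_prime <- if (g$strand[1] == "+") g$gene_id[1] else g$gene_id[2]
  expect_equal(anti, five_prime)
  expect_false(tox == five_prime)
})

test_that("antitoxin stays 5' on the minus strand", {
  gnm <- generate_genome(genome_plan(seed = 6, n_background_genes = 0,
                                     elements = list(ta_dyad(gap_nt = 20, strand = "-"))))
  g <- gnm$genes[order(gnm$genes$start), ]
  tr <- gnm$truth
  expect_equal(g$strand, c("-", "-"))
  expect_equal(tr$role[match(g$gene_id, tr$gene_id)], c("toxin", "antitoxin"))
})

test_that("a plan of only background genes yields all-background truth", {
  gnm <- generate_genome(genome_plan(seed = 9, n_background_genes = 10))
  expect_equal(nrow(gnm$genes), 10)
  expect_true(all(gnm$truth$role == "background"))
})

test_that("identical plan and seed give byte-identical GenBank output", {
  plan <- genome_plan(seed = 77, n_background_genes = 8,
                      elements = list(operon_element(c("A1", "B2"), 40),
                                      divergon_element()))
  f1 <- withr::local_tempfile(fileext = ".gbk")
  f2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(generate_genome(plan)$genes, f1)
  write_genbank(generate_genome(plan)$genes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible and out-of-range plans are rejected", {
  expect_error(genome_plan(seed = 1, elements = list(ta_dyad(gap_nt = -60))),
               "-50")
  expect_error(genome_plan(seed = 1, elements = list(ta_dyad(gap_nt = 6000))),
               "5000")
  # a -50 nt overlap on 300 nt genes is feasible and must not error
  gnm <- generate_genome(genome_plan(seed = 2, n_background_genes = 0,
                                     elements = list(ta_dyad(gap_nt = -50))))
  g <- gnm$genes[order(gnm$genes$start), ]
  expect_equal(g$start[2] - g$end[1], -50)
})

test_that("plant_motif writes exactly one site at the recorded coordinates", {
  for (sp in 4:6) {
    pm <- plant_motif(60, spacer = sp, seed = 100 + sp)
    ch <- strsplit(pm$seq, "")[[1]]
    expect_equal(ch[pm$truth$r_pos + 1], "R")
    expect_equal(ch[pm$truth$h_pos + 1], "H")
    expect_equal(pm$truth$h_pos, pm$truth$r_pos + sp + 1)
    expect_equal(sum(ch == "R"), 1)  # background cannot fabricate decoys
    expect_equal(sum(ch == "H"), 1)
  }
  expect_error(plant_motif(10, spacer = 6), "spacer \\+ 10")
})

test_that("plant_motif controls the residue after R and the upstream ExKR element", {
  pm <- plant_motif(50, spacer = 4, polar_after_r = TRUE, seed = 3)
  ch <- strsplit(pm$seq, "")[[1]]
  expect_true(ch[pm$truth$r_pos + 2] %in% c("N", "D"))
  pm2 <- plant_motif(50, spacer = 4, polar_after_r = FALSE, seed = 3)
  ch2 <- strsplit(pm2$seq, "")[[1]]
  expect_false(ch2[pm2$truth$r_pos + 2] %in% residue_classes()$p)
  pm3 <- plant_motif(50, spacer = 5, with_upstream_exkr = TRUE, seed = 4)
  ch3 <- strsplit(pm3$seq, "")[[1]]
  e <- pm3$truth$upstream_exkr_pos
  expect_equal(ch3[e + 1], "E")
  expect_true(ch3[e + 5] %in% c("K", "R"))
  expect_true(e + 4 < pm3$truth$r_pos)
})

test_that("protein families honour fixed, class and partial profile columns", {
  aln <- generate_protein_family(200, c("M", "h", "R:0.8", "*"), seed = 11)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  expect_true(all(m[, 1] == "M"))
  expect_true(all(m[, 2] %in% residue_classes()$h))
  frac_r <- mean(m[, 3] == "R")
  expect_gt(frac_r, 0.7)
  expect_lt(frac_r, 0.9)
  expect_error(generate_protein_family(5, c("q"), seed = 1), "unknown profile")
})

test_that("full pipeline recovers a feasible plan exactly (closure)", {
  plan <- genome_plan(seed = 123, n_background_genes = 15, elements = list(
    ta_dyad(gap_nt = 30), ta_dyad(gap_nt = -20, strand = "-"),
    operon_element(c("Methylase", "REase", "Helicase"), c(10, 80)),
    divergon_element(head_gap_nt = 120),
    fusion_element(c("MNT", "HEPN"))
  ))
  gnm <- generate_genome(plan)
  res <- analyze_genome(gnm$genes, truth_library(gnm))
  tr <- gnm$truth

  # every planted multi-gene element is one predicted operon, exactly
  for (eid in unique(stats::na.omit(tr$element_id[tr$element_type %in% c("ta_dyad", "operon")]))) {
    members <- sort(tr$gene_id[tr$element_id %in% eid])
    hit <- purrr::map_lgl(res$operons$gene_ids, ~ setequal(.x, members))
    expect_equal(sum(hit), 1)
  }
  # dyads recovered with canonical orientation
  planted_dyads <- unique(stats::na.omit(tr$element_id[tr$element_type == "ta_dyad"]))
  expect_equal(nrow(res$dyads), length(planted_dyads))
  expect_true(all(res$dyads$orientation == "canonical"))
  expect_equal(sort(res$dyads$antitoxin_gene), sort(tr$gene_id[tr$role == "antitoxin"]))
  # planted divergons present
  dv <- tr[tr$element_type == "divergon", ]
  expect_true(all(dv$gene_id[dv$role == "divergon_left"] %in% res$divergons$left_gene_id))
  # fusions recovered with the planted architecture
  fus <- tr[tr$role == "fusion", ]
  got <- res$architectures$architecture[match(fus$gene_id, res$architectures$protein_id)]
  expect_equal(got, gsub(",", "+", fus$domains))
})
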