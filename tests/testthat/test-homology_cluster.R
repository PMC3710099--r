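# Pairwise identity/coverage and single-linkage clustering.

test_that("identity and coverage behave on simple pairs", {
  p <- pairwise_identity(strrep("MKVLAWTE", 3), strrep("MKVLAWTE", 3))
  expect_equal(p$identity, 1)
  expect_equal(p$coverage, 1)
  expect_equal(pairwise_identity("AAAA", "AATA")$identity, 0.75)
  expect_error(pairwise_identity("", "AA"), "empty")
  # X matches nothing, not even X
  expect_lt(pairwise_identity("AXAXA", "AXAXA")$identity, 1)
})

test_that("alignment score and stats match the exhaustive DP oracle", {
  set.seed(501)
  alpha <- strsplit("ACDEFGHIKLX", "")[[1]]
  for (rep in 1:40) {
    a <- random_protein(sample(3:12, 1), alpha)
    b <- random_protein(sample(3:12, 1), alpha)
    got <- pairwise_identity(a, b)
    want <- oracle_align(a, b)
    expect_equal(got$score, want$score)
    # identity/coverage must be achievable by some optimal alignment
    match_row <- apply(want$stats, 1, function(r) {
      isTRUE(all.equal(unname(r[1]), got$identity)) &&
        isTRUE(all.equal(unname(r[2]), got$coverage))
    })
    expect_true(any(match_row))
  }
})

test_that("single linkage chains clusters through intermediate sequences", {
  base <- "MKVLAWTENPQSGDFI"
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq_len(k)
    ch[idx] <- rep(c("G", "P"), length.out = k)
    paste(ch, collapse = "")
  }
  # A~B and B~C pass 0.5 identity; A~C fails
  p <- tibble::tibble(protein_id = c("A", "B", "C"),
                      seq = c(base, mut(base, 6), mut(base, 12)))
  pid <- function(x, y) pairwise_identity(x, y)$identity
  expect_gte(pid(p$seq[1], p$seq[2]), 0.5)
  expect_gte(pid(p$seq[2], p$seq[3]), 0.5)
  expect_lt(pid(p$seq[1], p$seq[3]), 0.5)
  cl <- cluster_proteins(p, identity_threshold = 0.5, coverage_threshold = 0.7)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
})

test_that("clustering equals connected components of the thresholded pair graph", {
  set.seed(502)
  for (rep in 1:12) {
    n <- sample(4:14, 1)
    # families: copies of a few parents with point mutations, plus noise
    parents <- replicate(3, random_protein(sample(12:20, 1)))
    seqs <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.75) {
        s <- strsplit(sample(parents, 1), "")[[1]]
        k <- sample(0:3, 1)
        if (k > 0) s[sample(length(s), k)] <- sample(strsplit("ACDEFG", "")[[1]], k, replace = TRUE)
        paste(s, collapse = "")
      } else {
        random_protein(sample(10:22, 1))
      }
    }, character(1))
    p <- tibble::tibble(protein_id = sprintf("s%02d", seq_len(n)), seq = seqs)
    cl <- cluster_proteins(p, identity_threshold = 0.6, coverage_threshold = 0.7)
    pairs <- tidy(cl)
    pass <- pairs[pairs$identity >= 0.6 & pairs$coverage >= 0.7, ]
    ig <- igraph::graph_from_data_frame(pass[c("id_a", "id_b")], directed = FALSE,
                                        vertices = p["protein_id"])
    comp <- igraph::components(ig)$membership
    # same partition: cluster labels are a bijection of component labels
    expect_equal(dplyr::n_distinct(cl$cluster_id),
                 dplyr::n_distinct(comp))
    tab <- table(cl$cluster_id, comp[cl$protein_id])
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("partition is invariant to input order and refines as thresholds rise", {
  set.seed(503)
  parents <- replicate(2, random_protein(15))
  seqs <- c(parents, vapply(parents, function(s) {
    ch <- strsplit(s, "")[[1]]; ch[1:3] <- "G"; paste(ch, collapse = "")
  }, character(1)), random_protein(15))
  p <- tibble::tibble(protein_id = sprintf("q%d", seq_along(seqs)), seq = seqs)
  cl <- cluster_proteins(p, 0.5, 0.7)
  perm <- p[sample(nrow(p)), ]
  cl2 <- cluster_proteins(perm, 0.5, 0.7)
  m1 <- setNames(cl$cluster_id, cl$protein_id)
  m2 <- setNames(cl2$cluster_id, cl2$protein_id)
  same <- outer(names(m1), names(m1), function(x, y) m1[x] == m1[y])
  same2 <- outer(names(m1), names(m1), function(x, y) m2[x] == m2[y])
  expect_equal(same, same2)

  lo <- cluster_proteins(p, 0.3, 0.5)
  hi <- cluster_proteins(p, 0.8, 0.9)
  # every high-threshold cluster sits inside one low-threshold cluster
  ml <- setNames(lo$cluster_id, lo$protein_id)
  for (cid in unique(hi$cluster_id)) {
    members <- hi$protein_id[hi$cluster_id == cid]
    expect_equal(dplyr::n_distinct(ml[members]), 1)
  }
})

test_that("cluster labels take the plurality architecture with lexicographic ties", {
  cl <- tibble::tibble(protein_id = sprintf("p%d", 1:8),
                       cluster_id = c(rep("C001", 4), rep("C002", 4)))
  arch <- tibble::tibble(
    protein_id = sprintf("p%d", 1:7),
    architecture = c("HEPN", "HEPN", "HEPN", "MNT+HEPN",
                     "MNT", "MNT", "AAA")
  )
  ann <- annotate_clusters(cl, arch)
  expect_equal(ann$label[ann$cluster_id == "C001"], "HEPN")
  expect_equal(ann$fraction[ann$cluster_id == "C001"], 0.75)
  # C002: p8 has no architecture -> "unknown"; 2 MNT vs 1 AAA vs 1 unknown
  expect_equal(ann$label[ann$cluster_id == "C002"], "MNT")
  tie <- annotate_clusters(
    tibble::tibble(protein_id = c("a", "b", "c", "d"), cluster_id = "C001"),
    tibble::tibble(protein_id = c("a", "b", "c", "d"),
                   architecture = c("ZZZ", "ZZZ", "AAA", "AAA"))
  )
  expect_equal(tie$label, "AAA")
})
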