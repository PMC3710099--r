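# Independent brute-force oracles. These deliberately re-derive results
# from first principles (exhaustive enumeration, direct counting) and
# share no code with the implementation paths they check.

# ---- gene-table fixture ----------------------------------------------------

# build a linear/circular one-contig gene table from strands and gaps
make_genes <- function(strands, gaps = integer(0), len = 300,
                       contig = "c1", circular = FALSE, first_start = 50,
                       wrap_gap = 500) {
  n <- length(strands)
  stopifnot(length(gaps) == max(0, n - 1))
  start <- integer(n)
  start[1] <- first_start
  for (i in seq_len(n - 1)) start[i + 1] <- start[i] + len + gaps[i]
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    contig_id = contig,
    start = as.integer(start),
    end = as.integer(start + len),
    strand = strands,
    product = "",
    protein_seq = strrep("A", 10),
    contig_length = as.integer(start[n] + len + wrap_gap),
    circular = circular
  )
}

# ---- operon segmentation oracle -------------------------------------------

# enumerate all 2^(n-1) consecutive segmentations; keep the ones where
# every within-segment adjacency passes both rules and every cut fails at
# least one (maximality). Returns the unique surviving partition as a list
# of genomic-order index vectors.
oracle_segment <- function(strands, gaps, max_gap) {
  n <- length(strands)
  if (n == 1) return(list(1L))
  ok_adj <- strands[-1] == strands[-n] & gaps <= max_gap
  survivors <- list()
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- as.logical(bitwAnd(mask, 2^(0:(n - 2))))
    valid <- all(ok_adj[!cuts]) && all(!ok_adj[cuts])
    if (valid) {
      seg <- cumsum(c(TRUE, cuts))
      survivors[[length(survivors) + 1]] <- split(seq_len(n), seg)
    }
  }
  stopifnot(length(survivors) == 1)
  unname(survivors[[1]])
}

# predicted operons -> genomic-order index partition for comparison
operons_as_partition <- function(operons, genes) {
  g <- genes[order(genes$start), ]
  pos <- stats::setNames(seq_len(nrow(g)), g$gene_id)
  parts <- lapply(operons$gene_ids, function(ids) sort(unname(pos[ids])))
  parts[order(vapply(parts, min, integer(1)))]
}

# ---- affine-gap global alignment oracle -----------------------------------

# Gotoh DP (match +1, mismatch -1, X matches nothing, gap of length L
# costs 5 + L, terminal gaps penalised) plus enumeration of all optimal
# alignments; reports the best score and the set of (identity, coverage)
# values achievable by optimal alignments.
oracle_align <- function(a, b, max_paths = 500) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  sub <- function(x, y) if (x == y && x != "X") 1 else -1
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes A)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes B)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -5 - i
  for (j in seq_len(m)) Iy[1, j + 1] <- -5 - j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- sub(A[i], B[j]) + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - 6, Ix[i, j + 1] - 1, Iy[i, j + 1] - 6)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - 6, Ix[i + 1, j] - 6, Iy[i + 1, j] - 1)
    }
  }
  best <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])

  paths <- list()
  walk <- function(i, j, state, cols_a, cols_b) {
    if (length(paths) >= max_paths) return()
    if (i == 0 && j == 0 && state == "M") {
      paths[[length(paths) + 1]] <<- list(a = rev(cols_a), b = rev(cols_b))
      return()
    }
    val <- switch(state, M = M[i + 1, j + 1], Ix = Ix[i + 1, j + 1],
                  Iy = Iy[i + 1, j + 1])
    if (state == "M") {
      if (i == 0 && j == 0) return()
      s <- sub(A[i], B[j])
      for (prev in c("M", "Ix", "Iy")) {
        pv <- switch(prev, M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
        if (pv + s == val && pv > NEG / 2) {
          walk(i - 1, j - 1, prev, c(cols_a, A[i]), c(cols_b, B[j]))
        }
      }
    } else if (state == "Ix") {
      if (i == 0) return()
      for (prev in c("M", "Ix", "Iy")) {
        cost <- if (prev == "Ix") 1 else 6
        pv <- switch(prev, M = M[i, j + 1], Ix = Ix[i, j + 1], Iy = Iy[i, j + 1])
        if (pv - cost == val && pv > NEG / 2) {
          walk(i - 1, j, prev, c(cols_a, A[i]), c(cols_b, "-"))
        }
      }
    } else {
      if (j == 0) return()
      for (prev in c("M", "Ix", "Iy")) {
        cost <- if (prev == "Iy") 1 else 6
        pv <- switch(prev, M = M[i + 1, j], Ix = Ix[i + 1, j], Iy = Iy[i + 1, j])
        if (pv - cost == val && pv > NEG / 2) {
          walk(i, j - 1, prev, c(cols_a, "-"), c(cols_b, B[j]))
        }
      }
    }
  }
  for (st in c("M", "Ix", "Iy")) {
    v <- switch(st, M = M[n + 1, m + 1], Ix = Ix[n + 1, m + 1], Iy = Iy[n + 1, m + 1])
    if (v == best) walk(n, m, st, character(), character())
  }

  stats <- unique(t(vapply(paths, function(p) {
    ca <- p$a; cb <- p$b
    core <- which(ca != "-" & cb != "-")
    if (length(core) == 0) return(c(identity = 0, coverage = 0))
    span <- core[1]:core[length(core)]
    ident <- sum(ca[span] == cb[span] & ca[span] != "-" & ca[span] != "X")
    len_short <- min(n, m)
    short <- if (n <= m) ca else cb
    c(identity = ident / length(span),
      coverage = sum(short[span] != "-") / len_short)
  }, numeric(2))))
  list(score = best, stats = stats)
}

# ---- misc direct-count oracles --------------------------------------------

# exhaustive position enumeration for R-x(4..6)-H sites
oracle_rxh <- function(seq, min_spacer = 4, max_spacer = 6) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  for (r in seq_along(ch)) {
    for (sp in min_spacer:max_spacer) {
      h <- r + sp + 1
      if (h <= length(ch) && ch[r] == "R" && ch[h] == "H") {
        out <- rbind(out, c(r - 1, sp, h - 1))
      }
    }
  }
  out
}

# direct set-membership consensus, one column of residues at a time
oracle_consensus_char <- function(col, n_rows, threshold) {
  h_set <- strsplit("WFYMLIVACTH", "")[[1]]
  p_set <- strsplit("EDKRNQHTS", "")[[1]]
  s_set <- strsplit("ACDGNPSTV", "")[[1]]
  res <- col[col != "-"]
  if (length(res) == 0) return(".")
  counts <- table(res)
  top <- sort(names(counts)[counts == max(counts)])[1]
  if (counts[top] / n_rows >= threshold) return(top)
  if (sum(res %in% h_set) / n_rows >= threshold) return("h")
  if (sum(res %in% p_set) / n_rows >= threshold) return("p")
  if (sum(res %in% s_set) / n_rows >= threshold) return("s")
  "."
}

# direct recount of context-graph weights from raw inputs
oracle_network_weights <- function(archs, operons) {
  fusion <- sum(pmax(0, vapply(strsplit(archs$architecture, "+", fixed = TRUE),
                               function(d) if (identical(d, "unknown")) 0L else length(d),
                               integer(1)) - 1L))
  nb <- 0L
  arch_of <- stats::setNames(archs$architecture, archs$protein_id)
  for (i in seq_len(nrow(operons))) {
    ids <- operons$gene_ids[[i]]
    if (length(ids) < 2) next
    doms <- lapply(ids, function(g) {
      a <- arch_of[g]
      if (is.na(a) || a == "unknown") "unknown" else strsplit(a, "+", fixed = TRUE)[[1]]
    })
    pairs <- character()
    for (x in seq_along(ids)) {
      for (y in seq_along(ids)) {
        if (x >= y) next
        for (dx in doms[[x]]) for (dy in doms[[y]]) {
          pairs <- c(pairs, paste(sort(c(dx, dy)), collapse = "|"))
        }
      }
    }
    nb <- nb + length(unique(pairs))
  }
  list(fusion = fusion, neighborhood = nb)
}

# direct evaluation of the expansion rule
oracle_lse <- function(m, min_copies, min_fold) {
  out <- NULL
  for (f in rownames(m)) {
    for (t in colnames(m)) {
      cc <- m[f, t]
      bg <- stats::median(m[f, setdiff(colnames(m), t)])
      if (cc >= min_copies && (bg == 0 || cc >= min_fold * bg)) {
        out <- rbind(out, data.frame(family = f, taxon = t,
                                     copy_count = cc, background_median = bg))
      }
    }
  }
  out
}

# random protein of given length over the 20 standard residues
random_protein <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
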