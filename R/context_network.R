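# Domain-context network: fusion edges (adjacent domains in one
# polypeptide) and neighborhood edges (domains carried by different genes
# of one operon).
#
# Edges are stored undirected with lexicographically canonicalised node
# order; the N-to-C / 5'-to-3' direction survives as the `fwd` count
# (supporting instances observed in (from, to) orientation). A pair
# occurring several times within one protein or operon counts once for
# that protein/operon: weights are supporting-instance counts.

#' Build the domain-context network
#'
#' Fusion edges connect domains adjacent in the same polypeptide, weighted
#' by the number of distinct proteins supporting the pair. Neighborhood
#' edges connect every pair of domains carried by *different* genes of the
#' same operon, weighted by the number of distinct supporting operons;
#' domains of a single gene never get a neighborhood edge. A gene that is
#' referenced by an operon but has no architecture contributes the node
#' `"unknown"`.
#'
#' @param archs Tibble with `protein_id` and `architecture` (from
#'   [architectures()]).
#' @param operons Operon tibble from [predict_operons()] (optional).
#' @return A `context_graph`: list with `nodes` (tibble `name`,
#'   `category`) and `edges` (tibble `from`, `to`, `type`, `weight`,
#'   `fwd`), deterministically ordered.
#' @examples
#' a <- tibble::tibble(protein_id = "p1", architecture = "MNT+HEPN")
#' build_network(a)
#' @export
build_network <- function(archs, operons = NULL) {
  stopifnot(all(c("protein_id", "architecture") %in% names(archs)))
  fusion <- purrr::map_dfr(seq_len(nrow(archs)), function(i) {
    fp <- fusion_pairs(archs$architecture[i])
    if (nrow(fp) == 0) return(NULL)
    fp$protein_id <- archs$protein_id[i]
    fp
  })
  fusion_edges <- canon_count(fusion, "fusion", group = "protein_id")

  nb_edges <- tibble(from = character(), to = character(),
                     type = character(), weight = integer(), fwd = integer())
  extra_nodes <- character()
  if (!is.null(operons) && nrow(operons) > 0) {
    arch_of <- setNames(archs$architecture, archs$protein_id)
    pairs <- purrr::map_dfr(seq_len(nrow(operons)), function(i) {
      ids <- operons$gene_ids[[i]]
      if (length(ids) < 2) return(NULL)
      doms <- purrr::map(ids, function(g) {
        a <- arch_of[g]
        if (is.na(a) || a == "unknown") "unknown"
        else strsplit(a, "+", fixed = TRUE)[[1]]
      })
      out <- list()
      for (x in seq_along(ids)) {
        for (y in seq_along(ids)) {
          if (x >= y) next
          grid <- expand.grid(from = doms[[x]], to = doms[[y]],
                              stringsAsFactors = FALSE)
          out[[length(out) + 1]] <- grid
        }
      }
      res <- dplyr::bind_rows(out)
      res$operon_id <- operons$operon_id[i]
      res
    })
    nb_edges <- canon_count(pairs, "neighborhood", group = "operon_id")
    if (nrow(pairs) > 0) extra_nodes <- unique(c(pairs$from, pairs$to))
  }

  edges <- dplyr::bind_rows(fusion_edges, nb_edges)
  edges <- dplyr::arrange(edges, .data$from, .data$to, .data$type)
  node_names <- sort(unique(c(
    unlist(strsplit(archs$architecture[archs$architecture != "unknown"],
                    "+", fixed = TRUE)),
    extra_nodes, edges$from, edges$to
  )))
  structure(list(
    nodes = tibble(name = node_names, category = NA_character_),
    edges = edges
  ), class = "context_graph")
}

# canonicalise node order, count distinct supporting instances per
# unordered pair; `fwd` counts instances seen in (from, to) orientation
canon_count <- function(pairs, type, group) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(tibble(from = character(), to = character(), type = character(),
                  weight = integer(), fwd = integer()))
  }
  pairs <- dplyr::mutate(pairs,
    forward = .data$from <= .data$to,
    a = pmin(.data$from, .data$to),
    b = pmax(.data$from, .data$to)
  )
  # one row per (pair, supporting instance); orientation: any forward sighting
  pairs |>
    dplyr::group_by(.data$a, .data$b, .data[[group]]) |>
    dplyr::summarise(forward = any(.data$forward), .groups = "drop") |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(weight = dplyr::n(), fwd = sum(.data$forward),
                     .groups = "drop") |>
    dplyr::transmute(from = .data$a, to = .data$b, type = type,
                     weight = as.integer(.data$weight),
                     fwd = as.integer(.data$fwd)) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Collapse a context graph by functional category
#'
#' Replaces every node by its functional category (unmapped nodes fall to
#' `"other"`), merges parallel edges of the same type by summing weights,
#' and turns intra-category edges into self-loops. Total edge weight is
#' conserved exactly.
#'
#' @param graph A `context_graph`.
#' @param category_map Named character vector or tibble
#'   (`domain`, `category`).
#' @return A collapsed `context_graph` whose nodes are categories.
#' @export
collapse_by_category <- function(graph, category_map) {
  stopifnot(inherits(graph, "context_graph"))
  if (is.data.frame(category_map)) {
    category_map <- setNames(category_map$category, category_map$domain)
  }
  lookup <- function(x) {
    out <- unname(category_map[x])
    out[is.na(out)] <- "other"
    out
  }
  e <- graph$edges
  if (nrow(e) > 0) {
    e$from <- lookup(e$from)
    e$to <- lookup(e$to)
    swap <- e$from > e$to
    tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
    e <- e |>
      dplyr::group_by(.data$from, .data$to, .data$type) |>
      dplyr::summarise(weight = sum(.data$weight), fwd = sum(.data$fwd),
                       .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to, .data$type)
  }
  nodes <- tibble(name = sort(unique(c(lookup(graph$nodes$name), e$from, e$to))),
                  category = NA_character_)
  structure(list(nodes = nodes, edges = e), class = "context_graph")
}

#' Convert a context graph to igraph
#'
#' @param graph A `context_graph`.
#' @return An undirected [igraph::graph] with `type`, `weight` and `fwd`
#'   edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "context_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                vertices = graph$nodes)
}

#' Export a context graph
#'
#' GraphML (Cytoscape-readable, carries `type`/`weight`/`fwd` edge
#' attributes), SIF (`from<TAB>type<TAB>to`, one line per edge) or a plain
#' edge-list TSV. Output ordering is deterministic.
#'
#' @param graph A `context_graph`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"sif"`, `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "edge-tsv")) {
  stopifnot(inherits(graph, "context_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  } else if (format == "sif") {
    e <- graph$edges
    lines <- sprintf("%s\t%s\t%s", e$from, e$type, e$to)
    isolated <- setdiff(graph$nodes$name, c(e$from, e$to))
    writeLines(c(lines, isolated), path)
  } else {
    readr::write_tsv(graph$edges, path)
  }
  invisible(path)
}

#' Spring-embedded (Kamada-Kawai) layout
#'
#' Deterministic 2-D coordinates: each connected component is laid out
#' with the Kamada-Kawai spring embedder from a fixed circular start, and
#' components are placed on a grid. A single node sits at the origin of
#' its grid cell.
#'
#' @param graph A `context_graph`.
#' @param seed Integer seed (layout start configuration).
#' @return Tibble: `name`, `x`, `y`.
#' @export
layout_spring <- function(graph, seed = 1) {
  stopifnot(inherits(graph, "context_graph"))
  ig <- as_igraph(graph)
  n <- igraph::vcount(ig)
  if (n == 0) return(tibble(name = character(), x = numeric(), y = numeric()))
  comp <- igraph::components(ig)
  coords <- matrix(0, n, 2)
  # grid cell size: leave room for the largest component
  cell <- 3
  ncols <- ceiling(sqrt(comp$no))
  with_seed_(seed, {
    for (k in seq_len(comp$no)) {
      vs <- which(comp$membership == k)
      sub <- igraph::induced_subgraph(ig, vs)
      m <- length(vs)
      xy <- if (m == 1) {
        matrix(0, 1, 2)
      } else {
        start <- igraph::layout_in_circle(sub)
        igraph::layout_with_kk(sub, coords = start)
      }
      # centre the component, then offset to its grid cell
      xy <- sweep(xy, 2, colMeans(xy))
      row <- (k - 1) %/% ncols
      col <- (k - 1) %% ncols
      xy[, 1] <- xy[, 1] + col * cell
      xy[, 2] <- xy[, 2] - row * cell
      coords[vs, ] <- xy
    }
  })
  tibble(name = igraph::V(ig)$name, x = coords[, 1], y = coords[, 2])
}

#' @export
print.context_graph <- function(x, ...) {
  cat(sprintf("Domain-context graph: %d nodes, %d edges (%d fusion, %d neighborhood)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "fusion"),
              sum(x$edges$type == "neighborhood")))
  cat(sprintf("total edge weight: %d\n", sum(x$edges$weight)))
  invisible(x)
}

#' @rdname build_network
#' @param x A `context_graph`.
#' @param ... Unused.
#' @method tidy context_graph
#' @export
tidy.context_graph <- function(x, ...) {
  x$edges
}

#' @rdname build_network
#' @method glance context_graph
#' @export
glance.context_graph <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    fusion_weight = sum(x$edges$weight[x$edges$type == "fusion"]),
    neighborhood_weight = sum(x$edges$weight[x$edges$type == "neighborhood"])
  )
}

#' Plot a context graph
#'
#' Spring-embedded rendering with fusion edges in cyan and neighborhood
#' edges in gold, node labels at the layout coordinates.
#'
#' @param object A `context_graph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot context_graph
#' @export
autoplot.context_graph <- function(object, seed = 1, ...) {
  xy <- layout_spring(object, seed = seed)
  e <- object$edges
  seg <- dplyr::left_join(e, xy, by = c("from" = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(xy, by = c("to" = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x, yend = .data$y,
                   colour = .data$type, linewidth = .data$weight),
      alpha = 0.7
    ) +
    ggplot2::scale_colour_manual(values = c(fusion = "cyan3",
                                            neighborhood = "goldenrod2")) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::geom_point(data = xy, ggplot2::aes(.data$x, .data$y), size = 2) +
    ggplot2::geom_text(data = xy, ggplot2::aes(.data$x, .data$y,
                                               label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge type", linewidth = "support")
}
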