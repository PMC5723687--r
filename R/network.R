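#' Convert scan p-values to dense-module node scores
#'
#' The unsigned node score used by the module search is the upper-tail
#' standard-normal quantile `g = qnorm(1 - p)`, truncated below at 0 for
#' p > 0.5 (so below-median evidence never penalizes beyond zero). The
#' signed display score is `sign(beta) * qnorm(1 - p / 2)` (used only for
#' coloring positive vs negative associations). p-values of 0 are capped at
#' `p_floor` with a warning.
#'
#' @param p two-sided p-values in `[0, 1]`.
#' @param beta_sign sign of the association (vector recycled to `p`).
#' @param p_floor cap applied to p = 0 (default 1e-30).
#' @return Tibble: `p`, `g` (unsigned score), `z_signed`.
#' @export
p_to_z <- function(p, beta_sign = 1, p_floor = 1e-30) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (any(p == 0, na.rm = TRUE)) {
    warn(paste0("p-values of 0 capped at ", p_floor, "."))
    p[p == 0] <- p_floor
  }
  beta_sign <- rep_len(sign(beta_sign), length(p))
  # upper-tail quantiles computed on the log-safe side so tiny p never
  # underflows to Inf through 1 - p
  tibble::tibble(
    p = p,
    g = pmax(qnorm(p, lower.tail = FALSE), 0),
    z_signed = beta_sign * qnorm(p / 2, lower.tail = FALSE)
  )
}

#' Build a scored gene network from an edge list and scan results
#'
#' Attaches node scores (via [p_to_z()]) to an undirected, deduplicated,
#' self-loop-free interaction network. Network nodes without a scan p-value
#' keep `g = 0` (flagged `scored = FALSE`) so they can still act as
#' connectors inside modules.
#'
#' @param edges data frame edge list (`from`, `to` gene symbols).
#' @param results scan results tibble (`gene`, `p`, `beta`); a
#'   `"delta_scan"` is also accepted. When several features map to one gene,
#'   the smallest p is used.
#' @param p_floor cap for p = 0, see [p_to_z()].
#' @return A `"gene_network"` object: list with `nodes` (tibble: gene, p, g,
#'   z_signed, scored, degree) and `edges`.
#' @export
score_network <- function(edges, results, p_floor = 1e-30) {
  if (inherits(results, "delta_scan")) results <- results$results
  results <- tibble::as_tibble(results)
  stopifnot(all(c("gene", "p") %in% names(results)))
  edges <- tibble::as_tibble(edges)[, 1:2]
  names(edges) <- c("from", "to")
  edges <- dplyr::filter(edges, .data$from != .data$to)
  edges <- dplyr::distinct(tibble::tibble(from = pmin(edges$from, edges$to),
                                          to = pmax(edges$from, edges$to)))
  genes <- sort(unique(c(edges$from, edges$to)))
  best <- results |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_min(.data$p, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  nodes <- tibble::tibble(gene = genes) |>
    dplyr::left_join(best[, c("gene", "p", "beta")], by = "gene")
  scored <- !is.na(nodes$p)
  sc <- p_to_z(ifelse(scored, nodes$p, 1),
               ifelse(is.na(nodes$beta), 1, nodes$beta), p_floor = p_floor)
  nodes$g <- unname(ifelse(scored, sc$g, 0))
  nodes$z_signed <- unname(ifelse(scored, sc$z_signed, 0))
  nodes$p <- unname(nodes$p)
  nodes$scored <- scored
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$gene])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Scored gene network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      sum(x$nodes$scored), "scored\n")
  invisible(x)
}

# adjacency as a named list of integer neighbor indices
adjacency_list <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes$gene)
  adj <- igraph::as_adj_list(g, mode = "all")
  lapply(adj, function(v) as.integer(v))
}

#' Greedy dense-module search from one seed gene
#'
#' Best-first expansion of the module score `Z_m = sum(g_i) / sqrt(k)` over
#' the `k` current members: at each step every distance-1 neighbor of the
#' module is scored as a candidate, and the single best candidate (ties
#' broken by higher node score, then lexicographic gene symbol) is added iff
#' it strictly increases `Z_m`. The search stops at the first step with no
#' improving neighbor, so every trace is strictly score-increasing.
#'
#' @param network a `"gene_network"` from [score_network()].
#' @param seed_gene gene symbol present in the network.
#' @return A `"gene_module"` object: list with `seed`, `members`, `k`, `z_m`,
#'   and `trace` (tibble: step, gene, z_m after adding).
#' @export
grow_module <- function(network, seed_gene) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  si <- match(seed_gene, nodes$gene)
  if (is.na(si)) abort(paste0("Seed gene `", seed_gene, "` absent from the network."))
  adj <- adjacency_list(network)
  gsc <- unname(as.numeric(nodes$g))
  members <- si
  total <- gsc[si]
  z_m <- total / sqrt(1)
  trace <- list(tibble::tibble(step = 0L, gene = seed_gene, z_m = z_m))
  in_mod <- logical(nrow(nodes))
  in_mod[si] <- TRUE
  step <- 0L
  repeat {
    cand <- unique(unlist(adj[members], use.names = FALSE))
    cand <- cand[!in_mod[cand]]
    if (length(cand) == 0) break
    z_new <- (total + gsc[cand]) / sqrt(length(members) + 1)
    best_z <- max(z_new)
    if (!(best_z > z_m)) break
    tied <- cand[z_new == best_z]
    if (length(tied) > 1) {
      tied <- tied[order(-gsc[tied], nodes$gene[tied])]
    }
    pick <- tied[1]
    members <- c(members, pick)
    in_mod[pick] <- TRUE
    total <- total + gsc[pick]
    z_m <- best_z
    step <- step + 1L
    trace[[length(trace) + 1]] <-
      tibble::tibble(step = step, gene = nodes$gene[pick], z_m = z_m)
  }
  structure(list(seed = seed_gene,
                 members = nodes$gene[members],
                 k = length(members),
                 z_m = z_m,
                 trace = dplyr::bind_rows(trace)),
            class = "gene_module")
}

#' @export
print.gene_module <- function(x, ...) {
  cat("Module from seed", x$seed, ": k =", x$k, ", Z_m =", signif(x$z_m, 4), "\n")
  invisible(x)
}

#' Merged subnetwork from the top-seeded greedy modules
#'
#' Ranks scored network genes by scan p-value, grows one greedy module per
#' top seed, unions the member sets and induces the subgraph (all network
#' edges among members). Node degree within the subnetwork is reported for
#' display sizing.
#'
#' @param network a `"gene_network"`.
#' @param n_seeds number of top genes used as seeds (default 25); if fewer
#'   scored genes exist, available seeds are used with a warning.
#' @return A `"subnetwork"` object: list with `nodes` (gene, p, g, z_signed,
#'   scored, degree within the subnetwork), `edges`, `modules` (list of
#'   `"gene_module"`), `seeds`, `n_nodes`, `n_edges`.
#' @export
build_subnetwork <- function(network, n_seeds = 25) {
  stopifnot(inherits(network, "gene_network"))
  scored <- dplyr::filter(network$nodes, .data$scored)
  scored <- dplyr::arrange(scored, .data$p, .data$gene)
  if (nrow(scored) == 0) abort("No scored genes in the network.")
  if (nrow(scored) < n_seeds) {
    warn(paste0("Only ", nrow(scored), " scored gene(s) in the network; ",
                "using all of them as seeds."))
  }
  seeds <- head(scored$gene, n_seeds)
  modules <- lapply(seeds, function(s) grow_module(network, s))
  members <- sort(unique(unlist(lapply(modules, `[[`, "members"))))
  edges <- dplyr::filter(network$edges,
                         .data$from %in% members & .data$to %in% members)
  nodes <- dplyr::filter(network$nodes, .data$gene %in% members)
  deg <- table(c(edges$from, edges$to))
  nodes$degree <- as.integer(deg[nodes$gene])
  nodes$degree[is.na(nodes$degree)] <- 0L
  structure(list(nodes = nodes, edges = edges, modules = modules,
                 seeds = seeds, n_nodes = nrow(nodes), n_edges = nrow(edges)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Merged interaction subnetwork:", x$n_nodes, "nodes,", x$n_edges,
      "edges from", length(x$modules), "modules\n")
  invisible(x)
}

#' @rdname build_subnetwork
#' @param x a `"subnetwork"`.
#' @param ... unused.
#' @method tidy subnetwork
#' @export
tidy.subnetwork <- function(x, ...) x$nodes

#' @rdname build_subnetwork
#' @method glance subnetwork
#' @export
glance.subnetwork <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_edges = x$n_edges,
                 n_modules = length(x$modules),
                 max_z_m = max(vapply(x$modules, `[[`, 0, "z_m")))
}

#' @describeIn build_subnetwork Plot the merged subnetwork (deterministic
#'   circular layout; node size by degree, color by signed association).
#' @param object a `"subnetwork"`.
#' @method autoplot subnetwork
#' @export
autoplot.subnetwork <- function(object, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  nodes$x <- cos(2 * pi * (seq_len(k) - 1) / k)
  nodes$y <- sin(2 * pi * (seq_len(k) - 1) / k)
  seg <- dplyr::left_join(object$edges,
                          dplyr::rename(nodes[, c("gene", "x", "y")],
                                        x0 = "x", y0 = "y"),
                          by = c(from = "gene"))
  seg <- dplyr::left_join(seg,
                          dplyr::rename(nodes[, c("gene", "x", "y")],
                                        x1 = "x", y1 = "y"),
                          by = c(to = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree,
                                     colour = .data$z_signed)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x * 1.08, y = .data$y * 1.08,
                                    label = .data$gene), size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey85",
                                    high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(size = "Degree", colour = "Signed z")
}

#' Write a subnetwork (edge list + node attributes) to TSV files
#'
#' @param subnet a `"subnetwork"`.
#' @param edge_path,node_path output file paths.
#' @return `edge_path`, invisibly.
#' @export
write_subnetwork <- function(subnet, edge_path, node_path) {
  readr::write_tsv(subnet$edges, edge_path)
  readr::write_tsv(subnet$nodes[, c("gene", "p", "g", "z_signed", "degree")],
                   node_path)
  invisible(edge_path)
}
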