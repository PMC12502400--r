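#' Build the community-wide bipartite KO-metabolite network
#'
#' Constructs the bipartite graph whose edges connect each retained KO to the
#' non-cofactor reactants and products of its reactions. A KO is retained
#' when it is non-zero in at least `prevalence` of the samples of the gene
#' abundance table (default 0.5: present in a minimum of 50% of samples,
#' inclusive). Ubiquitous compounds (water, energy carriers, cofactors) are
#' removed so that paths reflect the main compounds of a reaction; compounds
#' left with no edge are dropped. KO features absent from the universe are
#' warned about and dropped.
#'
#' @param u a `reaction_universe`.
#' @param funMG an `omics_table` of gene abundances driving the prevalence
#'   filter.
#' @param prevalence fraction in (0, 1]; default 0.5.
#' @param cofactors compound ids to exclude (default: the universe's
#'   cofactor set).
#' @return object of class `community_network`: list with `edges` (tibble
#'   ko / compound / role), `kos`, `compounds`, `cofactors`, `prevalence`,
#'   and `activity` (empty until [attach_activity()]).
#' @export
build_network <- function(u, funMG, prevalence = 0.5, cofactors = NULL) {
  stopifnot(inherits(u, "reaction_universe"), inherits(funMG, "omics_table"))
  check_fraction(prevalence, "prevalence")
  cofactors <- cofactors %||% u$cofactors
  feats <- rownames(funMG$values)
  extra <- setdiff(feats, names(u$ko_reactions))
  if (length(extra) > 0) {
    warn(paste0(length(extra), " funMG feature(s) absent from the universe dropped (e.g. ",
                toString(head(extra, 3)), ")"))
  }
  feats <- intersect(feats, names(u$ko_reactions))
  prev <- rowMeans(funMG$values[feats, , drop = FALSE] > 0)
  kept <- feats[prev >= prevalence]

  edges <- purrr::map_dfr(kept, function(ko) {
    purrr::map_dfr(u$ko_reactions[[ko]], function(rx) {
      s <- u$reaction_sides[[rx]]
      dplyr::bind_rows(
        tibble::tibble(ko = ko, compound = s$reactants, role = "reactant"),
        tibble::tibble(ko = ko, compound = s$products, role = "product")
      )
    })
  })
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::filter(!.data$compound %in% cofactors) |>
      dplyr::distinct(.data$ko, .data$compound, .data$role) |>
      dplyr::arrange(.data$ko, .data$compound, .data$role)
  }
  structure(
    list(edges = edges, kos = sort(unique(edges$ko)),
         compounds = sort(unique(edges$compound)),
         cofactors = sort(cofactors), prevalence = prevalence,
         activity = NULL),
    class = "community_network"
  )
}

#' @export
print.community_network <- function(x, ...) {
  cat(sprintf("<community_network> %d KOs, %d compounds, %d bipartite edges (prevalence >= %g)\n",
              length(x$kos), length(x$compounds), nrow(x$edges), x$prevalence))
  if (!is.null(x$activity)) cat("  activity ratios attached\n")
  invisible(x)
}

#' Remove additional cofactor compounds from a built network
#'
#' Removing a compound deletes its edges (and the compound node); cofactor
#' removal commutes with network construction.
#'
#' @param net a `community_network`.
#' @param compounds compound ids to remove.
#' @return the pruned `community_network`.
#' @export
remove_cofactors <- function(net, compounds) {
  stopifnot(inherits(net, "community_network"))
  edges <- dplyr::filter(net$edges, !.data$compound %in% compounds)
  net$edges <- edges
  net$kos <- sort(unique(edges$ko))
  net$compounds <- sort(unique(edges$compound))
  net$cofactors <- sort(union(net$cofactors, compounds))
  net
}

#' Attach per-KO transcriptional activity ratios
#'
#' Annotates every KO node with the MT/MG ratio of mean normalized read
#' counts -- expression relative to gene copy abundance, a proxy for
#' transcriptional activity. Both tables must be sum-normalized; the ratio
#' uses a shared pseudocount of half the smallest positive value across the
#' two layers, so a KO missing or zero in one layer still yields a finite
#' positive ratio (such KOs are flagged).
#'
#' @param net a `community_network`.
#' @param funMT,funMG sum-normalized `omics_table`s.
#' @return the network with an `activity` tibble
#'   (`ko`, `mt_mean`, `mg_mean`, `ratio`, `flag`).
#' @export
attach_activity <- function(net, funMT, funMG) {
  stopifnot(inherits(net, "community_network"))
  if (!funMT$normalized || !funMG$normalized) {
    abort("funMT and funMG must be sum-normalized")
  }
  eps <- half_min_positive(c(funMT$values, funMG$values))
  means_of <- function(t, kos) {
    out <- setNames(rep(NA_real_, length(kos)), kos)
    hit <- intersect(kos, rownames(t$values))
    out[hit] <- rowMeans(t$values[hit, , drop = FALSE])
    out
  }
  mt <- means_of(funMT, net$kos)
  mg <- means_of(funMG, net$kos)
  net$activity <- tibble::tibble(
    ko = net$kos,
    mt_mean = as.numeric(mt), mg_mean = as.numeric(mg),
    ratio = (dplyr::coalesce(as.numeric(mt), 0) + eps) /
      (dplyr::coalesce(as.numeric(mg), 0) + eps),
    flag = dplyr::if_else(is.na(mt) | is.na(mg), "missing_layer", NA_character_)
  )
  attr(net$activity, "eps") <- eps
  net
}

# Shared projection engine: nodes of `node_col` joined when they share a
# neighbour of the other class; the shared neighbours become the edge label.
project_bipartite <- function(edges, node_col, label_col) {
  nodes <- sort(unique(edges[[node_col]]))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (nrow(edges) == 0) return(g)
  by_label <- split(edges[[node_col]], edges[[label_col]])
  pair_rows <- purrr::imap(by_label, function(members, label) {
    members <- sort(unique(members))
    if (length(members) < 2) return(NULL)
    prs <- combn(members, 2)
    tibble::tibble(a = prs[1, ], b = prs[2, ], label = label)
  })
  pairs <- dplyr::bind_rows(pair_rows)
  if (nrow(pairs) == 0) return(g)
  agg <- pairs |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(shared = paste(sort(unique(.data$label)), collapse = ","),
                     n_shared = dplyr::n_distinct(.data$label), .groups = "drop") |>
    dplyr::arrange(.data$a, .data$b)
  g <- igraph::add_edges(g, rbind(match(agg$a, nodes), match(agg$b, nodes)))
  g <- igraph::set_edge_attr(g, "shared", value = agg$shared)
  igraph::set_edge_attr(g, "n_shared", value = agg$n_shared)
}

#' One-mode projections of the community network
#'
#' `project_ko()` returns the KO-mode graph: KOs are nodes and two KOs are
#' joined exactly when they share at least one non-cofactor compound
#' (reactant or product, treated symmetrically); the shared compound ids are
#' kept on the edge (`shared` attribute, comma-separated, with multiplicity
#' in `n_shared`). `project_compound()` is the inverted network: compounds
#' are nodes and genes are edges. Projections are simple undirected graphs;
#' centrality is computed unweighted.
#'
#' KO activity ratios (when attached) and cofactor status are carried as
#' node attributes.
#'
#' @param net a `community_network`.
#' @return an `igraph` graph.
#' @export
project_ko <- function(net) {
  stopifnot(inherits(net, "community_network"))
  g <- project_bipartite(net$edges, "ko", "compound")
  if (!is.null(net$activity)) {
    idx <- match(igraph::V(g)$name, net$activity$ko)
    g <- igraph::set_vertex_attr(g, "activity_ratio", value = net$activity$ratio[idx])
  }
  g
}

#' @rdname project_ko
#' @export
project_compound <- function(net) {
  stopifnot(inherits(net, "community_network"))
  project_bipartite(net$edges, "compound", "ko")
}

#' Betweenness centrality report
#'
#' Shortest-path betweenness of every node of an unweighted undirected
#' graph, both raw (count of shortest paths through the node, unordered
#' pairs) and normalized by \eqn{(n-1)(n-2)/2}. Deterministic; isolated
#' nodes score 0; a graph with fewer than 3 nodes has all centralities 0.
#' Disconnected graphs are handled per component with global normalization.
#'
#' @param g an `igraph` graph.
#' @return tibble of class `centrality_report` with columns `node`,
#'   `bc_raw`, `bc_norm`.
#' @export
betweenness_centrality <- function(g) {
  n <- igraph::vcount(g)
  raw <- if (n < 3) setNames(rep(0, n), igraph::V(g)$name) else
    igraph::betweenness(g, directed = FALSE, weights = NA)
  norm <- if (n < 3) raw else raw / ((n - 1) * (n - 2) / 2)
  out <- tibble::tibble(node = igraph::V(g)$name,
                        bc_raw = as.numeric(raw), bc_norm = as.numeric(norm))
  class(out) <- c("centrality_report", class(out))
  out
}

#' Subnetwork centrality summary
#'
#' Compares the mean whole-graph betweenness over a node subset (e.g. the
#' KOs linked to one metabolite) against the mean over all nodes, on both
#' the raw and normalized scales. Centralities are whole-graph values
#' restricted to the subset -- not recomputed on the induced subgraph --
#' because the comparison of interest is the subnetwork's importance within
#' the whole community. The induced subgraph's edge count and component
#' structure are reported alongside.
#'
#' @param g the projected graph the report was computed on.
#' @param report a `centrality_report` from [betweenness_centrality()].
#' @param nodes non-empty node subset (ids missing from the graph are
#'   flagged with a warning and ignored).
#' @param label free-text label for the subnetwork.
#' @return one-row tibble with subnetwork size, mean subset/whole BC on both
#'   scales, their ratio, induced edge count and component count.
#' @export
subnetwork_report <- function(g, report, nodes, label = "subnetwork") {
  if (length(nodes) == 0) abort("empty node subset")
  missing <- setdiff(nodes, report$node)
  if (length(missing) > 0) {
    warn(paste0(length(missing), " subnetwork node(s) absent from graph (e.g. ",
                toString(head(missing, 3)), ")"))
  }
  nodes <- intersect(nodes, report$node)
  if (length(nodes) == 0) abort("no subnetwork node present in the graph")
  sub <- dplyr::filter(report, .data$node %in% nodes)
  sg <- igraph::induced_subgraph(g, nodes)
  tibble::tibble(
    label = label,
    n_nodes = length(nodes),
    n_missing = length(missing),
    mean_bc_raw = mean(sub$bc_raw),
    mean_bc_norm = mean(sub$bc_norm),
    whole_mean_bc_raw = mean(report$bc_raw),
    whole_mean_bc_norm = mean(report$bc_norm),
    bc_ratio = mean(sub$bc_norm) / mean(report$bc_norm),
    induced_edges = igraph::ecount(sg),
    n_components = igraph::components(sg)$no
  )
}

#' Write a projected network as GraphML
#'
#' Nodes are emitted in the graph's (sorted) construction order, so
#' identical inputs produce byte-identical files.
#'
#' @param g an `igraph` graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
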