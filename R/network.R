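#' Build a thresholded sequence similarity network
#'
#' Two records are connected by an edge iff their filtered hit has percent
#' identity at least `threshold`; edge weight is the percent identity. Nodes
#' without any edge at the threshold (singletons) are excluded. Node labels
#' (`molecule`, `epoch`, `site`, `habitat`, `truth_species`) are copied from
#' `records` as vertex attributes.
#'
#' @param hits a filtered hit `data.frame` (see [filter_hits()]).
#' @param records record `data.frame`.
#' @param threshold percent-identity threshold in (0, 100].
#' @return An `igraph` object with graph attribute `threshold`.
#' @export
build_network <- function(hits, records, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 100)
    stopf("threshold must lie in (0, 100], got %s", format(threshold))
  records <- validate_records(records)
  keep <- hits$pct_identity >= threshold & hits$query_id != hits$subject_id
  edges <- hits[keep, c("query_id", "subject_id", "pct_identity"), drop = FALSE]
  ids <- sort(unique(c(edges$query_id, edges$subject_id)))
  verts <- records[match(ids, records$id),
                   c("id", "molecule", "epoch", "site", "habitat",
                     "truth_species"), drop = FALSE]
  if (anyNA(verts$id))
    stopf("hit ids not present in records: %s",
          paste(utils::head(setdiff(ids, records$id), 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$query_id, to = edges$subject_id,
               weight = edges$pct_identity, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "max"))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

new_partition <- function(id, cluster, kind, threshold) {
  structure(data.frame(id = id, cluster = cluster, kind = kind,
                       threshold = threshold, stringsAsFactors = FALSE),
            class = c("ssn_partition", "data.frame"))
}

# Deterministic cluster naming: prefix + lexicographically smallest member id.
name_clusters <- function(ids, membership, prefix) {
  smallest <- tapply(ids, membership, min)
  paste0(prefix, "_", unname(smallest[as.character(membership)]))
}

#' Connected components of a similarity network
#'
#' @param net an `igraph` network from [build_network()].
#' @return A partition `data.frame` (`id`, `cluster`, `kind = "CC"`,
#'   `threshold`); cluster ids are `CC_<smallest member id>`.
#' @export
connected_components <- function(net) {
  comp <- igraph::components(net)
  ids <- igraph::V(net)$name
  new_partition(ids, name_clusters(ids, comp$membership, "CC"), "CC",
                igraph::graph_attr(net, "threshold") %||% NA_real_)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ W_c / W - (S_c / 2W)^2 ]` with `W` the total edge weight,
#' `W_c` the intra-cluster weight and `S_c` the total strength of cluster
#' `c`. With `weighted = FALSE` all edges count 1.
#'
#' @param net an `igraph` network.
#' @param membership cluster assignment: named vector (by node id) or a
#'   partition `data.frame` from [connected_components()]/[louvain_level1()].
#' @param weighted use edge weights (percent identity) or unit weights.
#' @return Modularity `Q` in `[-0.5, 1]`.
#' @export
graph_modularity <- function(net, membership, weighted = TRUE) {
  ids <- igraph::V(net)$name
  memb <- as_membership(membership, ids)
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- if (weighted) igraph::E(net)$weight else rep(1, igraph::ecount(net))
  if (length(w) == 0L) stopf("modularity undefined for an edgeless network")
  W <- sum(w)
  same <- memb[el[, 1]] == memb[el[, 2]]
  Wc <- tapply(w[same], memb[el[, 1]][same], sum)
  strength <- tapply(c(w, w), memb[c(el[, 1], el[, 2])], sum)
  Wc_full <- stats::setNames(rep(0, length(strength)), names(strength))
  Wc_full[names(Wc)] <- Wc
  sum(Wc_full / W - (strength / (2 * W))^2)
}

as_membership <- function(membership, ids) {
  if (is.data.frame(membership)) {
    memb <- stats::setNames(membership$cluster, membership$id)
  } else if (!is.null(names(membership))) {
    memb <- membership
  } else stopf("membership must be a partition data.frame or a named vector")
  if (!all(ids %in% names(memb)))
    stopf("partition does not cover all network nodes")
  memb[ids]
}

#' Level-1 Louvain communities
#'
#' One phase of Louvain local-move optimization of weighted Newman-Girvan
#' modularity (edge weights = percent identity), iterated until no single
#' node move increases modularity, *without* the aggregation step: the
#' most fine-grained resolution of the Louvain hierarchy. Node visiting
#' order is shuffled by `seed` (re-shuffled each sweep); ties between equally
#' good target communities break to the smallest community index, so the
#' result is reproducible for a given seed.
#'
#' Because the local-move phase is order-dependent and can stall in a
#' single-move local optimum, the phase is restarted `restarts` times with
#' visiting orders derived from `seed`, and the partition with the highest
#' modularity is returned (ties: earliest restart). The whole procedure is
#' deterministic for a given seed.
#'
#' @param net an `igraph` network (non-empty).
#' @param seed RNG seed for the node visiting orders.
#' @param weighted use edge weights or unit weights.
#' @param restarts number of seeded restarts of the local-move phase.
#' @return A partition `data.frame` (`kind = "LC"`, cluster ids
#'   `LC_<smallest member id>`). Always refines the connected-component
#'   partition, and its modularity is >= that of the all-singletons
#'   partition.
#' @export
louvain_level1 <- function(net, seed = 1L, weighted = TRUE, restarts = 4L) {
  n <- igraph::vcount(net)
  if (n == 0L) stopf("louvain_level1 needs a non-empty network")
  ids <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- if (weighted) igraph::E(net)$weight else rep(1, igraph::ecount(net))
  best <- NULL; best_q <- -Inf
  for (r in seq_len(max(1L, restarts))) {
    memb <- with_seed(derive_seed(seed, r), louvain_local_moves(n, el, w))
    q <- modularity_from_membership(el, w, memb)
    if (q > best_q + 1e-12) { best <- memb; best_q <- q }
  }
  new_partition(ids, name_clusters(ids, best, "LC"), "LC",
                igraph::graph_attr(net, "threshold") %||% NA_real_)
}

# Q from an integer edge list, weights and membership vector.
modularity_from_membership <- function(el, w, memb) {
  W <- sum(w)
  if (W <= 0) return(NA_real_)
  same <- memb[el[, 1]] == memb[el[, 2]]
  strength <- tapply(c(w, w), memb[c(el[, 1], el[, 2])], sum)
  sum(w[same]) / W - sum((strength / (2 * W))^2)
}

# Local-move phase on an integer edge list (no aggregation).
louvain_local_moves <- function(n, el, w) {
  adj_n <- vector("list", n)   # neighbour indices
  adj_w <- vector("list", n)   # edge weights
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    adj_n[[i]] <- c(adj_n[[i]], j); adj_w[[i]] <- c(adj_w[[i]], w[k])
    adj_n[[j]] <- c(adj_n[[j]], i); adj_w[[j]] <- c(adj_w[[j]], w[k])
  }
  strength <- vapply(adj_w, function(x) sum(x %||% 0), numeric(1))
  W2 <- sum(strength)                       # = 2W
  memb <- seq_len(n)
  S <- strength                             # per-community strength
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      if (length(adj_n[[i]]) == 0L) next
      ci <- memb[i]
      w_to <- tapply(adj_w[[i]], memb[adj_n[[i]]], sum)
      # candidate targets: neighbouring communities, staying put, and
      # splitting off into a fresh singleton community (weight 0 to it)
      cand <- as.integer(names(w_to))
      w_cand <- unname(w_to)
      if (!ci %in% cand) { cand <- c(cand, ci); w_cand <- c(w_cand, 0) }
      free <- setdiff(seq_len(n), unique(memb))
      if (length(free) > 0L && sum(memb == ci) > 1L) {
        cand <- c(cand, free[1]); w_cand <- c(w_cand, 0)
      }
      w_cur <- if (as.character(ci) %in% names(w_to)) w_to[[as.character(ci)]] else 0
      # gain of moving i from ci to c (both evaluated with i removed from ci)
      gain <- (w_cand - w_cur) / (W2 / 2) -
        strength[i] * (S[cand] - ifelse(cand == ci, strength[i], 0) -
                         (S[ci] - strength[i])) / (2 * (W2 / 2)^2)
      gain[cand == ci] <- 0
      best <- which(gain > 1e-12)
      if (length(best) > 0L) {
        pick <- best[order(-gain[best], cand[best])][1]
        tgt <- cand[pick]
        S[ci] <- S[ci] - strength[i]
        S[tgt] <- S[tgt] + strength[i]
        memb[i] <- tgt
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  match(memb, sort(unique(memb)))
}

#' Giant connected component
#'
#' @param net an `igraph` network.
#' @param partition optionally a precomputed CC partition.
#' @return The cluster id of the largest component (ties: lexicographically
#'   smallest cluster id).
#' @export
giant_component <- function(net, partition = NULL) {
  cc <- partition %||% connected_components(net)
  sizes <- table(cc$cluster)
  names(sizes)[order(-sizes, names(sizes))][1]
}

#' Supernode (quotient) graph over Louvain communities
#'
#' One supernode per community, carrying its size and label composition;
#' two supernodes are connected iff at least one original edge crosses
#' between the two communities.
#'
#' @param net an `igraph` network.
#' @param lc_partition a `kind = "LC"` partition over `net`.
#' @return A list with `graph` (the quotient `igraph`, vertex attribute
#'   `size`, edge attribute `n_cross`) and `composition` (long `data.frame`:
#'   `supernode`, `class` in epoch/site/habitat, `value`, `fraction`).
#' @export
supernode_graph <- function(net, lc_partition) {
  if (!identical(unique(lc_partition$kind), "LC"))
    stopf("supernode_graph expects a kind = \"LC\" partition")
  ids <- igraph::V(net)$name
  memb <- as_membership(lc_partition, ids)
  el <- igraph::as_edgelist(net, names = TRUE)
  cross <- el[memb[el[, 1]] != memb[el[, 2]], , drop = FALSE]
  sn <- sort(unique(memb))
  qedges <- if (nrow(cross) > 0L) {
    a <- memb[cross[, 1]]; b <- memb[cross[, 2]]
    pair <- data.frame(from = pmin(a, b), to = pmax(a, b),
                       stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(n_cross = rep(1L, nrow(pair))),
                            pair, FUN = sum)
    agg
  } else data.frame(from = character(0), to = character(0),
                    n_cross = integer(0))
  g <- igraph::graph_from_data_frame(
    qedges, directed = FALSE,
    vertices = data.frame(name = sn,
                          size = as.integer(table(memb)[sn]),
                          stringsAsFactors = FALSE))
  comp <- list()
  for (cls in c("epoch", "site", "habitat")) {
    vals <- igraph::vertex_attr(net, cls)
    tab <- table(supernode = memb, value = vals, useNA = "no")
    if (nrow(tab) == 0L) next
    for (v in colnames(tab)) {
      comp[[length(comp) + 1L]] <- data.frame(
        supernode = rownames(tab), class = cls, value = v,
        fraction = as.numeric(tab[, v]) /
          as.integer(table(memb)[rownames(tab)]),
        stringsAsFactors = FALSE)
    }
  }
  composition <- if (length(comp) > 0L) do.call(rbind, comp) else
    data.frame(supernode = character(0), class = character(0),
               value = character(0), fraction = numeric(0))
  rownames(composition) <- NULL
  list(graph = g, composition = composition)
}

#' Export a network as a weighted edge list
#'
#' Three tab-separated columns: `node1`, `node2`, `pct_identity`.
#'
#' @param net an `igraph` network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(node1 = el[, 1], node2 = el[, 2],
                   pct_identity = igraph::E(net)$weight,
                   stringsAsFactors = FALSE)
  df <- df[order(df$node1, df$node2), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' @param net an `igraph` network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  # GraphML attributes cannot be NA; encode absent labels as "".
  for (a in igraph::vertex_attr_names(net)) {
    v <- igraph::vertex_attr(net, a)
    if (is.character(v)) net <- igraph::set_vertex_attr(net, a, value = ifelse(is.na(v), "", v))
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Export a partition as TSV
#'
#' Columns `id`, `cluster`, `kind`, `threshold`.
#'
#' @param partition a partition `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition[order(partition$id), , drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
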