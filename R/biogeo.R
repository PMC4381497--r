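#' Two-category assortativity coefficient
#'
#' Newman's categorical assortativity for two categories (nodes carrying a
#' target label versus all other nodes), on unweighted edges. With `e_ij`
#' half the fraction of ordered edge endpoints joining category `i` to `j`
#' and `a_i = sum_j e_ij`:
#' `r = (sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2)`.
#' `r = 0` under random mixing, positive when same-label nodes connect
#' preferentially, negative under disassortative mixing.
#'
#' @param graph an `igraph` (sub)graph with at least one edge.
#' @param target logical vector (in vertex order) or character vector of
#'   vertex names marking the target category.
#' @return `r` in `[-1, 1]`, or `NA` when only one category is present
#'   among the graph's nodes (denominator 0).
#' @export
assortativity_two_cat <- function(graph, target) {
  if (igraph::ecount(graph) == 0L) stopf("assortativity needs >= 1 edge")
  tgt <- as_target(graph, target)
  el <- igraph::as_edgelist(graph, names = FALSE)
  r_from_edges(tgt[el[, 1]], tgt[el[, 2]])
}

as_target <- function(graph, target) {
  if (is.character(target)) {
    tgt <- igraph::V(graph)$name %in% target
  } else {
    stopifnot(is.logical(target), length(target) == igraph::vcount(graph))
    tgt <- target
  }
  tgt
}

# r from the two endpoint label vectors of an edge list.
r_from_edges <- function(t1, t2) {
  m <- length(t1)
  e_tt <- sum(t1 & t2) / m
  e_oo <- sum(!t1 & !t2) / m
  a_t <- (sum(t1) + sum(t2)) / (2 * m)
  denom <- 1 - (a_t^2 + (1 - a_t)^2)
  if (denom <= 0) return(NA_real_)
  (e_tt + e_oo - (a_t^2 + (1 - a_t)^2)) / denom
}

#' Topology-preserving label-shuffle null for assortativity
#'
#' Permutes the node-label multiset over the graph's nodes (category counts
#' preserved, edges untouched) `n_perm` times and returns the assortativity
#' of each permutation. Seeded and reproducible.
#'
#' @param graph an `igraph` (sub)graph with at least one edge.
#' @param target as in [assortativity_two_cat()].
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Numeric vector of length `n_perm` of null `r` values.
#' @export
shuffle_null <- function(graph, target, n_perm = 100L, seed = 1L) {
  if (n_perm == 0L) return(numeric(0))
  tgt <- as_target(graph, target)
  el <- igraph::as_edgelist(graph, names = FALSE)
  with_seed(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample(tgt)
    r_from_edges(p[el[, 1]], p[el[, 2]])
  }, numeric(1)))
}

#' One-sided significance of observed assortativity against the null
#'
#' Two-sample Kolmogorov-Smirnov test of the alternative "observed `r`
#' stochastically greater than null `r`". `NA` values (single-category
#' clusters) must have been excluded symmetrically upstream.
#'
#' @param observed,null numeric vectors of assortativity values.
#' @param alpha significance level (default 0.05).
#' @return A list: `statistic`, `p_value`, `significant`.
#' @export
assortativity_significance <- function(observed, null, alpha = 0.05) {
  observed <- observed[!is.na(observed)]
  null <- null[!is.na(null)]
  if (length(observed) == 0L || length(null) == 0L)
    stopf("observed and null distributions must be non-empty")
  kt <- suppressWarnings(stats::ks.test(observed, null, alternative = "less"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       significant = kt$p.value < alpha)
}

#' Per-cluster assortativity scan with permutation null
#'
#' For every cluster of the partition and every value of the chosen label
#' class (site or habitat), computes the observed two-category assortativity
#' on the cluster's induced subgraph and `n_perm` label-shuffle null values.
#' Clusters lacking edges or carrying only one category for a label value
#' are excluded from both the observed and the null distributions
#' (symmetrically), and recorded with the reason.
#'
#' @param net an `igraph` network with `site`/`habitat` vertex attributes.
#' @param partition a partition `data.frame` (CC or LC).
#' @param label_class `"site"` or `"habitat"`.
#' @param n_perm permutations per cluster-label combination.
#' @param seed RNG seed (each combination gets a derived seed).
#' @return An object of class `assortativity_scan`: list with `observed`
#'   (`data.frame`: cluster, label, r), `null` (`data.frame`: cluster,
#'   label, perm, r), `excluded` (`data.frame`: cluster, label, reason),
#'   `label_class`, `n_perm`.
#' @export
assortativity_scan <- function(net, partition, label_class = c("site", "habitat"),
                               n_perm = 100L, seed = 1L) {
  label_class <- match.arg(label_class)
  ids <- igraph::V(net)$name
  memb <- as_membership(partition, ids)
  labs <- stats::setNames(igraph::vertex_attr(net, label_class), ids)
  values <- sort(unique(labs[!is.na(labs)]))
  obs <- list(); nul <- list(); exc <- list()
  k <- 0L
  for (cl in sort(unique(memb))) {
    sub <- igraph::induced_subgraph(net, ids[memb == cl])
    if (igraph::ecount(sub) == 0L) {
      exc[[length(exc) + 1L]] <- data.frame(cluster = cl, label = NA_character_,
                                            reason = "no_edges")
      next
    }
    sublabs <- igraph::vertex_attr(sub, label_class)
    for (v in values) {
      k <- k + 1L
      tgt <- !is.na(sublabs) & sublabs == v
      if (!any(tgt) || all(tgt)) {
        exc[[length(exc) + 1L]] <- data.frame(cluster = cl, label = v,
                                              reason = "single_category")
        next
      }
      r_obs <- assortativity_two_cat(sub, tgt)
      if (is.na(r_obs)) {
        exc[[length(exc) + 1L]] <- data.frame(cluster = cl, label = v,
                                              reason = "undefined_r")
        next
      }
      r_null <- shuffle_null(sub, tgt, n_perm, seed = derive_seed(seed, k))
      obs[[length(obs) + 1L]] <- data.frame(cluster = cl, label = v, r = r_obs,
                                            stringsAsFactors = FALSE)
      nul[[length(nul) + 1L]] <- data.frame(cluster = cl, label = v,
                                            perm = seq_len(n_perm), r = r_null,
                                            stringsAsFactors = FALSE)
    }
  }
  bindrows <- function(x, proto) if (length(x) > 0L) do.call(rbind, x) else proto
  structure(list(
    observed = bindrows(obs, data.frame(cluster = character(0),
                                        label = character(0), r = numeric(0))),
    null = bindrows(nul, data.frame(cluster = character(0), label = character(0),
                                    perm = integer(0), r = numeric(0))),
    excluded = bindrows(exc, data.frame(cluster = character(0),
                                        label = character(0),
                                        reason = character(0))),
    label_class = label_class, n_perm = n_perm), class = "assortativity_scan")
}

#' Endemism test from an assortativity scan
#'
#' Pools observed and null assortativity values over all clusters (and,
#' for the class-level test, over all label values) and applies the
#' one-sided KS test "observed stochastically greater than null". Returns
#' both the pooled class-level test (the primary endemism statistic) and
#' per-label tests.
#'
#' @param scan an [assortativity_scan()] result.
#' @param alpha significance level.
#' @return A list: `pooled` (list as in [assortativity_significance()],
#'   plus `n_observed`), `per_label` (`data.frame`: label, n_observed,
#'   statistic, p_value, significant), `label_class`.
#' @export
dispersal_test <- function(scan, alpha = 0.05) {
  stopifnot(inherits(scan, "assortativity_scan"))
  if (nrow(scan$observed) == 0L)
    stopf("no cluster-label combination had both categories present")
  pooled <- assortativity_significance(scan$observed$r, scan$null$r, alpha)
  pooled$n_observed <- nrow(scan$observed)
  per <- do.call(rbind, lapply(sort(unique(scan$observed$label)), function(v) {
    o <- scan$observed$r[scan$observed$label == v]
    n <- scan$null$r[scan$null$label == v]
    s <- assortativity_significance(o, n, alpha)
    data.frame(label = v, n_observed = length(o), statistic = s$statistic,
               p_value = s$p_value, significant = s$significant,
               stringsAsFactors = FALSE)
  }))
  list(pooled = pooled, per_label = per, label_class = scan$label_class)
}

#' Simpson evenness index
#'
#' `SI = 1 - sum_i p_i^2` over the proportional abundances `p_i` of a
#' cluster's sequences across sampling sites. 0 for a single-site cluster;
#' upper limit `1 - 1/N` for perfectly even counts over `N` sites.
#'
#' @param counts non-negative per-site counts, sum > 0.
#' @return SI in `[0, 1 - 1/N]`.
#' @export
simpson_evenness <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stopf("counts must be non-negative with positive sum")
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Per-cluster abundance, occurrence and evenness profiles
#'
#' For each cluster: abundance (node count), occurrence (number of distinct
#' sampling sites among environmental members; cultured and
#' prior-environmental members carry no site and are ignored), Simpson
#' evenness of the per-site counts, a cosmopolitan flag (occurrence equals
#' `n_sites`), a restricted flag (occurrence between 1 and
#' `restricted_max`), and the exclusive site/habitat when all environmental
#' members share one.
#'
#' @param partition a partition `data.frame`.
#' @param records record `data.frame`.
#' @param n_sites total number of sampling sites in the design (default 8).
#' @param restricted_max upper bound of the "restricted" occurrence bin
#'   (default 4 sites).
#' @return A `data.frame` with one row per cluster.
#' @export
cluster_profiles <- function(partition, records, n_sites = 8L,
                             restricted_max = 4L) {
  records <- validate_records(records)
  site <- stats::setNames(records$site, records$id)
  habitat <- stats::setNames(records$habitat, records$id)
  memb <- split(partition$id, partition$cluster)
  rows <- lapply(names(memb), function(cl) {
    m <- memb[[cl]]
    s <- site[m]; h <- habitat[m]
    s <- s[!is.na(s)]; h <- h[!is.na(h)]
    occ <- length(unique(s))
    si <- if (occ == 0L) NA_real_ else simpson_evenness(table(s))
    data.frame(
      cluster = cl, abundance = length(m), occurrence = occ,
      evenness = si,
      cosmopolitan = occ == n_sites,
      restricted = occ >= 1L && occ <= restricted_max,
      exclusive_site = if (occ == 1L) unique(s) else NA_character_,
      exclusive_habitat = if (length(h) > 0L && length(unique(h)) == 1L)
        unique(h) else NA_character_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$cluster), , drop = FALSE]
}

#' Fraction of clusters exclusive to each label value
#'
#' A cluster is exclusive to a value when it has at least one environmental
#' member and every environmental member carries that value. The
#' denominator is the total cluster count.
#'
#' @param partition a partition `data.frame`.
#' @param records record `data.frame`.
#' @param label_class `"site"` or `"habitat"`.
#' @return A `data.frame`: `value`, `n_exclusive`, `fraction`.
#' @export
exclusivity_fractions <- function(partition, records,
                                  label_class = c("habitat", "site")) {
  label_class <- match.arg(label_class)
  records <- validate_records(records)
  lab <- stats::setNames(records[[label_class]], records$id)
  memb <- split(partition$id, partition$cluster)
  n_total <- length(memb)
  values <- sort(unique(lab[!is.na(lab)]))
  excl <- vapply(memb, function(m) {
    l <- lab[m]; l <- l[!is.na(l)]
    if (length(l) == 0L || length(unique(l)) != 1L) NA_character_
    else unique(l)
  }, character(1))
  data.frame(
    value = values,
    n_exclusive = vapply(values, function(v) sum(excl == v, na.rm = TRUE),
                         integer(1)),
    fraction = vapply(values, function(v) sum(excl == v, na.rm = TRUE),
                      integer(1)) / n_total,
    stringsAsFactors = FALSE, row.names = NULL)
}
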