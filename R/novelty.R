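#' Epoch composition of clusters
#'
#' Per-cluster fractions of cultured, prior-environmental and new-survey
#' members; fractions sum to 1 within each cluster.
#'
#' @param partition a partition `data.frame`.
#' @param records record `data.frame` supplying the epoch labels.
#' @return A `data.frame` with columns `cluster`, `n`, `frac_cultured`,
#'   `frac_prior_env`, `frac_new_survey`.
#' @export
epoch_composition <- function(partition, records) {
  records <- validate_records(records)
  epoch <- stats::setNames(records$epoch, records$id)[partition$id]
  if (anyNA(epoch)) stopf("partition ids missing from records")
  tab <- table(cluster = partition$cluster,
               epoch = factor(epoch, levels = VALID_EPOCHS))
  frac <- prop.table(tab, margin = 1)
  data.frame(cluster = rownames(tab), n = as.integer(rowSums(tab)),
             frac_cultured = as.numeric(frac[, "cultured"]),
             frac_prior_env = as.numeric(frac[, "prior_env"]),
             frac_new_survey = as.numeric(frac[, "new_survey"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Best identity of each record to a cultured reference pool
#'
#' For each query record, the highest percent identity over all filtered
#' hits against the cultured references; records with no qualifying hit get
#' 0 (and are reported via the `no_hit` attribute).
#'
#' @param query_records records to score.
#' @param cultured_records the cultured reference pool (non-empty).
#' @param hits optional precomputed hit `data.frame` covering
#'   query-vs-reference pairs (e.g. the filtered all-vs-all hits); when
#'   `NULL`, alignments are computed with [all_vs_all_hits()] and filtered
#'   with [filter_hits()] at default settings.
#' @param params an [align_params()] (used only when `hits` is `NULL`).
#' @return Named numeric vector of best identities (0 where no hit), with
#'   attribute `no_hit` listing the ids that had no qualifying hit.
#' @export
best_identity_to_culture <- function(query_records, cultured_records,
                                     hits = NULL, params = align_params()) {
  cultured_records <- validate_records(cultured_records)
  if (nrow(cultured_records) == 0L)
    stopf("empty cultured reference set")
  if (is.null(hits)) {
    pool <- rbind(query_records[, names(cultured_records)], cultured_records)
    pool <- pool[!duplicated(pool$id), , drop = FALSE]
    hits <- filter_hits(all_vs_all_hits(pool, params), pool)
  }
  cult <- cultured_records$id
  rel <- hits[(hits$query_id %in% cult) != (hits$subject_id %in% cult), ,
              drop = FALSE]
  qid <- ifelse(rel$query_id %in% cult, rel$subject_id, rel$query_id)
  best <- stats::setNames(rep(0, nrow(query_records)), query_records$id)
  if (nrow(rel) > 0L) {
    mx <- tapply(rel$pct_identity, qid, max)
    hitids <- intersect(names(mx), names(best))
    best[hitids] <- mx[hitids]
  }
  attr(best, "no_hit") <- names(best)[best == 0]
  best
}

#' Novel Louvain communities
#'
#' A community is novel when (a) every member is a new-survey sequence and
#' (b) the mean over members of each member's best identity to any cultured
#' reference (0 when no qualifying hit) is below `avg_identity_cutoff`.
#' Intended for the most inclusive (85%) threshold network.
#'
#' @param lc_partition a `kind = "LC"` partition.
#' @param records record `data.frame` for all partition members.
#' @param cultured_records the cultured reference pool (non-empty).
#' @param hits optional precomputed filtered hits (see
#'   [best_identity_to_culture()]).
#' @param avg_identity_cutoff mean-identity rule threshold (default 95).
#' @param mean_over `"best_per_member"` (default; mean of per-member best
#'   identities) or `"all_pairs"` (mean over all member-by-reference
#'   qualifying hits).
#' @param params an [align_params()].
#' @return `data.frame` of novel communities: `cluster`, `n`,
#'   `mean_identity`.
#' @export
novel_lcs <- function(lc_partition, records, cultured_records, hits = NULL,
                      avg_identity_cutoff = 95.0,
                      mean_over = c("best_per_member", "all_pairs"),
                      params = align_params()) {
  mean_over <- match.arg(mean_over)
  records <- validate_records(records)
  epoch <- stats::setNames(records$epoch, records$id)
  memb_ids <- split(lc_partition$id, lc_partition$cluster)
  exclusive <- vapply(memb_ids, function(m)
    all(epoch[m] == "new_survey"), logical(1))
  out <- data.frame(cluster = character(0), n = integer(0),
                    mean_identity = numeric(0), stringsAsFactors = FALSE)
  if (!any(exclusive)) return(out)
  cand_ids <- unlist(memb_ids[exclusive], use.names = FALSE)
  qrec <- records[match(cand_ids, records$id), , drop = FALSE]
  best <- best_identity_to_culture(qrec, cultured_records, hits, params)
  if (mean_over == "best_per_member") {
    for (cl in names(memb_ids)[exclusive]) {
      m <- mean(best[memb_ids[[cl]]])
      if (m < avg_identity_cutoff)
        out <- rbind(out, data.frame(cluster = cl,
                                     n = length(memb_ids[[cl]]),
                                     mean_identity = m,
                                     stringsAsFactors = FALSE))
    }
  } else {
    cult <- cultured_records$id
    if (is.null(hits)) {
      pool <- rbind(qrec[, 1:6], cultured_records[, 1:6])
      hits <- filter_hits(all_vs_all_hits(validate_records(pool), params), pool)
    }
    rel <- hits[(hits$query_id %in% cult) != (hits$subject_id %in% cult), ,
                drop = FALSE]
    qid <- ifelse(rel$query_id %in% cult, rel$subject_id, rel$query_id)
    for (cl in names(memb_ids)[exclusive]) {
      v <- rel$pct_identity[qid %in% memb_ids[[cl]]]
      m <- if (length(v) == 0L) 0 else mean(v)
      if (m < avg_identity_cutoff)
        out <- rbind(out, data.frame(cluster = cl,
                                     n = length(memb_ids[[cl]]),
                                     mean_identity = m,
                                     stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out[order(out$cluster), , drop = FALSE]
}

#' Shortest-path distance to the nearest cultured node
#'
#' Unweighted breadth-first distance (edge count) from each environmental
#' node to its closest cultured node; `Inf` when no cultured node is
#' reachable. Cultured nodes themselves are not part of the query set.
#'
#' @param net an `igraph` network with an `epoch` vertex attribute.
#' @return Named numeric vector over the environmental (non-cultured) nodes.
#' @export
distance_to_culture <- function(net) {
  epoch <- igraph::V(net)$epoch
  env <- which(epoch != "cultured")
  cult <- which(epoch == "cultured")
  ids <- igraph::V(net)$name
  if (length(env) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (length(cult) == 0L)
    return(stats::setNames(rep(Inf, length(env)), ids[env]))
  d <- igraph::distances(net, v = env, to = cult, weights = NA)
  stats::setNames(apply(d, 1, min), ids[env])
}

#' Per-component closeness centrality
#'
#' For a node `v` in a component of `n_c` nodes, closeness is
#' `(n_c - 1) / sum of unweighted shortest-path distances` to all other
#' nodes of its component; nodes of a single-edge pair component get 1.
#' Cross-component distances are undefined in a disconnected network, hence
#' the per-component convention.
#'
#' @param net an `igraph` network.
#' @return Named numeric vector over all nodes.
#' @export
node_closeness <- function(net) {
  comp <- igraph::components(net)
  ids <- igraph::V(net)$name
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (c in seq_len(comp$no)) {
    vs <- which(comp$membership == c)
    if (length(vs) == 1L) { out[ids[vs]] <- NA_real_; next }
    d <- igraph::distances(net, v = vs, to = vs, weights = NA)
    out[ids[vs]] <- (length(vs) - 1) / rowSums(d)
  }
  out
}

#' One-sided closeness contrast (Kolmogorov-Smirnov)
#'
#' Tests whether the values of group A (e.g. cultured sequences) are
#' stochastically greater than those of group B (environmental sequences),
#' with the two-sample Kolmogorov-Smirnov test, reporting significance at
#' 0.05 and 0.01.
#'
#' @param a,b numeric vectors (non-empty).
#' @return A list: `statistic`, `p_value`, `direction`,
#'   `significant_05`, `significant_01`.
#' @export
closeness_contrast <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L)
    stopf("both groups must be non-empty")
  # alternative "less": CDF of a below CDF of b, i.e. a stochastically greater
  kt <- suppressWarnings(stats::ks.test(a, b, alternative = "less"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       direction = "A_greater",
       significant_05 = kt$p.value < 0.05,
       significant_01 = kt$p.value < 0.01)
}

#' Novelty report for one threshold network
#'
#' Assembles the reference-free diversity measures for a network and its
#' partitions: per-cluster epoch composition, epoch-exclusive clusters,
#' novel communities (on the LC partition), per-node distance to culture and
#' closeness, and the two closeness contrasts (cultured vs prior
#' environmental; cultured vs all environmental).
#'
#' @param net an `igraph` network.
#' @param cc_partition,lc_partition partitions of `net`.
#' @param records record `data.frame`.
#' @param cultured_records cultured reference pool (may include references
#'   absent from the network).
#' @param hits filtered hit `data.frame` used for the novelty rule.
#' @param avg_identity_cutoff novelty mean-identity rule (default 95).
#' @return A list of tables: `composition`, `exclusive`, `novel`,
#'   `node_measures`, `contrasts`.
#' @export
novelty_report <- function(net, cc_partition, lc_partition, records,
                           cultured_records, hits,
                           avg_identity_cutoff = 95.0) {
  comp <- epoch_composition(lc_partition, records)
  exclusive <- do.call(rbind, lapply(VALID_EPOCHS, function(ep) {
    cl <- comp$cluster[comp[[paste0("frac_", ep)]] == 1]
    data.frame(epoch = rep(ep, length(cl)), kind = rep("LC", length(cl)),
               cluster = cl, stringsAsFactors = FALSE)
  }))
  novel <- novel_lcs(lc_partition, records, cultured_records, hits,
                     avg_identity_cutoff)
  dist <- distance_to_culture(net)
  clo <- node_closeness(net)
  epoch <- stats::setNames(records$epoch, records$id)
  nm <- data.frame(id = names(clo), epoch = unname(epoch[names(clo)]),
                   closeness = unname(clo),
                   distance_to_culture = unname(dist[names(clo)]),
                   stringsAsFactors = FALSE)
  cult_clo <- clo[epoch[names(clo)] == "cultured"]
  pre_clo <- clo[epoch[names(clo)] == "prior_env"]
  env_clo <- clo[epoch[names(clo)] != "cultured"]
  contrasts <- list()
  if (length(cult_clo) > 0L && length(pre_clo) > 0L)
    contrasts$cultured_vs_prior <- closeness_contrast(cult_clo, pre_clo)
  if (length(cult_clo) > 0L && length(env_clo) > 0L)
    contrasts$cultured_vs_all_env <- closeness_contrast(cult_clo, env_clo)
  list(composition = comp, exclusive = exclusive, novel = novel,
       node_measures = nm, contrasts = contrasts)
}
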