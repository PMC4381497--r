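#' Pipeline configuration
#'
#' Bundles every stage parameter with the defaults of the reference
#' protocol: hit filters E-value < 1e-5, identity >= 60%, alignment length
#' >= 40% of the shorter sequence, record length >= 300 bp; network
#' thresholds 85/90/95/96/97/98/99; novelty rule at the 85% threshold with a
#' 95% mean-identity cutoff; permutation null of 100 shuffles; significance
#' levels 0.05 and 0.01. The resolved configuration is written beside every
#' run's outputs.
#'
#' @param fasta input FASTA path(s); ignored when `scenario` is given.
#' @param scenario optional [scenario_config()]: simulate instead of reading.
#' @param blast_tab optional precomputed BLAST tabular hits; when given, the
#'   internal aligner is skipped.
#' @param thresholds percent-identity thresholds for network construction.
#' @param min_len,max_evalue,min_identity,min_cover_frac dataset/hit filters.
#' @param novelty_threshold threshold whose LC partition feeds the novelty
#'   rule.
#' @param novelty_cutoff mean-identity cutoff of the novelty rule.
#' @param profile_threshold threshold whose CC partition feeds the
#'   abundance/occurrence/evenness profiles (conspecific level).
#' @param n_perm label shuffles per cluster-label combination.
#' @param alpha significance levels.
#' @param n_sites number of sites in the sampling design.
#' @param seed root seed; all stage randomness derives from it.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, scenario = NULL, blast_tab = NULL,
                            thresholds = c(85, 90, 95, 96, 97, 98, 99),
                            min_len = 300L, max_evalue = 1e-5,
                            min_identity = 60.0, min_cover_frac = 0.40,
                            novelty_threshold = 85, novelty_cutoff = 95.0,
                            profile_threshold = 97,
                            n_perm = 100L, alpha = c(0.05, 0.01),
                            n_sites = 8L, seed = 1L, out_dir = "ssn_out") {
  if (length(thresholds) == 0L) stopf("thresholds must be non-empty")
  if (any(thresholds <= 0 | thresholds > 100))
    stopf("thresholds must lie in (0, 100]")
  if (is.null(fasta) && is.null(scenario))
    stopf("either fasta input or a scenario must be given")
  structure(list(fasta = fasta, scenario = scenario, blast_tab = blast_tab,
                 thresholds = sort(thresholds), min_len = as.integer(min_len),
                 max_evalue = max_evalue, min_identity = min_identity,
                 min_cover_frac = min_cover_frac,
                 novelty_threshold = novelty_threshold,
                 novelty_cutoff = novelty_cutoff,
                 profile_threshold = profile_threshold,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 n_sites = as.integer(n_sites), seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full similarity-network pipeline
#'
#' Executes: (optional) simulation -> length filter -> per-site
#' dereplication -> all-vs-all similarity (or imported BLAST hits) -> hit
#' filtering -> one network per threshold with CC and level-1 LC partitions
#' -> novelty report at the novelty threshold -> biogeography report
#' (assortativity scans with permutation null at the most inclusive
#' threshold, cluster profiles and exclusivity at the conspecific
#' threshold). Writes TSV/GraphML outputs, the resolved configuration and a
#' JSON manifest of per-stage counts under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (invisibly a list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  manifest <- list(package = "seqsimnet",
                   version = as.character(utils::packageVersion("seqsimnet")),
                   seed = config$seed, counts = list())

  # -- input / simulate ------------------------------------------------
  truth <- NULL
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", generate_dataset(config$scenario))
    records <- sim$records
    truth <- sim
    stage("simulate", {
      write_fasta(records, out("records.fasta"))
      write_truth_table(sim$truth, out("truth.tsv"))
      write_tsv(sim$species, out("truth_species.tsv"))
    })
  } else {
    records <- stage("read", do.call(rbind, lapply(config$fasta, read_fasta)))
  }
  manifest$counts$input <- nrow(records)

  # -- dataset preparation --------------------------------------------
  records <- stage("length_filter", length_filter(records, config$min_len))
  manifest$counts$post_length_filter <- nrow(records)
  derep <- stage("dereplicate", dereplicate(records))
  records <- derep$records
  manifest$counts$post_dereplication <- nrow(records)
  stage("dereplicate", write_tsv(derep$multiplicity, out("multiplicity.tsv")))

  # -- pairwise similarity --------------------------------------------
  hits <- if (!is.null(config$blast_tab)) {
    stage("read_blast", read_blast_tab(config$blast_tab))
  } else {
    stage("align", all_vs_all_hits(records))
  }
  manifest$counts$raw_hits <- nrow(hits)
  hits <- stage("filter_hits",
                filter_hits(hits, records, config$max_evalue,
                            config$min_identity, config$min_cover_frac))
  manifest$counts$filtered_hits <- nrow(hits)
  stage("filter_hits", write_blast_tab(hits, out("hits_filtered.tsv")))

  # -- networks and partitions ----------------------------------------
  nets <- list(); ccs <- list(); lcs <- list()
  manifest$counts$thresholds <- list()
  for (i in seq_along(config$thresholds)) {
    tau <- config$thresholds[i]
    key <- sprintf("t%g", tau)
    net <- stage(key, build_network(hits, records, tau))
    cc <- stage(key, connected_components(net))
    lc <- stage(key, louvain_level1(net, seed = derive_seed(config$seed, i)))
    nets[[key]] <- net; ccs[[key]] <- cc; lcs[[key]] <- lc
    stage(key, {
      write_edge_list(net, out(sprintf("network_%s_edges.tsv", key)))
      write_graphml(net, out(sprintf("network_%s.graphml", key)))
      write_partition(cc, out(sprintf("partition_%s_cc.tsv", key)))
      write_partition(lc, out(sprintf("partition_%s_lc.tsv", key)))
    })
    manifest$counts$thresholds[[key]] <-
      list(nodes = igraph::vcount(net), edges = igraph::ecount(net),
           n_cc = length(unique(cc$cluster)),
           n_lc = length(unique(lc$cluster)))
  }

  # -- novelty ---------------------------------------------------------
  nov_key <- sprintf("t%g", config$novelty_threshold)
  cultured <- records[records$epoch == "cultured", , drop = FALSE]
  novelty <- NULL
  if (!is.null(nets[[nov_key]]) && nrow(cultured) > 0L) {
    novelty <- stage("novelty",
      novelty_report(nets[[nov_key]], ccs[[nov_key]], lcs[[nov_key]],
                     records, cultured, hits, config$novelty_cutoff))
    stage("novelty", {
      write_tsv(novelty$composition, out("novelty_composition.tsv"))
      write_tsv(novelty$novel, out("novelty_novel_lcs.tsv"))
      write_tsv(novelty$node_measures, out("novelty_node_measures.tsv"))
    })
    manifest$counts$novel_lcs <- nrow(novelty$novel)
  }

  # -- biogeography ----------------------------------------------------
  bio_key <- sprintf("t%g", min(config$thresholds))
  prof_key <- sprintf("t%g", config$profile_threshold)
  biogeo <- list()
  if (!is.null(nets[[bio_key]])) {
    for (cls in c("site", "habitat")) {
      scan <- stage("biogeo",
        assortativity_scan(nets[[bio_key]], ccs[[bio_key]], cls,
                           config$n_perm,
                           seed = derive_seed(config$seed, 900L +
                                                match(cls, c("site", "habitat")))))
      if (nrow(scan$observed) > 0L) {
        dt <- dispersal_test(scan, alpha = config$alpha[1])
        biogeo[[paste0("assortativity_", cls)]] <- dt
        stage("biogeo", write_tsv(scan$observed,
                                  out(sprintf("assortativity_%s_observed.tsv", cls))))
      }
    }
  }
  if (!is.null(ccs[[prof_key]])) {
    profiles <- stage("biogeo",
      cluster_profiles(ccs[[prof_key]], records, config$n_sites))
    stage("biogeo", write_tsv(profiles, out("cluster_profiles.tsv")))
    biogeo$profiles <- profiles
    for (cls in c("site", "habitat")) {
      ex <- stage("biogeo", exclusivity_fractions(ccs[[prof_key]], records, cls))
      stage("biogeo", write_tsv(ex, out(sprintf("exclusivity_%s.tsv", cls))))
      biogeo[[paste0("exclusivity_", cls)]] <- ex
    }
  }

  # -- manifest / resolved config -------------------------------------
  resolved <- config
  resolved$scenario <- if (!is.null(config$scenario))
    unclass(config$scenario) else NULL
  jsonlite::write_json(unclass(resolved), out("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, records = records, hits = hits,
                 networks = nets, cc = ccs, lc = lcs, novelty = novelty,
                 biogeo = biogeo, truth = truth))
}
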