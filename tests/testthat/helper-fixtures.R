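# Shared fixtures: small mock networks and memoized full-scenario runs.

# Minimal record table for hit-driven mock networks (sequences are dummies
# of a stated length; labels settable per id).
mock_records <- function(ids, len = 380L, epoch = "new_survey",
                         site = "site_1", habitat = "DCM") {
  n <- length(ids)
  epoch <- rep_len(epoch, n)
  site <- rep_len(site, n); habitat <- rep_len(habitat, n)
  site[epoch == "cultured"] <- NA
  habitat[epoch == "cultured"] <- NA
  sequence_records(ids, strrep("A", len), epoch = epoch,
                   site = site, habitat = habitat)
}

# A hit row list in the 12-column layout from just the fields that matter.
mock_hits <- function(query, subject, pident, alen = 380L, evalue = 1e-50) {
  n <- length(query)
  data.frame(query_id = query, subject_id = subject,
             pct_identity = pident, align_length = rep_len(alen, n),
             mismatches = 0L, gap_openings = 0L,
             qstart = 1L, qend = rep_len(alen, n),
             sstart = 1L, send = rep_len(alen, n),
             evalue = rep_len(evalue, n), bitscore = 100,
             stringsAsFactors = FALSE)
}

# The five-node mock network of the worked example: A-B 99, B-C 97,
# D-E 97, C-D 96.
figure_mock <- function() {
  recs <- mock_records(c("A", "B", "C", "D", "E"))
  hits <- mock_hits(c("A", "B", "D", "C"), c("B", "C", "E", "D"),
                    c(99, 97, 97, 96))
  list(records = recs, hits = hits)
}

# Memoized default-scale scenario runs (one per dispersal mode): the
# alignment stage is the expensive part, so every test file shares these.
.scenario_cache <- new.env(parent = emptyenv())

scenario_run <- function(mode, seed = 11L) {
  key <- paste(mode, seed, sep = "_")
  if (!is.null(.scenario_cache[[key]])) return(.scenario_cache[[key]])
  cfg <- scenario_config(dispersal_mode = mode, seed = seed)
  sim <- generate_dataset(cfg)
  hits <- filter_hits(all_vs_all_hits(sim$records), sim$records)
  nets <- list()
  for (tau in c(85, 90, 95, 96, 97, 98, 99))
    nets[[sprintf("t%d", tau)]] <- build_network(hits, sim$records, tau)
  run <- list(config = cfg, sim = sim, hits = hits, nets = nets,
              cc85 = connected_components(nets$t85),
              lc85 = louvain_level1(nets$t85, seed = 1L),
              cc97 = connected_components(nets$t97),
              cultured = sim$records[sim$records$epoch == "cultured", ,
                                     drop = FALSE],
              truth_of = stats::setNames(sim$records$truth_species,
                                         sim$records$id))
  .scenario_cache[[key]] <- run
  run
}

# Species detected as novel, given the novel-LC table of a run.
novel_species_detected <- function(run, novel_tab) {
  unique(unlist(lapply(novel_tab$cluster, function(cl)
    unique(run$truth_of[run$lc85$id[run$lc85$cluster == cl]]))))
}
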