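#' Scenario configuration for the synthetic community generator
#'
#' Defines a planted-species dataset emulating a multi-site, multi-habitat
#' amplicon survey (V4-like fragment length, eight coastal sites, three
#' habitats) with a cultured reference pool. Species centroids are drawn as
#' radiations from a small number of family ancestors, so that sibling
#' species merge into one connected component at the most inclusive (85%)
#' identity threshold yet separate at 90% and above, while sequences within a
#' species stay above 99% identity on average.
#'
#' @param n_species number of planted species.
#' @param seqs_per_species environmental (new-survey) sequences per species.
#' @param seq_length sequence length in nucleotides (default 380, V4-like).
#' @param within_species_divergence per-site substitution probability applied
#'   to each member relative to its species centroid (default 0.005, i.e.
#'   about 99% expected pairwise identity within a species).
#' @param between_species_divergence minimum pairwise divergence enforced
#'   between species centroids by rejection sampling (default 0.10).
#' @param radiation_divergence per-site substitution probability from a family
#'   ancestor to each anchored (cultured) species centroid (default 0.085,
#'   giving ~84-86% identity between sibling species, so cross-species pairs
#'   straddle the 85% threshold: families form connected components at 85%
#'   while species separate cleanly at 90% and above).
#' @param novel_divergence per-site substitution probability from the family
#'   ancestor to each planted-novel species centroid (default 0.13, ~76%
#'   identity to sibling species: novel species stay detached at every
#'   network threshold, like divergent novel lineages, while remaining
#'   alignable to the cultured pool for the mean-identity novelty rule).
#' @param species_per_family sibling species drawn from one ancestor.
#' @param n_sites number of sampling sites (default 8).
#' @param habitats habitat label set.
#' @param dispersal_mode `"endemic"` (each species confined to one site),
#'   `"cosmopolitan"` (each species present at every site, member sites
#'   marginally uniform) or `"habitat_structured"` (a fraction of species
#'   confined to one habitat).
#' @param frac_confined fraction of species confined to `confined_habitat`
#'   in `habitat_structured` mode.
#' @param confined_habitat the habitat confined species are restricted to.
#' @param frac_cultured fraction of species anchored by a cultured reference
#'   (the unmutated centroid, epoch `"cultured"`).
#' @param frac_novel fraction of species with no cultured reference whose
#'   centroid is verified `< 95%` identical to every cultured centroid.
#'   `frac_cultured + frac_novel` must equal 1 so that planted novelty is
#'   well defined.
#' @param prior_env_per_species sequences from "earlier environmental
#'   studies" (epoch `"prior_env"`, no site/habitat) emitted per cultured
#'   species.
#' @param molecule molecule label applied to environmental sequences.
#' @param indel_rate per-site indel probability (default 0; the substitution-
#'   only model keeps percent identity in closed form).
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_species = 40L, seqs_per_species = 20L,
                            seq_length = 380L,
                            within_species_divergence = 0.005,
                            between_species_divergence = 0.10,
                            radiation_divergence = 0.085,
                            novel_divergence = 0.13,
                            species_per_family = 5L,
                            n_sites = 8L,
                            habitats = c("subsurface", "DCM", "sediment"),
                            dispersal_mode = c("endemic", "cosmopolitan",
                                               "habitat_structured"),
                            frac_confined = 0.5,
                            confined_habitat = "sediment",
                            frac_cultured = 0.75, frac_novel = 0.25,
                            prior_env_per_species = 1L,
                            molecule = "DNA", indel_rate = 0,
                            seed = 1L) {
  dispersal_mode <- match.arg(dispersal_mode)
  for (nm in c("n_species", "seqs_per_species", "seq_length", "n_sites",
               "species_per_family"))
    if (!is_count(get(nm))) stopf("%s must be a count >= 1", nm)
  for (nm in c("within_species_divergence", "between_species_divergence",
               "radiation_divergence", "novel_divergence", "frac_confined",
               "frac_cultured", "frac_novel", "indel_rate"))
    if (!is_prob(get(nm))) stopf("%s must be a probability in [0,1]", nm)
  if (abs(frac_cultured + frac_novel - 1) > 1e-9)
    stopf("frac_cultured + frac_novel must equal 1 (every species is either anchored or planted-novel)")
  if (!confined_habitat %in% habitats)
    stopf("confined_habitat must be one of the configured habitats")
  if (prior_env_per_species < 0 || prior_env_per_species != round(prior_env_per_species))
    stopf("prior_env_per_species must be a non-negative integer")
  structure(list(
    n_species = as.integer(n_species),
    seqs_per_species = as.integer(seqs_per_species),
    seq_length = as.integer(seq_length),
    within_species_divergence = within_species_divergence,
    between_species_divergence = between_species_divergence,
    radiation_divergence = radiation_divergence,
    novel_divergence = novel_divergence,
    species_per_family = as.integer(species_per_family),
    n_sites = as.integer(n_sites),
    sites = sprintf("site_%d", seq_len(n_sites)),
    habitats = habitats,
    dispersal_mode = dispersal_mode,
    frac_confined = frac_confined,
    confined_habitat = confined_habitat,
    frac_cultured = frac_cultured,
    frac_novel = frac_novel,
    prior_env_per_species = as.integer(prior_env_per_species),
    molecule = molecule,
    indel_rate = indel_rate,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

BASES <- c("A", "C", "G", "T")

random_seq_chars <- function(len) sample(BASES, len, replace = TRUE)

# Substitution-only mutation of a character-vector sequence: each site is
# replaced, with probability `rate`, by one of the three other bases.
mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  chars
}

apply_indels <- function(chars, rate) {
  if (rate <= 0) return(chars)
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) next                         # deletion
    out <- c(out, ch)
    if (u >= rate / 2 && u < rate) out <- c(out, sample(BASES, 1L))  # insertion
  }
  if (length(out) == 0L) out <- sample(BASES, 1L)
  out
}

# Exact fraction of differing sites between equal-length char vectors.
hamming_divergence <- function(a, b) mean(a != b)

#' Generate a synthetic labelled community with ground truth
#'
#' Draws family ancestors, radiates species centroids from them (rejection
#' sampling enforces the minimum between-species divergence and, for planted
#' novel species, `< 95%` identity to every cultured centroid), then emits
#' per species: an optional cultured reference (the unmutated centroid),
#' optional prior-environmental sequences, and `seqs_per_species` new-survey
#' members mutated i.i.d. at `within_species_divergence`, with site/habitat
#' labels drawn according to `dispersal_mode`.
#'
#' @param config a [scenario_config()].
#' @param max_attempts rejection-sampling bound per centroid; exceeding it
#'   signals incompatible divergence settings.
#' @return A list with elements `records` (record `data.frame`), `truth`
#'   (per-record `id`, `truth_species`, `dispersal_mode`) and `species`
#'   (per-species table: family, cultured/novel status, planted site or
#'   confined habitat).
#' @export
generate_dataset <- function(config, max_attempts = 1000L) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, generate_dataset_impl(config, max_attempts))
}

generate_dataset_impl <- function(cfg, max_attempts) {
  n_fam <- ceiling(cfg$n_species / cfg$species_per_family)
  ancestors <- lapply(seq_len(n_fam), function(i) random_seq_chars(cfg$seq_length))
  family_of <- rep(seq_len(n_fam), each = cfg$species_per_family)[seq_len(cfg$n_species)]

  n_novel <- round(cfg$frac_novel * cfg$n_species)
  novel_idx <- if (n_novel > 0) sort(sample(cfg$n_species, n_novel)) else integer(0)
  is_novel <- seq_len(cfg$n_species) %in% novel_idx
  has_culture <- !is_novel

  max_id <- 1 - cfg$between_species_divergence
  centroids <- vector("list", cfg$n_species)
  for (s in seq_len(cfg$n_species)) {
    ok <- FALSE
    div_s <- if (is_novel[s]) cfg$novel_divergence else cfg$radiation_divergence
    for (attempt in seq_len(max_attempts)) {
      cand <- mutate_chars(ancestors[[family_of[s]]], div_s)
      prev <- seq_len(s - 1L)
      sep <- all(vapply(prev, function(p)
        1 - hamming_divergence(cand, centroids[[p]]) <= max_id, logical(1)))
      # planted-novel species must be < 95% identical to every cultured centroid
      nov_ok <- !is_novel[s] || all(vapply(prev[has_culture[prev]], function(p)
        1 - hamming_divergence(cand, centroids[[p]]) < 0.95, logical(1)))
      if (sep && nov_ok) { centroids[[s]] <- cand; ok <- TRUE; break }
    }
    if (!ok)
      stopf("rejection sampling failed for species %d after %d attempts; divergence settings are incompatible", s, max_attempts)
  }

  species_id <- sprintf("sp%02d", seq_len(cfg$n_species))
  endemic_site <- rep(NA_character_, cfg$n_species)
  confined <- rep(FALSE, cfg$n_species)
  if (cfg$dispersal_mode == "endemic") {
    endemic_site <- sample(cfg$sites, cfg$n_species, replace = TRUE)
  } else if (cfg$dispersal_mode == "habitat_structured") {
    n_conf <- round(cfg$frac_confined * cfg$n_species)
    confined[sample(cfg$n_species, n_conf)] <- TRUE
  }

  member_sites <- function(s) {
    k <- cfg$seqs_per_species
    switch(cfg$dispersal_mode,
      endemic = rep(endemic_site[s], k),
      # random surjection: every site present when k >= n_sites, each member's
      # marginal site distribution uniform
      cosmopolitan = {
        base <- sample(cfg$sites)
        extra <- if (k > cfg$n_sites)
          sample(cfg$sites, k - cfg$n_sites, replace = TRUE) else character(0)
        sample(c(base, extra))[seq_len(k)]
      },
      habitat_structured = sample(cfg$sites, k, replace = TRUE)
    )
  }
  member_habitats <- function(s) {
    k <- cfg$seqs_per_species
    if (cfg$dispersal_mode == "habitat_structured" && confined[s])
      rep(cfg$confined_habitat, k)
    else sample(cfg$habitats, k, replace = TRUE)
  }

  rows <- list()
  for (s in seq_len(cfg$n_species)) {
    cen <- centroids[[s]]
    if (has_culture[s]) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("CUL_%s", species_id[s]),
        sequence = paste(cen, collapse = ""), molecule = cfg$molecule,
        epoch = "cultured", site = NA_character_, habitat = NA_character_,
        truth_species = species_id[s], stringsAsFactors = FALSE)
      for (j in seq_len(cfg$prior_env_per_species)) {
        seqc <- apply_indels(mutate_chars(cen, cfg$within_species_divergence),
                             cfg$indel_rate)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("PRE_%s_%02d", species_id[s], j),
          sequence = paste(seqc, collapse = ""), molecule = cfg$molecule,
          epoch = "prior_env", site = NA_character_, habitat = NA_character_,
          truth_species = species_id[s], stringsAsFactors = FALSE)
      }
    }
    sites_s <- member_sites(s)
    habs_s <- member_habitats(s)
    for (j in seq_len(cfg$seqs_per_species)) {
      seqc <- apply_indels(mutate_chars(cen, cfg$within_species_divergence),
                           cfg$indel_rate)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("ENV_%s_%03d", species_id[s], j),
        sequence = paste(seqc, collapse = ""), molecule = cfg$molecule,
        epoch = "new_survey", site = sites_s[j], habitat = habs_s[j],
        truth_species = species_id[s], stringsAsFactors = FALSE)
    }
  }
  records <- validate_records(do.call(rbind, rows))

  truth <- data.frame(id = records$id, truth_species = records$truth_species,
                      dispersal_mode = cfg$dispersal_mode,
                      stringsAsFactors = FALSE)
  species <- data.frame(
    species = species_id, family = sprintf("fam%02d", family_of),
    is_novel = is_novel, has_culture = has_culture,
    endemic_site = endemic_site,
    confined_habitat = ifelse(confined, cfg$confined_habitat, NA_character_),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth, species = species)
}

#' Write a ground-truth table as TSV
#'
#' @param truth the per-record truth table from [generate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
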