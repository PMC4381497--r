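#' Labelled amplicon sequence records
#'
#' A record set is a plain `data.frame` with one row per sequence and columns
#' `id`, `sequence`, `molecule` (`"DNA"` or `"cDNA"`), `epoch` (`"cultured"`,
#' `"prior_env"` or `"new_survey"`), `site`, `habitat` and `truth_species`.
#' `site`/`habitat` are `NA` where the label does not apply (cultured isolates
#' and sequences from earlier environmental projects carry no sampling site);
#' `truth_species` is `NA` except for synthetic data, where it names the
#' planted species.
#'
#' @param id character vector of unique sequence identifiers.
#' @param sequence character vector of nucleotide sequences (IUPAC alphabet).
#' @param molecule,epoch,site,habitat,truth_species per-record labels,
#'   recycled if length 1; `site`, `habitat` and `truth_species` may be `NA`.
#' @return A validated record `data.frame`.
#' @examples
#' sequence_records(c("a", "b"), c("ACGT", "AAAA"), epoch = "new_survey",
#'                  site = "site_1", habitat = "DCM")
#' @export
sequence_records <- function(id, sequence, molecule = "DNA",
                             epoch = "new_survey", site = NA_character_,
                             habitat = NA_character_,
                             truth_species = NA_character_) {
  n <- length(id)
  rec <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    molecule = rep_len(as.character(molecule), n),
    epoch = rep_len(as.character(epoch), n),
    site = rep_len(as.character(site), n),
    habitat = rep_len(as.character(habitat), n),
    truth_species = rep_len(as.character(truth_species), n),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
}

VALID_EPOCHS <- c("cultured", "prior_env", "new_survey")
VALID_MOLECULES <- c("DNA", "cDNA")
IUPAC_REGEX <- "^[ACGTUMRWSYKVHDBN-]+$"

validate_records <- function(rec) {
  stopifnot(is.data.frame(rec))
  needed <- c("id", "sequence", "molecule", "epoch", "site", "habitat")
  if (!all(needed %in% names(rec)))
    stopf("record table lacks columns: %s",
          paste(setdiff(needed, names(rec)), collapse = ", "))
  if (!("truth_species" %in% names(rec))) rec$truth_species <- NA_character_
  if (anyDuplicated(rec$id))
    stopf("duplicate record ids: %s",
          paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  if (any(!nzchar(rec$sequence)))
    stopf("empty sequence for record(s): %s",
          paste(rec$id[!nzchar(rec$sequence)], collapse = ", "))
  bad <- !grepl(IUPAC_REGEX, rec$sequence)
  if (any(bad))
    stopf("non-IUPAC characters in sequence(s): %s",
          paste(rec$id[bad], collapse = ", "))
  if (any(!rec$epoch %in% VALID_EPOCHS))
    stopf("epoch must be one of %s", paste(VALID_EPOCHS, collapse = "/"))
  if (any(!rec$molecule %in% VALID_MOLECULES))
    stopf("molecule must be one of %s", paste(VALID_MOLECULES, collapse = "/"))
  cult <- rec$epoch == "cultured"
  if (any(cult & (!is.na(rec$site) | !is.na(rec$habitat))))
    stopf("cultured records must not carry site or habitat labels")
  rownames(rec) <- NULL
  rec
}

fasta_header <- function(rec) {
  fields <- c(molecule = rec$molecule, epoch = rec$epoch,
              site = rec$site, habitat = rec$habitat)
  fields <- fields[!is.na(fields)]
  paste(c(rec$id, paste0(names(fields), "=", fields)), collapse = "|")
}

#' Write labelled records to FASTA
#'
#' Headers use the key=value dialect
#' `>id|molecule=..|epoch=..|site=..|habitat=..`, omitting absent fields, and
#' round-trip losslessly through [read_fasta()] (apart from `truth_species`,
#' which travels in the separate truth table).
#'
#' @param records a record `data.frame` (see [sequence_records()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- validate_records(records)
  if (nrow(records) == 0L) stopf("refusing to write an empty FASTA")
  headers <- vapply(seq_len(nrow(records)),
                    function(i) fasta_header(records[i, ]), character(1))
  seqs <- Biostrings::DNAStringSet(records$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80L)
  invisible(path)
}

#' Read labelled records from FASTA
#'
#' Parses the header dialect written by [write_fasta()]; headers without
#' key=value fields yield records with default labels (`molecule = "DNA"`,
#' `epoch = "new_survey"`).
#'
#' @param path FASTA file path.
#' @return A record `data.frame`.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("no sequences in %s", path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  parse1 <- function(p) {
    out <- c(molecule = "DNA", epoch = "new_survey",
             site = NA_character_, habitat = NA_character_)
    for (tok in p[-1]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2L && kv[1] %in% names(out)) out[kv[1]] <- kv[2]
    }
    out
  }
  meta <- t(vapply(parts, parse1, character(4)))
  sequence_records(
    id = vapply(parts, `[`, character(1), 1L),
    sequence = as.character(seqs),
    molecule = meta[, "molecule"], epoch = meta[, "epoch"],
    site = meta[, "site"], habitat = meta[, "habitat"]
  )
}
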