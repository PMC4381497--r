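#' Length filter for amplicon records
#'
#' Retains records with at least `min_len` nucleotides (the classical
#' "at least 300 bp" dataset-preparation rule), preserving input order.
#'
#' @param records record `data.frame`.
#' @param min_len minimum length in nucleotides (inclusive).
#' @return The filtered record `data.frame`.
#' @export
length_filter <- function(records, min_len = 300L) {
  records <- validate_records(records)
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

#' Per-site dereplication
#'
#' Collapses identical sequence strings (case-folded) to one representative
#' within each (site, molecule) group; cultured and prior-environmental
#' records, which carry no site, are grouped by epoch (and molecule) instead.
#' Identical sequences observed at different sites are each kept once per
#' site. The first occurrence in input order is the representative.
#'
#' @param records record `data.frame`.
#' @param collapse_revcomp also collapse a sequence with its reverse
#'   complement (off by default: same-stranded amplicons).
#' @return A list with `records` (representatives, input order preserved) and
#'   `multiplicity` (`data.frame` of `id`, `n_replaced`: how many input
#'   records each representative stands for, itself included).
#' @export
dereplicate <- function(records, collapse_revcomp = FALSE) {
  records <- validate_records(records)
  if (nrow(records) == 0L)
    return(list(records = records,
                multiplicity = data.frame(id = character(0),
                                          n_replaced = integer(0))))
  seqs <- toupper(records$sequence)
  if (collapse_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    seqs <- pmin(seqs, rc)  # canonical strand: lexicographic min
  }
  grp <- ifelse(records$epoch %in% c("cultured", "prior_env"),
                paste0("epoch:", records$epoch), paste0("site:", records$site))
  key <- paste(grp, records$molecule, seqs, sep = "\r")
  keep <- !duplicated(key)
  reps <- records[keep, , drop = FALSE]
  counts <- table(key)
  mult <- data.frame(id = reps$id,
                     n_replaced = as.integer(counts[key[keep]]),
                     stringsAsFactors = FALSE)
  rownames(reps) <- NULL
  list(records = reps, multiplicity = mult)
}

#' Alignment scoring parameters
#'
#' BLASTN-like local alignment scoring (match +1, mismatch -2, gap open -5,
#' gap extend -2) and the Karlin-Altschul parameters used for E-values.
#' `lambda` is solved from the score-generating equation under uniform base
#' composition; for +1/-2 it has the closed form `log((3 + sqrt(21))/2)`.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores (penalties
#'   positive for the gap terms).
#' @param K Karlin-Altschul K (default 0.46, the standard ungapped value for
#'   the +1/-2 score pair).
#' @param db_size effective database size in nucleotides; `NULL` means "use
#'   the subject length" in [align_pair()] or the total residue count in
#'   [all_vs_all_hits()].
#' @return An `align_params` list (with the solved `lambda`).
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 5,
                         gap_extend = 2, K = 0.46, db_size = NULL) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0, K > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, db_size = db_size,
                 lambda = ka_lambda(match, mismatch)),
            class = "align_params")
}

# Solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for uniform base composition:
# (4 exp(lambda*match) + 12 exp(lambda*mismatch)) / 16 = 1.
ka_lambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-9, 10), tol = 1e-12)$root
}

ka_evalue <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

ka_bitscore <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), align_length = integer(0),
             mismatches = integer(0), gap_openings = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

# Build a hits data.frame from a batch of Smith-Waterman statistics
# (the compiled aligner; one subject, many queries).
hits_from_sw <- function(stats, query_ids, query_lens, subject_id,
                         subject_len, params, db_size) {
  keep <- which(stats[, "score"] > 0)
  if (length(keep) == 0L) return(empty_hits())
  st <- stats[keep, , drop = FALSE]
  data.frame(
    query_id = query_ids[keep], subject_id = subject_id,
    pct_identity = 100 * st[, "matches"] / st[, "align_length"],
    align_length = st[, "align_length"],
    mismatches = st[, "mismatches"], gap_openings = st[, "gap_openings"],
    qstart = st[, "qstart"], qend = st[, "qend"],
    sstart = st[, "sstart"], send = st[, "send"],
    evalue = ka_evalue(st[, "score"], query_lens[keep],
                       db_size %||% subject_len, params),
    bitscore = ka_bitscore(st[, "score"], params),
    stringsAsFactors = FALSE)
}

#' Local alignment of one sequence pair
#'
#' Smith-Waterman local alignment (affine gaps, compiled) under the scoring
#' of [align_params()]. Percent identity is matches divided by alignment
#' columns (gap columns included) times 100, the `pident` convention of
#' BLAST tabular output. The E-value follows the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' effective database size.
#'
#' @param a,b single-row record `data.frame`s (or lists with `id` and
#'   `sequence`).
#' @param params an [align_params()].
#' @return A one-row hit `data.frame`, or `NULL` when no local alignment
#'   scores above zero.
#' @export
align_pair <- function(a, b, params = align_params()) {
  for (r in list(a, b)) {
    if (is.null(r$sequence) || !nzchar(r$sequence))
      stopf("align_pair needs non-empty sequences")
    if (!grepl(IUPAC_REGEX, toupper(r$sequence)))
      stopf("malformed sequence (non-IUPAC characters) in record '%s'",
            r$id %||% "?")
  }
  st <- .sw_align_batch(toupper(a$sequence), toupper(b$sequence),
                        params$match, params$mismatch,
                        params$gap_open, params$gap_extend)
  hits <- hits_from_sw(st, a$id %||% "query", nchar(a$sequence),
                       b$id %||% "subject", nchar(b$sequence),
                       params, params$db_size)
  if (nrow(hits) == 0L) NULL else hits
}

#' All-vs-all similarity search
#'
#' Finds candidate record pairs sharing at least one exact word of
#' `word_size` nucleotides (a seed prefilter, so that unrelated pairs are
#' never fully aligned), then scores each candidate pair with the
#' Smith-Waterman aligner of [align_pair()]. Pairs sharing no word yield no
#' hit. Output is an unfiltered hit table in 12-column BLAST tabular layout;
#' apply [filter_hits()] before building networks.
#'
#' @param records record `data.frame`.
#' @param params an [align_params()]; its `db_size` defaults to the total
#'   residue count of `records`.
#' @param word_size exact-match seed length (default 12).
#' @return A hit `data.frame` (one row per ordered candidate pair direction
#'   collapsed to query < subject by input order; symmetrization proper is
#'   done in [filter_hits()]).
#' @export
all_vs_all_hits <- function(records, params = align_params(), word_size = 12L) {
  records <- validate_records(records)
  n <- nrow(records)
  if (n < 2L) return(empty_hits())
  if (is.null(params$db_size)) params$db_size <- sum(nchar(records$sequence))
  seqs <- toupper(records$sequence)

  # sparse sequence x word incidence; shared-word counts via tcrossprod
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < word_size) return(character(0))
    unique(substring(s, 1:(L - word_size + 1L), word_size:L))
  })
  all_k <- unique(unlist(kmers))
  if (length(all_k) == 0L) return(empty_hits())
  ii <- rep(seq_len(n), lengths(kmers))
  jj <- match(unlist(kmers), all_k)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n, length(all_k)))
  shared <- Matrix::tcrossprod(M)
  cand <- Matrix::which(shared >= 1, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_hits())

  lens <- nchar(seqs)
  out <- vector("list", 0L)
  for (j in sort(unique(cand[, 2]))) {
    qi <- cand[cand[, 2] == j, 1]
    st <- .sw_align_batch(seqs[qi], seqs[j], params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
    h <- hits_from_sw(st, records$id[qi], lens[qi], records$id[j],
                      lens[j], params, params$db_size)
    if (nrow(h) > 0L) out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

BLAST_COLS <- c("query_id", "subject_id", "pct_identity", "align_length",
                "mismatches", "gap_openings", "qstart", "qend",
                "sstart", "send", "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' Parses the standard 12-column layout (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`); extra columns
#' are ignored; a row with fewer than 12 fields is a parse error naming the
#' line.
#'
#' @param path path to a BLAST tabular file.
#' @return A hit `data.frame`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 12L))
    stopf("malformed BLAST tabular row (need 12 columns, got %d) at line %d",
          nf[which(nf < 12L)[1]], which(nf < 12L)[1])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(k) {
    v <- suppressWarnings(as.numeric(m[, k]))
    if (anyNA(v))
      stopf("non-numeric value in column %d at line %d", k, which(is.na(v))[1])
    v
  }
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             pct_identity = num(3), align_length = as.integer(num(4)),
             mismatches = as.integer(num(5)), gap_openings = as.integer(num(6)),
             qstart = as.integer(num(7)), qend = as.integer(num(8)),
             sstart = as.integer(num(9)), send = as.integer(num(10)),
             evalue = num(11), bitscore = num(12),
             stringsAsFactors = FALSE)
}

#' Write hits in BLAST tabular layout
#'
#' @param hits hit `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(BLAST_COLS %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3e\t%.1f",
                   hits$query_id, hits$subject_id, hits$pct_identity,
                   hits$align_length, hits$mismatches, hits$gap_openings,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Filter pairwise hits into an edge candidate list
#'
#' Applies the classical similarity-network filters: E-value strictly below
#' `max_evalue`, percent identity at least `min_identity`, and alignment
#' length at least `min_cover_frac` of the shorter of the two sequences
#' (both inclusive). Self-hits are removed and the hit set is symmetrized:
#' per unordered pair the hit with the greatest identity is kept (ties:
#' greatest alignment length, then lowest E-value), with `query_id` set to
#' the lexicographically smaller id.
#'
#' The operation is idempotent and invariant under swapping query/subject
#' roles in the input.
#'
#' @param hits hit `data.frame`.
#' @param records record `data.frame` supplying sequence lengths.
#' @param max_evalue E-value threshold (exclusive).
#' @param min_identity percent-identity threshold (inclusive).
#' @param min_cover_frac minimum alignment length as a fraction of the
#'   shorter sequence (inclusive; evaluated with 1e-9 absolute slack against
#'   floating-point representation of the product).
#' @return The filtered, symmetrized hit `data.frame`, ordered by pair.
#' @export
filter_hits <- function(hits, records, max_evalue = 1e-5,
                        min_identity = 60.0, min_cover_frac = 0.40) {
  stopifnot(all(BLAST_COLS[1:4] %in% names(hits)))
  records <- validate_records(records)
  if (nrow(hits) == 0L) return(hits)
  len <- stats::setNames(nchar(records$sequence), records$id)
  unknown <- setdiff(c(hits$query_id, hits$subject_id), names(len))
  if (length(unknown) > 0L)
    stopf("hit ids not present in records: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  min_len <- pmin(len[hits$query_id], len[hits$subject_id])
  keep <- hits$evalue < max_evalue &
    hits$pct_identity >= min_identity &
    hits$align_length >= min_cover_frac * min_len - 1e-9
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) { rownames(hits) <- NULL; return(hits) }

  # canonical orientation: query = lexicographically smaller id
  swap <- hits$query_id > hits$subject_id
  if (any(swap)) {
    tmp <- hits$query_id[swap]
    hits$query_id[swap] <- hits$subject_id[swap]
    hits$subject_id[swap] <- tmp
    for (p in list(c("qstart", "sstart"), c("qend", "send"))) {
      t2 <- hits[[p[1]]][swap]
      hits[[p[1]]][swap] <- hits[[p[2]]][swap]
      hits[[p[2]]][swap] <- t2
    }
  }
  ord <- order(hits$query_id, hits$subject_id, -hits$pct_identity,
               -hits$align_length, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
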