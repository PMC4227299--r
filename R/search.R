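# Homology search: exact affine Smith-Waterman, a two-hit k-mer seeded
# backend, Karlin-Altschul E-values, and BLAST tabular interoperability.

# Gapped BLOSUM62 / gap open 11 / gap extend 1 Karlin-Altschul constants.
KA_LAMBDA <- 0.267
KA_K <- 0.041
GAP_OPEN <- 11L
GAP_EXT <- 1L
SEED_K <- 4L

#' Optimal local alignment of two protein sequences
#'
#' Full affine-gap Smith-Waterman under BLOSUM62 with gap open 11 and
#' gap extend 1 (a gap of length L costs 11 + L). The score floor is 0:
#' two sequences with no positive-scoring local segment score 0 with an
#' empty alignment.
#'
#' @param a,b protein sequences (character scalars).
#' @return A list with `raw_score`, `alignment_length` and
#'   `percent_identity` (0 when no alignment exists).
#' @export
align_pair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_sw_align(encode_protein(toupper(a)), encode_protein(toupper(b)),
                    blosum62(), GAP_OPEN, GAP_EXT)
  pid <- if (r$align_length > 0) 100 * r$matches / r$align_length else 0
  list(raw_score = r$score, alignment_length = r$align_length,
       percent_identity = pid)
}

#' Seeded pair alignment
#'
#' The seeded backend used by [best_hit_search()]: a pair is aligned
#' only when it passes a two-hit exact 4-mer filter (two non-overlapping
#' word matches on one diagonal); pairs failing the filter score 0.
#' Seeding can only miss alignments, never inflate a score.
#'
#' @inheritParams align_pair
#' @return As [align_pair()]; all-zero when the seed filter rejects.
#' @export
seeded_pair_score <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  res <- cpp_seeded_search(list(encode_protein(toupper(a))),
                           list(encode_protein(toupper(b))),
                           blosum62(), GAP_OPEN, GAP_EXT, SEED_K,
                           nrow(blosum62()))
  if (nrow(res) == 0)
    return(list(raw_score = 0, alignment_length = 0, percent_identity = 0))
  list(raw_score = res$score[1], alignment_length = res$align_length[1],
       percent_identity = 100 * res$matches[1] / res$align_length[1])
}

#' E-value from a raw alignment score
#'
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * S)` with the
#' standard gapped BLOSUM62/11/1 constants `lambda = 0.267`,
#' `K = 0.041`. E is strictly decreasing in S and linear in the search
#' space `m * n`.
#'
#' @param raw_score non-negative alignment score.
#' @param query_length,db_residue_count search-space dimensions (> 0).
#' @param lambda,k Karlin-Altschul constants.
#' @return The E-value (positive numeric).
#' @export
evalue_from_score <- function(raw_score, query_length, db_residue_count,
                              lambda = KA_LAMBDA, k = KA_K) {
  if (any(query_length <= 0) || any(db_residue_count <= 0))
    stop("search-space lengths must be positive")
  if (any(raw_score < 0)) stop("raw_score must be non-negative")
  k * query_length * db_residue_count * exp(-lambda * raw_score)
}

#' Bit score from a raw alignment score
#'
#' `B = (lambda * S - ln K) / ln 2` under the same constants as
#' [evalue_from_score()].
#'
#' @inheritParams evalue_from_score
#' @return The normalized bit score.
#' @export
bit_score_from_raw <- function(raw_score, lambda = KA_LAMBDA, k = KA_K) {
  (lambda * raw_score - log(k)) / log(2)
}

#' Longest open reading frame over six frames
#'
#' Translates a nucleotide sequence in all six frames and returns the
#' longest stop-free stretch of at least `min_aa` residues, or `NA`
#' when none exists. Used to turn transcript queries into protein
#' queries before template search.
#'
#' @param x a nucleotide sequence (character scalar).
#' @param min_aa minimum ORF length in residues.
#' @return A protein string or `NA_character_`.
#' @export
translate_longest_orf <- function(x, min_aa = 30L) {
  x <- chartr("U", "T", toupper(x))
  dna <- Biostrings::DNAString(x)
  frames <- list(dna, Biostrings::subseq(dna, 2), Biostrings::subseq(dna, 3))
  rc <- Biostrings::reverseComplement(dna)
  frames <- c(frames, list(rc, Biostrings::subseq(rc, 2),
                           Biostrings::subseq(rc, 3)))
  best <- NA_character_
  for (f in frames) {
    n <- length(f) - length(f) %% 3L
    if (n < 3L) next
    aa <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::subseq(f, 1, n),
                            if.fuzzy.codon = "solve")))
    for (orf in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(orf) >= min_aa &&
          (is.na(best) || nchar(orf) > nchar(best)))
        best <- orf
    }
  }
  best
}

#' Best homology hit per query against one template
#'
#' Runs the seeded Smith-Waterman backend (or selects from precomputed
#' BLAST tabular hits) and keeps, per query, the single subject with the
#' highest bit score. Ties go to the lower E-value, then to the
#' lexicographically smaller subject id. The E-value filter is applied
#' after best-hit selection: a query whose best hit exceeds the
#' threshold yields no row.
#'
#' @param queries a [seq_set()] (protein, or nucleotide: each transcript
#'   is reduced to its longest six-frame ORF of >= 30 residues first).
#' @param template a [template_db()].
#' @param threshold inclusive E-value ceiling (default `1e-5`).
#' @param hits optional data.frame from [read_blast_tabular()] holding
#'   precomputed hits of these queries against this template; when
#'   given, no internal search is run.
#' @return A `best_hit_table` data.frame with columns `query_id`,
#'   `subject_id`, `template_species`, `raw_score`, `bit_score`,
#'   `e_value`, `percent_identity`, `alignment_length`.
#' @export
best_hit_search <- function(queries, template, threshold = 1e-5,
                            hits = NULL) {
  stopifnot(inherits(template, "template_db"))
  if (nrow(template$records) == 0) stop("empty template database")
  if (is.null(hits)) {
    hits <- internal_search(queries, template)
  } else {
    hits$template_species <- template$species_code
  }
  best_of_hits(hits, threshold)
}

internal_search <- function(queries, template) {
  stopifnot(inherits(queries, "seq_set"))
  qseq <- queries$residues
  qid <- queries$id
  if (moltype(queries) == "nucleotide") {
    prot <- vapply(qseq, translate_longest_orf, character(1),
                   USE.NAMES = FALSE)
    drop <- is.na(prot)
    if (any(drop))
      warning(sum(drop), " transcript(s) with no ORF >= 30 aa dropped ",
              "from the search")
    qseq <- prot[!drop]
    qid <- qid[!drop]
  }
  if (length(qseq) == 0)
    return(empty_hit_table())
  sub <- blosum62()
  qenc <- lapply(qseq, encode_protein)
  senc <- lapply(template$records$residues, encode_protein)
  res <- cpp_seeded_search(qenc, senc, sub, GAP_OPEN, GAP_EXT, SEED_K,
                           nrow(sub))
  if (nrow(res) == 0) return(empty_hit_table())
  n_db <- sum(template$records$length)
  m <- nchar(qseq)[res$query]
  data.frame(
    query_id = qid[res$query],
    subject_id = template$records$id[res$subject],
    template_species = template$species_code,
    raw_score = res$score,
    bit_score = bit_score_from_raw(res$score),
    e_value = evalue_from_score(res$score, m, n_db),
    percent_identity = 100 * res$matches / res$align_length,
    alignment_length = res$align_length,
    stringsAsFactors = FALSE
  )
}

empty_hit_table <- function() {
  structure(data.frame(query_id = character(), subject_id = character(),
                       template_species = character(),
                       raw_score = numeric(), bit_score = numeric(),
                       e_value = numeric(), percent_identity = numeric(),
                       alignment_length = integer(),
                       stringsAsFactors = FALSE),
            class = c("best_hit_table", "data.frame"))
}

# Per-query best hit: highest bit score, then lowest e-value, then
# lexicographically smallest subject id; threshold applied last.
best_of_hits <- function(hits, threshold) {
  if (nrow(hits) == 0) return(empty_hit_table())
  ord <- order(hits$query_id, -hits$bit_score, hits$e_value,
               hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$query_id), , drop = FALSE]
  best <- best[best$e_value <= threshold, , drop = FALSE]
  rownames(best) <- NULL
  class(best) <- c("best_hit_table", "data.frame")
  best
}

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular (outfmt 6) search results
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore). Scientific-notation E-values are handled.
#'
#' @param path path to the tabular file.
#' @return A data.frame of hits with the columns used by
#'   [best_hit_search()] (`raw_score` is `NA`: BLAST tabular output
#'   carries only the bit score).
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != 12))
    stop("line ", which(nc != 12)[1], " has ", nc[nc != 12][1],
         " columns; expected 12 (BLAST outfmt 6)")
  m <- do.call(rbind, fields)
  colnames(m) <- BLAST6_COLS
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("unparseable number in column '", col, "', line ",
           which(is.na(v))[1])
    v
  }
  data.frame(
    query_id = m[, "qseqid"],
    subject_id = m[, "sseqid"],
    template_species = NA_character_,
    raw_score = NA_real_,
    bit_score = num("bitscore"),
    e_value = num("evalue"),
    percent_identity = num("pident"),
    alignment_length = as.integer(num("length")),
    stringsAsFactors = FALSE
  )
}

#' Write hits in BLAST tabular (outfmt 6) layout
#'
#' @param hits a hit table as returned by [best_hit_search()] or
#'   [internal search]; query/subject coordinates are not tracked by the
#'   internal backend and are written as 0.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  mism <- round(hits$alignment_length *
                  (1 - hits$percent_identity / 100))
  lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$subject_id, hits$percent_identity,
                   hits$alignment_length, mism, 0L, 0L, 0L, 0L, 0L,
                   format(hits$e_value, scientific = TRUE, digits = 3),
                   hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}
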