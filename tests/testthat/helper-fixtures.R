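# Shared fixture builders and independent oracles.

# Biostrings BLOSUM62, loaded once for the alignment oracle.
b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
AA <- rownames(b62)[1:20]

rand_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                  collapse = "")

mutate_protein <- function(x, rate) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(AA, a), 1),
                      character(1))
  paste(ch, collapse = "")
}

# Independent full-DP local alignment score (floor 0), no seeding.
sw_oracle <- function(a, b) {
  max(0, Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = b62, type = "local",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

# Naive majority-vote oracle: frequency = distinct species per KO,
# winner needs >= min_votes, ties by smaller e-value sum then smaller
# K number. Written as plain loops, independently of assign_ko().
naive_assign <- function(votes, min_votes = 2) {
  if (is.null(votes) || nrow(votes) == 0)
    return(list(status = "unassigned", ko = NA_character_, count = 0))
  kos <- unique(votes$ko)
  freq <- esum <- numeric(length(kos))
  for (i in seq_along(kos)) {
    sel <- votes[votes$ko == kos[i], ]
    sel <- sel[!duplicated(sel$template_species), ]
    freq[i] <- length(unique(sel$template_species))
    esum[i] <- sum(sel$e_value)
  }
  top <- max(freq)
  if (top < min_votes)
    return(list(status = "unassigned", ko = NA_character_, count = 0))
  cand <- kos[freq == top]
  if (length(cand) > 1) {
    es <- esum[freq == top]
    cand <- cand[es == min(es)]
    cand <- sort(cand)
  }
  list(status = "assigned", ko = cand[1], count = top)
}

# A template whose records and labels are given directly.
quick_template <- function(code, ids, seqs, labels = list()) {
  template_db(code, seq_set(ids, seqs, moltype = "protein"), labels)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".faa")
  writeLines(lines, f)
  f
}

wing_kgml_path <- function() {
  system.file("extdata", "wing_development_synthetic.kgml",
              package = "pathvote")
}
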