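# The voting system: per-template best hits cast KO votes; the
# highest-frequency KO with at least min_votes supporting species wins.

#' Collect KO votes from best hits
#'
#' Each best hit contributes one vote per K number labeling its subject
#' in that subject's template; a best hit on an unlabeled subject
#' contributes nothing. Votes are unique per (query, species, KO): a
#' species casts at most one vote for a given KO through its single
#' best hit.
#'
#' @param best_hits a `best_hit_table` (rows from one or more templates,
#'   e.g. `rbind` of [best_hit_search()] results).
#' @param templates a list of [template_db()] objects covering every
#'   species present in `best_hits`.
#' @return A `vote_set` data.frame with columns `query_id`,
#'   `template_species`, `ko`, `e_value`.
#' @export
collect_votes <- function(best_hits, templates) {
  templates <- as_template_list(templates)
  votes <- vector("list", nrow(best_hits))
  for (i in seq_len(nrow(best_hits))) {
    sp <- best_hits$template_species[i]
    tdb <- templates[[sp]]
    if (is.null(tdb))
      stop("no template database for species '", sp, "'")
    sid <- best_hits$subject_id[i]
    if (!sid %in% tdb$records$id)
      stop("best hit references unknown subject '", sid,
           "' in template '", sp, "'")
    kos <- tdb$ko_labels[[sid]]
    if (length(kos) == 0) next
    votes[[i]] <- data.frame(query_id = best_hits$query_id[i],
                             template_species = sp, ko = kos,
                             e_value = best_hits$e_value[i],
                             stringsAsFactors = FALSE)
  }
  votes <- do.call(rbind, votes)
  if (is.null(votes))
    votes <- data.frame(query_id = character(),
                        template_species = character(),
                        ko = character(), e_value = numeric(),
                        stringsAsFactors = FALSE)
  votes <- votes[!duplicated(votes[c("query_id", "template_species", "ko")]),
                 , drop = FALSE]
  rownames(votes) <- NULL
  class(votes) <- c("vote_set", "data.frame")
  votes
}

as_template_list <- function(templates) {
  if (inherits(templates, "template_db")) templates <- list(templates)
  codes <- vapply(templates, function(t) t$species_code, character(1))
  if (anyDuplicated(codes))
    stop("duplicate template species codes: ",
         paste(codes[duplicated(codes)], collapse = ", "))
  names(templates) <- codes
  templates
}

#' Assign the final KO to one query's ballot
#'
#' The frequency of a KO is the number of distinct template species
#' voting for it. The KO with the highest frequency wins when that
#' frequency reaches `min_votes`; otherwise the query is unassigned.
#' Frequency ties are broken by the smaller sum of supporting E-values
#' (stronger homology evidence), then by the lexicographically smaller
#' K number; `tie_broken` records that a tie was resolved.
#'
#' @param votes a `vote_set` (or plain data.frame with columns
#'   `template_species`, `ko`, `e_value`) for a single query; may have
#'   zero rows.
#' @param min_votes minimum winning frequency (default 2).
#' @return A one-row data.frame with `status` (`assigned`/`unassigned`),
#'   `ko`, `vote_count`, `supporting_species` (comma-joined) and
#'   `tie_broken`.
#' @export
assign_ko <- function(votes, min_votes = 2L) {
  if (min_votes < 1) stop("min_votes must be >= 1")
  unassigned <- data.frame(status = "unassigned", ko = NA_character_,
                           vote_count = 0L, supporting_species = "",
                           tie_broken = FALSE, stringsAsFactors = FALSE)
  if (is.null(votes) || nrow(votes) == 0) return(unassigned)
  votes <- votes[!duplicated(votes[c("template_species", "ko")]), ,
                 drop = FALSE]
  freq <- tapply(votes$template_species, votes$ko,
                 function(s) length(unique(s)))
  top <- max(freq)
  if (top < min_votes) {
    unassigned$vote_count <- 0L
    return(unassigned)
  }
  cand <- names(freq)[freq == top]
  tie <- length(cand) > 1
  if (tie) {
    esum <- vapply(cand, function(k) sum(votes$e_value[votes$ko == k]),
                   numeric(1))
    cand <- cand[esum == min(esum)]
    cand <- sort(cand)[1]
  }
  winner <- cand[1]
  sup <- sort(unique(votes$template_species[votes$ko == winner]))
  data.frame(status = "assigned", ko = winner,
             vote_count = as.integer(top),
             supporting_species = paste(sup, collapse = ","),
             tie_broken = tie, stringsAsFactors = FALSE)
}

#' Annotate a query set against all templates
#'
#' The full voting pipeline: run [best_hit_search()] against every
#' template, collect the votes, and call [assign_ko()] per query. Every
#' query receives one row, assigned or not.
#'
#' @inheritParams best_hit_search
#' @param templates list of [template_db()] objects (>= 2; with fewer
#'   than `min_votes` templates no KO can reach the cutoff).
#' @param min_votes minimum winning frequency (default 2).
#' @param hits optional named list (by species code) of precomputed hit
#'   tables from [read_blast_tabular()]; species without an entry are
#'   searched internally.
#' @param verbose log per-template hit counts via [message()].
#' @return A `ko_assignments` data.frame with one row per query:
#'   `query_id`, `status`, `ko`, `vote_count`, `supporting_species`,
#'   `tie_broken`.
#' @export
annotate_all <- function(queries, templates, threshold = 1e-5,
                         min_votes = 2L, hits = NULL, verbose = FALSE) {
  templates <- as_template_list(templates)
  if (nrow(queries) == 0) return(empty_assignments())
  if (length(templates) < min_votes)
    warning("fewer than min_votes (", min_votes, ") templates: ",
            "all queries will be unassigned")
  best <- lapply(templates, function(tdb) {
    h <- best_hit_search(queries, tdb, threshold,
                         hits = hits[[tdb$species_code]])
    if (verbose)
      message("template ", tdb$species_code, ": ", nrow(h),
              " best hits <= ", format(threshold))
    h
  })
  best <- do.call(rbind, c(best, list(make.row.names = FALSE)))
  votes <- collect_votes(best, templates)
  per_query <- split(votes, factor(votes$query_id, levels = queries$id))
  rows <- lapply(queries$id, function(q) {
    cbind(query_id = q, assign_ko(per_query[[q]], min_votes),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ko_assignments", "data.frame")
  out
}

empty_assignments <- function() {
  structure(data.frame(query_id = character(), status = character(),
                       ko = character(), vote_count = integer(),
                       supporting_species = character(),
                       tie_broken = logical(),
                       stringsAsFactors = FALSE),
            class = c("ko_assignments", "data.frame"))
}

#' Write a KO assignment table as TSV
#'
#' Columns: `query_id`, `ko` (empty when unassigned), `vote_count`,
#' `supporting_species` (comma-joined), `status`.
#'
#' @param assignments a `ko_assignments` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(query_id = assignments$query_id,
                    ko = ifelse(is.na(assignments$ko), "",
                                assignments$ko),
                    vote_count = assignments$vote_count,
                    supporting_species = assignments$supporting_species,
                    status = assignments$status,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a KO assignment table written by [write_assignments()]
#' @param path path to the TSV.
#' @return A `ko_assignments` data.frame.
#' @export
read_assignments <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = c("character", "character",
                                          "integer", "character",
                                          "character"),
                           na.strings = NULL)
  tab$ko[tab$ko == ""] <- NA_character_
  class(tab) <- c("ko_assignments", "data.frame")
  tab
}
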