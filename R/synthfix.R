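# Deterministic synthetic fixtures: a KO universe, template species and
# query sets with known truth labels, emulating the homology structure
# the voting method assumes (one diverged copy of each ancestral
# protein per species).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic fixture generator
#'
#' Defaults model a desk-scale analogue of a multi-species annotation
#' study: 100 KO families in 10 pathways, 10 annotated template
#' species, 200-residue proteins diverged from a common root by
#' independent per-site substitution at rate 0.05. Generation is a pure
#' function of the configuration: the same config yields byte-identical
#' fixtures.
#'
#' @param n_kos number of KO families.
#' @param n_pathways number of synthetic pathways (KOs are dealt to
#'   pathways round-robin).
#' @param kos_per_pathway expected KOs per pathway; defaults to
#'   `ceiling(n_kos / n_pathways)` and must be consistent with it.
#' @param n_species number of template species.
#' @param root_length root protein length in residues.
#' @param substitution_rate per-residue substitution probability in
#'   `[0, 1)` applied independently to every species/query copy.
#' @param unlabeled_fraction fraction of each template's records whose
#'   KO labels are stripped.
#' @param mislabeled_species number of templates whose labels are
#'   permuted among KOs (annotation-noise model).
#' @param seed RNG seed (integer, < 2^31 - 1).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_kos = 100L, n_pathways = 10L,
                         kos_per_pathway = NULL, n_species = 10L,
                         root_length = 200L, substitution_rate = 0.05,
                         unlabeled_fraction = 0, mislabeled_species = 0L,
                         seed = 42L) {
  if (is.null(kos_per_pathway))
    kos_per_pathway <- ceiling(n_kos / n_pathways)
  cfg <- list(n_kos = as.integer(n_kos),
              n_pathways = as.integer(n_pathways),
              kos_per_pathway = as.integer(kos_per_pathway),
              n_species = as.integer(n_species),
              root_length = as.integer(root_length),
              substitution_rate = substitution_rate,
              unlabeled_fraction = unlabeled_fraction,
              mislabeled_species = as.integer(mislabeled_species),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_kos >= 1, n_pathways >= 1, n_species >= 1,
              root_length >= 1,
              substitution_rate >= 0, substitution_rate < 1,
              unlabeled_fraction >= 0, unlabeled_fraction <= 1,
              mislabeled_species >= 0, mislabeled_species <= n_species,
              seed >= 0, seed < 2^31 - 2)
    if (n_pathways * kos_per_pathway < n_kos)
      stop("n_pathways * kos_per_pathway must cover n_kos")
    if (n_kos > 99999 - 90000)
      stop("at most 9999 synthetic KOs are supported")
  })
  structure(cfg, class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the synthetic KO universe
#'
#' Creates K numbers `K90001 ...`, deals them round-robin onto
#' `n_pathways` synthetic pathways (`ko90001 ...`), and draws one
#' random root protein per KO uniformly over the 20 standard residues.
#'
#' @param config a [synth_config()].
#' @return A list with `index` (a `ko_index`) and `roots` (named
#'   character, KO -> root protein).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    kos <- sprintf("K9%04d", seq_len(config$n_kos))
    pids <- sprintf("ko9%04d", seq_len(config$n_pathways))
    assignment <- pids[((seq_len(config$n_kos) - 1L) %%
                          config$n_pathways) + 1L]
    roots <- vapply(kos, function(k)
      paste(sample(AA20, config$root_length, replace = TRUE),
            collapse = ""), character(1))
    ko2pw <- as.list(assignment)
    names(ko2pw) <- kos
    defn <- stats::setNames(paste("synthetic KO family", seq_along(kos)),
                            kos)
    title <- stats::setNames(paste("Synthetic pathway",
                                   seq_along(pids)), pids)
    index <- structure(list(definition = defn, pathways = ko2pw,
                            title = title, class = character()),
                       class = "ko_index")
    list(index = index, roots = roots)
  })
}

mutate_seq <- function(x, rate) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(chars, collapse = "")
}

#' Generate template species and query sets from a universe
#'
#' Every species receives one independently mutated copy of each root
#' protein, labeled with its source KO, except that
#' `unlabeled_fraction` of each template's records lose their labels
#' and `mislabeled_species` randomly chosen templates have their labels
#' permuted among KOs (a derangement). Queries are fresh mutated copies
#' of every root with truth = source KO.
#'
#' @param universe a [generate_universe()] result.
#' @param config the same [synth_config()].
#' @return A list with `templates` (list of [template_db()]),
#'   `queries` (a `seq_set`), `truth` (data.frame `query_id`, `ko`)
#'   and `mislabeled` (character vector of affected species codes).
#' @export
generate_templates_and_queries <- function(universe, config) {
  stopifnot(inherits(config, "synth_config"))
  kos <- names(universe$roots)
  with_seed(config$seed + 1L, {
    species <- sprintf("sp%02d", seq_len(config$n_species))
    mislabeled <- if (config$mislabeled_species > 0)
      sort(sample(species, config$mislabeled_species)) else character()
    templates <- lapply(species, function(sp) {
      ids <- paste0(sp, "_", tolower(kos))
      seqs <- vapply(universe$roots, mutate_seq, character(1),
                     rate = config$substitution_rate)
      labels <- as.list(kos)
      names(labels) <- ids
      if (sp %in% mislabeled) {
        perm <- sample(length(kos))
        while (length(kos) > 1 && all(perm == seq_along(kos)))
          perm <- sample(length(kos))
        labels <- as.list(kos[perm])
        names(labels) <- ids
      }
      if (config$unlabeled_fraction > 0) {
        n_strip <- round(config$unlabeled_fraction * length(ids))
        if (n_strip > 0)
          labels[sample(length(ids), n_strip)] <- list(character())
      }
      labels <- labels[lengths(labels) > 0]
      template_db(sp, seq_set(ids, seqs, moltype = "protein"), labels)
    })
    qids <- sprintf("q%04d", seq_along(kos))
    qseqs <- vapply(universe$roots, mutate_seq, character(1),
                    rate = config$substitution_rate)
    queries <- seq_set(qids, qseqs, moltype = "protein")
    truth <- data.frame(query_id = qids, ko = kos,
                        stringsAsFactors = FALSE)
    list(templates = templates, queries = queries, truth = truth,
         mislabeled = mislabeled)
  })
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper: [generate_universe()] followed by
#' [generate_templates_and_queries()].
#'
#' @param config a [synth_config()].
#' @return The combined list: `index`, `roots`, `templates`, `queries`,
#'   `truth`, `mislabeled`, `config`.
#' @export
generate_fixture <- function(config = synth_config()) {
  uni <- generate_universe(config)
  tq <- generate_templates_and_queries(uni, config)
  c(uni, tq, list(config = config))
}

#' Write a fixture to disk in the production input formats
#'
#' Emits, under `dir`: one FASTA plus KO sidecar TSV per species
#' (`<sp>.faa`, `<sp>.ko.tsv`), the query FASTA (`queries.faa`), the
#' truth table (`truth.tsv`) and the KO index (`ko_index.tsv`). The
#' tree is byte-identical across runs with the same configuration.
#'
#' @param fixture a [generate_fixture()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tdb in fixture$templates) {
    write_fasta(tdb$records, file.path(dir, paste0(tdb$species_code,
                                                   ".faa")))
    lab <- data.frame(
      id = rep(names(tdb$ko_labels), lengths(tdb$ko_labels)),
      ko = unlist(tdb$ko_labels, use.names = FALSE))
    utils::write.table(lab, file.path(dir, paste0(tdb$species_code,
                                                  ".ko.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, eol = "\n")
  }
  write_fasta(fixture$queries, file.path(dir, "queries.faa"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  write_ko_index_tsv(fixture$index, file.path(dir, "ko_index.tsv"))
  invisible(dir)
}

#' Write a KO index as the four-column TSV
#' @param index a `ko_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ko_index_tsv <- function(index, path) {
  kos <- names(index$pathways)
  lines <- vapply(kos, function(k) {
    pids <- index$pathways[[k]]
    paste(k, if (k %in% names(index$definition))
               index$definition[[k]] else "",
          paste(pids, collapse = ";"),
          paste(index$title[pids], collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
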