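mkindex <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "K00001\talcohol dehydrogenase\tko00010;ko00071\tGlycolysis;Fatty acid degradation",
    "K00002\treductase\tko00010\tGlycolysis",
    "K00003\tkinase\tko00010\tGlycolysis",
    "K00010\torphan enzyme\tko00099\tOrphan pathway"), f)
  build_ko_index(tsv = f)
}

mkasg <- function(ids, kos) {
  data.frame(query_id = ids, status = ifelse(is.na(kos), "unassigned",
                                             "assigned"),
             ko = kos, vote_count = ifelse(is.na(kos), 0L, 2L),
             supporting_species = "", tie_broken = FALSE,
             stringsAsFactors = FALSE)
}

test_that("the KO index parses TSV rows and unions KGML sources", {
  idx <- mkindex()
  expect_equal(idx$pathways[["K00001"]], c("ko00010", "ko00071"))
  expect_equal(unname(idx$title["ko00071"]), "Fatty acid degradation")

  # KGML source adds its ortholog entries; overlaps deduplicate
  idx2 <- build_ko_index(kgml_files = wing_kgml_path())
  expect_true(all(sprintf("K950%02d", 1:12) %in% names(idx2$pathways)))
  expect_equal(idx2$pathways[["K95001"]], "ko99001")

  expect_error(build_ko_index(), "empty")

  conflict <- tempfile()
  writeLines(c("K00001\tx\tko00010\tGlycolysis",
               "K00002\ty\tko00010\tNot glycolysis"), conflict)
  expect_error(build_ko_index(tsv = conflict), "conflicting")
})

test_that("assigned KOs fan out to every pathway they map to", {
  idx <- mkindex()
  rec <- reconstruct_pathways(mkasg("q1", "K00001"), idx)
  expect_setequal(rec$pathway_id, c("ko00010", "ko00071"))
  expect_true(all(vapply(rec$members, identical, logical(1), "q1")))
})

test_that("completeness is the fraction of reference KOs present", {
  expect_equal(pathway_completeness(paste0("K", 1:7), paste0("K", 1:10)),
               0.7)
  expect_equal(pathway_completeness(paste0("K", 1:10), paste0("K", 1:10)),
               1.0)
  expect_lt(pathway_completeness(paste0("K", 1:9), paste0("K", 1:10)), 1)
  idx <- mkindex()
  rec <- reconstruct_pathways(mkasg(c("q1", "q2"), c("K00001", "K00002")),
                              idx)
  glyco <- rec[rec$pathway_id == "ko00010", ]
  expect_equal(glyco$completeness, 2 / 3)
  full <- reconstruct_pathways(
    mkasg(c("q1", "q2", "q3"), c("K00001", "K00002", "K00003")), idx)
  expect_equal(full$completeness[full$pathway_id == "ko00010"], 1.0)
})

test_that("unknown assigned KOs are skipped with a warning", {
  idx <- mkindex()
  expect_warning(rec <- reconstruct_pathways(mkasg("q1", "K99999"), idx),
                 "K99999")
  expect_equal(nrow(rec), 0L)
})

test_that("summaries count annotated sequences, KO terms, pathways", {
  idx <- mkindex()
  asg <- mkasg(paste0("q", 1:10),
               c("K00001", "K00001", "K00002", "K00010", rep(NA, 6)))
  rec <- reconstruct_pathways(asg, idx)
  s <- summarize_annotation(asg, rec, 10)
  expect_equal(s$total_sequences, 10L)
  expect_equal(s$annotated_sequences, 4L)
  expect_equal(s$distinct_ko_terms, 3L)
  expect_equal(s$pathway_count, 3L) # ko00010, ko00071, ko00099

  empty <- reconstruct_pathways(mkasg("q1", NA), idx)
  s0 <- summarize_annotation(mkasg("q1", NA), empty, 5)
  expect_equal(unlist(s0[2:4], use.names = FALSE), c(0L, 0L, 0L))

  # invariance to query order
  perm <- asg[sample(nrow(asg)), ]
  s2 <- summarize_annotation(perm, reconstruct_pathways(perm, idx), 10)
  expect_equal(unclass(s2), unclass(s))
})

test_that("summary and member counts agree with a raw TSV recount", {
  cfg <- synth_config(n_kos = 20, n_species = 3, root_length = 60,
                      seed = 42)
  fix <- generate_fixture(cfg)
  asg <- annotate_all(fix$queries, fix$templates)
  f <- tempfile(fileext = ".tsv")
  write_assignments(asg, f)
  rec <- reconstruct_pathways(asg, fix$index)
  s <- summarize_annotation(asg, rec, nrow(fix$queries))
  # independent recount from the written TSV
  raw <- utils::read.table(f, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  ann <- raw[raw$status == "assigned", ]
  expect_equal(s$annotated_sequences, nrow(ann))
  expect_equal(s$distinct_ko_terms, length(unique(ann$ko)))
  pw <- unique(unlist(fix$index$pathways[unique(ann$ko)]))
  expect_equal(s$pathway_count, length(pw))
  # fan-out only inflates membership
  expect_gte(sum(rec$n_members), nrow(ann))
})

test_that("map links normalize the prefix and sort the K numbers", {
  expect_equal(map_link("ko00903", c("K10717", "K00001")),
               "https://www.kegg.jp/kegg-bin/show_pathway?map00903+K00001+K10717")
  expect_equal(map_link("map00903", character()),
               "https://www.kegg.jp/kegg-bin/show_pathway?map00903")
  expect_equal(map_link("ko00903", c("K10717", "K00001")),
               map_link("ko00903", c("K00001", "K10717")))
  expect_error(map_link("pathway1"), "invalid")
  expect_error(map_link("ko00903", "K1"), "invalid")
})

test_that("pathway outputs are written as TSV, summary, list and links", {
  idx <- mkindex()
  asg <- mkasg(c("q1", "q2"), c("K00001", "K00002"))
  rec <- reconstruct_pathways(asg, idx)
  s <- summarize_annotation(asg, rec, 2)
  prefix <- file.path(tempdir(), "pwtest")
  write_pathway_outputs(rec, s, prefix)
  expect_true(all(file.exists(paste0(prefix, c(".pathways.tsv",
                                               ".summary.txt",
                                               ".pathway_list.txt",
                                               ".links.txt")))))
  tab <- utils::read.table(paste0(prefix, ".pathways.tsv"), sep = "\t",
                           header = TRUE)
  expect_equal(nrow(tab), nrow(rec))
})
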