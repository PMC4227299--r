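mkvotes <- function(...) {
  rows <- list(...)
  data.frame(template_species = vapply(rows, `[[`, character(1), 1),
             ko = vapply(rows, `[[`, character(1), 2),
             e_value = vapply(rows, function(r)
               if (length(r) > 2) as.numeric(r[[3]]) else 1e-30,
               numeric(1)),
             stringsAsFactors = FALSE)
}

test_that("votes derive from subject labels, one per K number", {
  tdb_a <- quick_template("A", "a1", strrep("MK", 20),
                          list(a1 = "K00001"))
  tdb_b <- quick_template("B", "b1", strrep("MK", 20),
                          list(b1 = c("K00001", "K00002")))
  tdb_c <- quick_template("C", "c1", strrep("MK", 20)) # unlabeled
  hits <- data.frame(query_id = "q1", subject_id = c("a1", "b1", "c1"),
                     template_species = c("A", "B", "C"),
                     e_value = 1e-30, stringsAsFactors = FALSE)
  v <- collect_votes(hits, list(tdb_a, tdb_b, tdb_c))
  expect_equal(nrow(v), 3L)
  expect_equal(sort(v$ko[v$template_species == "B"]),
               c("K00001", "K00002"))
  expect_false("C" %in% v$template_species)

  bad <- hits; bad$subject_id[1] <- "zz"
  expect_error(collect_votes(bad, list(tdb_a, tdb_b, tdb_c)), "zz")
})

test_that("the highest-frequency KO wins subject to the vote cutoff", {
  a <- assign_ko(mkvotes(list("A", "K00001"), list("B", "K00001"),
                         list("C", "K00002")))
  expect_equal(a$status, "assigned")
  expect_equal(a$ko, "K00001")
  expect_equal(a$vote_count, 2L)
  expect_equal(a$supporting_species, "A,B")
  expect_false(a$tie_broken)

  # a single vote never reaches the minimum cutoff of 2
  s <- assign_ko(mkvotes(list("A", "K00500")))
  expect_equal(s$status, "unassigned")

  e <- assign_ko(mkvotes()[0, ])
  expect_equal(e$status, "unassigned")
  expect_equal(e$vote_count, 0L)

  one <- assign_ko(mkvotes(list("A", "K00500")), min_votes = 1)
  expect_equal(one$status, "assigned")
})

test_that("frequency ties break by summed E-value, then K number", {
  t1 <- assign_ko(mkvotes(list("A", "K00001", 1e-80),
                          list("B", "K00001", 1e-80),
                          list("C", "K00002", 1e-20),
                          list("D", "K00002", 1e-20)))
  expect_equal(t1$ko, "K00001")
  expect_true(t1$tie_broken)

  # stronger evidence wins even for the larger K number
  t2 <- assign_ko(mkvotes(list("A", "K00009", 1e-80),
                          list("B", "K00009", 1e-80),
                          list("C", "K00002", 1e-20),
                          list("D", "K00002", 1e-20)))
  expect_equal(t2$ko, "K00009")

  # equal evidence: lexicographically smaller K number
  t3 <- assign_ko(mkvotes(list("A", "K00005", 1e-30),
                          list("B", "K00005", 1e-30),
                          list("C", "K00002", 1e-30),
                          list("D", "K00002", 1e-30)))
  expect_equal(t3$ko, "K00002")
})

test_that("vote counts are per distinct species, and the winner is in the ballot", {
  dup <- assign_ko(mkvotes(list("A", "K00001"), list("A", "K00001"),
                           list("B", "K00002"), list("C", "K00002")))
  expect_equal(dup$ko, "K00002") # A's duplicate rows count once
  set.seed(41)
  for (i in 1:30) {
    v <- mkvotes()
    n <- sample(1:12, 1)
    v <- data.frame(
      template_species = sample(LETTERS[1:6], n, TRUE),
      ko = sample(sprintf("K%05d", 1:4), n, TRUE),
      e_value = 10^-sample(10:60, n, TRUE), stringsAsFactors = FALSE)
    a <- assign_ko(v)
    if (a$status == "assigned") {
      expect_true(a$ko %in% v$ko)
      # monotonicity: a fresh vote for the winner never dethrones it
      extra <- rbind(v, data.frame(template_species = "Z", ko = a$ko,
                                   e_value = 1e-10))
      expect_equal(assign_ko(extra)$ko, a$ko)
    }
  }
})

test_that("verbatim presence in enough templates yields that KO", {
  set.seed(42)
  probe <- rand_protein(100)
  other <- rand_protein(100)
  tpl <- lapply(1:5, function(i) {
    seqs <- c(if (i <= 3) probe else rand_protein(100), other)
    quick_template(paste0("sp", i), c("hit", "bg"), seqs,
                   list(hit = "K00042", bg = "K00099"))
  })
  q <- seq_set(c("q1", "q2"), c(probe, rand_protein(100)))
  asg <- annotate_all(q, tpl)
  expect_equal(asg$status, c("assigned", "unassigned"))
  expect_equal(asg$ko[1], "K00042")
  expect_equal(asg$vote_count[1], 3L)
})

test_that("fewer templates than the cutoff warns and leaves all unassigned", {
  tdb <- quick_template("A", "a1", strrep("MK", 20), list(a1 = "K00001"))
  q <- seq_set("q1", strrep("MK", 20))
  expect_warning(asg <- annotate_all(q, list(tdb)), "unassigned")
  expect_equal(asg$status, "unassigned")
})

test_that("the pipeline matches a naive full-DP search plus naive counting", {
  cfg <- synth_config(n_kos = 12, n_species = 4, root_length = 80,
                      substitution_rate = 0.05, seed = 42)
  fix <- generate_fixture(cfg)
  asg <- annotate_all(fix$queries, fix$templates)

  # independent reference: exhaustive alignment, naive best hit,
  # naive vote counting
  votes <- list()
  for (tdb in fix$templates) {
    n_db <- sum(tdb$records$length)
    for (qi in seq_len(nrow(fix$queries))) {
      q <- fix$queries$residues[qi]
      scores <- vapply(tdb$records$residues, function(s) sw_oracle(q, s),
                       numeric(1))
      best <- max(scores)
      cand <- sort(tdb$records$id[scores == best])[1]
      ev <- 0.041 * nchar(q) * n_db * exp(-0.267 * best)
      if (ev > 1e-5) next
      for (ko in tdb$ko_labels[[cand]])
        votes[[length(votes) + 1]] <- data.frame(
          query_id = fix$queries$id[qi],
          template_species = tdb$species_code, ko = ko, e_value = ev,
          stringsAsFactors = FALSE)
    }
  }
  votes <- do.call(rbind, votes)
  for (qi in seq_len(nrow(fix$queries))) {
    qid <- fix$queries$id[qi]
    ref <- naive_assign(votes[votes$query_id == qid, , drop = FALSE])
    row <- asg[asg$query_id == qid, ]
    expect_equal(row$status, ref$status)
    if (ref$status == "assigned") {
      expect_equal(row$ko, ref$ko)
      expect_equal(row$vote_count, as.integer(ref$count))
    }
  }
})

test_that("assignment tables round-trip through TSV", {
  asg <- data.frame(query_id = c("q1", "q2"),
                    status = c("assigned", "unassigned"),
                    ko = c("K00001", NA), vote_count = c(3L, 0L),
                    supporting_species = c("A,B,C", ""),
                    tie_broken = c(FALSE, FALSE),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_assignments(asg, f)
  r <- read_assignments(f)
  expect_equal(r$query_id, asg$query_id)
  expect_equal(r$ko, asg$ko)
  expect_equal(r$vote_count, asg$vote_count)
})
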