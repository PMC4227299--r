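test_that("self-alignment score equals the sum of diagonal BLOSUM62 entries", {
  s <- "MKVLIE"
  expected <- sum(diag(b62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]]))
  r <- align_pair(s, s)
  expect_equal(r$raw_score, expected)
  expect_equal(r$percent_identity, 100)
  expect_equal(r$alignment_length, nchar(s))
})

test_that("alignment score floors at zero and is symmetric", {
  r <- align_pair("MKVLIE", "AAAAAA")
  expect_equal(r$raw_score, 0)
  set.seed(31)
  for (i in 1:20) {
    a <- rand_protein(sample(5:60, 1))
    b <- rand_protein(sample(5:60, 1))
    expect_equal(align_pair(a, b)$raw_score, align_pair(b, a)$raw_score)
  }
  expect_error(align_pair("", "MK"), "non-empty")
})

test_that("full DP scores agree with an independent aligner on varied pairs", {
  set.seed(32)
  for (i in 1:40) {
    a <- rand_protein(sample(10:100, 1))
    b <- if (i %% 2 == 0) rand_protein(sample(10:100, 1)) else {
      x <- mutate_protein(a, runif(1, 0, 0.4))
      # occasional deletion so gaps are exercised
      if (i %% 3 == 0 && nchar(x) > 20) x <- paste0(substr(x, 1, 5),
                                                    substr(x, 11, nchar(x)))
      x
    }
    expect_equal(align_pair(a, b)$raw_score, sw_oracle(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul closed form", {
  expect_equal(evalue_from_score(0, 100, 1000), 0.041 * 100 * 1000)
  e1 <- evalue_from_score(80, 300, 5e5)
  expect_equal(evalue_from_score(80, 300, 1e6), 2 * e1)
  # closed-form inversion round trip at the threshold
  m <- 300; n <- 1e6
  s_star <- log(0.041 * m * n / 1e-5) / 0.267
  expect_equal(evalue_from_score(s_star, m, n), 1e-5)
  # strictly decreasing in S
  expect_lt(evalue_from_score(81, 300, 5e5), e1)
  expect_error(evalue_from_score(10, 0, 100), "positive")
})

test_that("best-hit search keeps the top subject under the threshold", {
  set.seed(33)
  target <- rand_protein(120)
  decoys <- vapply(rep(120, 4), rand_protein, character(1))
  tdb <- quick_template("spa", paste0("s", 1:5), c(target, decoys))
  q <- seq_set("q1", target)
  hits <- best_hit_search(q, tdb)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$subject_id, "s1")
  expect_equal(hits$percent_identity, 100)
  expect_lte(hits$e_value, 1e-5)
})

test_that("a best hit above the E-value threshold yields no row", {
  # short shared word: strong enough to seed, too weak to pass 1e-5
  core <- "MKVLIEPT"
  set.seed(34)
  q <- seq_set("q1", paste0(rand_protein(40), core, rand_protein(40)))
  tdb <- quick_template("spa", "s1",
                        paste0(rand_protein(40), core, rand_protein(40)))
  hits <- best_hit_search(q, tdb)
  expect_equal(nrow(hits), 0L)
})

test_that("equal-score ties go to the lexicographically smaller subject", {
  set.seed(35)
  target <- rand_protein(100)
  tdb <- quick_template("spa", c("s2", "s1"), c(target, target))
  hits <- best_hit_search(seq_set("q1", target), tdb)
  expect_equal(hits$subject_id, "s1")
})

test_that("seeded search equals the exact aligner on homologous pairs", {
  set.seed(36)
  for (i in 1:25) {
    a <- rand_protein(sample(60:120, 1))
    b <- mutate_protein(a, runif(1, 0, 0.2))
    expect_equal(seeded_pair_score(a, b)$raw_score,
                 align_pair(a, b)$raw_score)
  }
})

test_that("BLAST tabular files parse to hits, bad lines are fatal", {
  f <- tempfile()
  writeLines(paste("q1", "s1", "98.5", "200", "3", "0", "1", "200",
                   "1", "200", "1e-50", "180", sep = "\t"), f)
  h <- read_blast_tabular(f)
  expect_equal(h$e_value, 1e-50)
  expect_equal(h$bit_score, 180)
  expect_equal(h$percent_identity, 98.5)

  writeLines("q1\ts1\t98.5", f)
  expect_error(read_blast_tabular(f), "line 1")

  writeLines(paste("q1", "s1", "xx", "200", "3", "0", "1", "200",
                   "1", "200", "1e-50", "180", sep = "\t"), f)
  expect_error(read_blast_tabular(f), "unparseable")

  file.create(f2 <- tempfile())
  expect_equal(nrow(read_blast_tabular(f2)), 0L)
})

test_that("precomputed tabular hits drive best-hit selection", {
  tdb <- quick_template("spa", c("s1", "s2"),
                        c(strrep("MK", 30), strrep("IE", 30)),
                        list(s1 = "K00001"))
  f <- tempfile()
  writeLines(c(
    paste("q1", "s2", "90", "50", "5", "0", "1", "50", "1", "50",
          "1e-20", "95", sep = "\t"),
    paste("q1", "s1", "95", "50", "2", "0", "1", "50", "1", "50",
          "1e-30", "120", sep = "\t"),
    paste("q2", "s1", "40", "30", "18", "0", "1", "30", "1", "30",
          "0.5", "28", sep = "\t")), f)
  best <- best_hit_search(seq_set("q1", "MKV"), tdb,
                          hits = read_blast_tabular(f))
  expect_equal(best$query_id, "q1")   # q2 fails the threshold
  expect_equal(best$subject_id, "s1") # higher bit score wins
})

test_that("six-frame translation finds the longest ORF on either strand", {
  # leucine as TTA makes the reverse-complement frames hit TAA stops,
  # so the encoded peptide is the strict longest ORF over six frames
  pep <- "MKVLIEPTLMLRA"
  codons <- c(M = "ATG", K = "AAA", V = "GTT", L = "TTA", I = "ATT",
              E = "GAA", P = "CCT", T = "ACT", R = "CGT", A = "GCT")
  dna <- paste(codons[strsplit(pep, "")[[1]]], collapse = "")
  expect_equal(translate_longest_orf(dna, min_aa = 10), pep)
  # reverse complement: same ORF found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  expect_equal(translate_longest_orf(rc, min_aa = 10), pep)
  # nothing >= min_aa
  expect_true(is.na(translate_longest_orf("ATGTAA", min_aa = 5)))
})
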