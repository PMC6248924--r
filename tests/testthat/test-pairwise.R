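scheme <- scoring_scheme()

test_that("identity and no-match limit cases behave as contracted", {
  s <- "MKVLAAGF"
  al <- local_align(s, s, scheme)
  expect_equal(al$score,
               sum(diag(scheme$substitution[strsplit(s, "")[[1]],
                                            strsplit(s, "")[[1]]])))
  expect_equal(unname(al$query_interval), c(1, 8))
  expect_equal(unname(al$subject_interval), c(1, 8))

  # tryptophan vs a pool it only scores negatively against
  none <- local_align("WWWW", "PGPG", scheme)
  expect_equal(none$score, 0)
  expect_equal(unname(none$query_interval[2]), 0) # empty interval

  ga <- global_align("AC", "AC", scheme)
  expect_equal(ga$score, scheme$substitution["A", "A"] +
                 scheme$substitution["C", "C"])
  expect_true(all(!is.na(ga$columns$query)))
  expect_error(global_align("AC", ""), "empty sequence")
  expect_error(local_align("", "AC"), "empty sequence")
})

test_that("DP scores equal exhaustive enumeration on short sequences", {
  set.seed(42)
  # cheaper gaps than BLOSUM defaults so gapped optima actually occur at
  # these lengths
  sch <- scoring_scheme(gap_open = 4, gap_extend = 1)
  for (rep in 1:25) {
    a <- rand_seq(sample(2:8, 1))
    b <- rand_seq(sample(2:8, 1))
    expect_equal(local_align(a, b, sch)$score,
                 oracle_align_score(a, b, sch, local = TRUE),
                 info = paste(a, b, "local"))
    expect_equal(global_align(a, b, sch)$score,
                 oracle_align_score(a, b, sch, local = FALSE),
                 info = paste(a, b, "global"))
  }
})

test_that("alignment score is symmetric and locally monotone", {
  set.seed(7)
  alpha <- strsplit("ACDEFGHIKL", "")[[1]]
  for (rep in 1:10) {
    a <- rand_seq(20, alpha)
    b <- rand_seq(20, alpha)
    expect_equal(local_align(a, b, scheme)$score,
                 local_align(b, a, scheme)$score)
    ext <- paste0(a, rand_seq(5, alpha))
    expect_gte(local_align(ext, b, scheme)$score,
               local_align(a, b, scheme)$score)
  }
})

test_that("local alignment score equals recomputing its columns", {
  set.seed(9)
  a <- rand_seq(40, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  b <- rand_seq(40, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  al <- local_align(a, b, scheme)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  cols <- al$columns
  sc <- 0; gap_a <- 0; gap_b <- 0
  for (i in seq_len(nrow(cols))) {
    if (is.na(cols$query[i])) {
      gap_b <- gap_b + 1
    } else if (is.na(cols$subject[i])) {
      gap_a <- gap_a + 1
    } else {
      sc <- sc + scheme$substitution[av[cols$query[i]], bv[cols$subject[i]]]
    }
  }
  gaps <- rle(ifelse(is.na(cols$query), "gq",
                     ifelse(is.na(cols$subject), "gs", "m")))
  gapcost <- sum(vapply(which(gaps$values != "m"), function(i)
    scheme$gap_open + (gaps$lengths[i] - 1) * scheme$gap_extend, numeric(1)))
  expect_equal(al$score, sc - gapcost)
  expect_gte(al$score, 0)
})

test_that("dot-plots are symmetric on self, diagonal-maximal, and reveal repeats", {
  set.seed(5)
  s <- rand_seq(80, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  dp <- dotplot(s, s, window = 15, scheme = scheme)
  expect_equal(dp$matrix, t(dp$matrix))
  for (i in seq_len(nchar(s)))
    expect_gte(dp$matrix[i, i], max(dp$matrix[i, ]) - 1e-12)

  # window 1 reduces to the raw substitution lookup
  dp1 <- dotplot("ACD", "ACD", window = 1, scheme = scheme)
  expect_equal(dp1$matrix,
               unname(scheme$substitution[c("A", "C", "D"), c("A", "C", "D")]))
  expect_error(dotplot(s, s, window = 14), "odd")

  # planted repeat: off-diagonal at the repeat offset outscores background
  core <- rand_seq(60, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  rep_u <- rand_seq(50, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  s2 <- paste0(core, rep_u, rep_u)
  dp2 <- dotplot(s2, s2, window = 11, scheme = scheme)
  off <- vapply(61:110, function(i) dp2$matrix[i, i + 50], numeric(1))
  bg <- dp2$matrix[row(dp2$matrix) - col(dp2$matrix) == 37]
  expect_gt(mean(off), mean(bg))
})

test_that("off-diagonal self-alignment recovers planted duplications and respects the band", {
  set.seed(13)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pre <- rand_seq(50, alpha); post <- rand_seq(40, alpha)
  R <- rand_seq(60, alpha)
  s <- paste0(pre, R, R, post)
  al <- self_offdiagonal_align(s, scheme, exclusion_band = 20)
  # the optimum rides the duplication diagonal: it must cover both planted
  # copies (raw local optima may extend a little into chance matches; the
  # repeat caller polishes boundaries)
  expect_lte(al$query_interval[["start"]], 51)
  expect_gte(al$query_interval[["end"]], 110 - 3)
  expect_lte(abs(al$query_interval[["start"]] - 51), 20)
  expect_lte(abs(al$subject_interval[["end"]] - 170), 20)
  expect_gte(al$score, local_align(R, R, scheme)$score)

  # band = len - 1 leaves only the two extreme corner cells admissible
  short <- "MKVLA"
  al2 <- self_offdiagonal_align(short, scheme, exclusion_band = 4)
  expect_equal(nrow(al2$columns) <= 1, TRUE)
  expect_error(self_offdiagonal_align(short, scheme, exclusion_band = 5),
               "smaller than the sequence length")

  # i.i.d. sequences stay below a repeat-calling threshold
  null_scores <- vapply(1:60, function(i) {
    self_offdiagonal_align(rand_seq(100, alpha), scheme, 20)$score
  }, numeric(1))
  planted <- al$score
  expect_lt(quantile(null_scores, 0.99), planted / 2)
})
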