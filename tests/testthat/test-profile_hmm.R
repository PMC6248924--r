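test_that("built models satisfy the probability invariants", {
  set.seed(31)
  for (rep in 1:5) {
    rows <- vapply(1:5, function(i)
      paste(sample(c(strsplit("ACDEFGHIKL", "")[[1]], "-"), 30,
                   replace = TRUE, prob = c(rep(0.09, 10), 0.1)),
            collapse = ""), character(1))
    rows[1] <- gsub("-", "A", rows[1]) # keep every column buildable
    msa <- flg_msa(paste0("r", 1:5), rows)
    hmm <- build_hmm(msa)
    expect_true(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
    expect_true(all(hmm$match_emissions > 0))
    if (hmm$L > 1) {
      expect_true(all(abs(hmm$tMM + hmm$tMI + hmm$tMD - 1) < 1e-9))
      expect_true(all(abs(hmm$tIM + hmm$tII - 1) < 1e-9))
      expect_true(all(abs(hmm$tDM + hmm$tDD - 1) < 1e-9))
    }
  }

  # identical gap-free rows: L = row length, emissions concentrate on the
  # observed residue
  msa <- flg_msa(c("a", "b", "c"), rep("MKVLA", 3))
  hmm <- build_hmm(msa)
  expect_equal(hmm$L, 5L)
  cons <- strsplit("MKVLA", "")[[1]]
  for (k in 1:5)
    expect_equal(names(which.max(hmm$match_emissions[k, ])), cons[k])

  expect_error(build_hmm(flg_msa(c("a", "b"), c("A---", "-AAA")),
                         match_column_rule = 0.3),
               "no match columns")
})

test_that("the source consensus outscores shuffles of itself", {
  msa <- flagellin_training()$msa
  hmm <- build_hmm(msa, name = "flic")
  m <- as.matrix(msa)
  cons <- apply(m, 2, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0) NA_character_ else names(sort(table(res),
                                                        decreasing = TRUE))[1]
  })
  cons <- paste(cons[!is.na(cons)], collapse = "")
  sc <- forward_score(hmm, cons)
  set.seed(32)
  v <- strsplit(cons, "")[[1]]
  shuf <- vapply(1:100, function(i)
    forward_score(hmm, paste(sample(v), collapse = "")), numeric(1))
  expect_gte(sum(sc > shuf), 99)
})

test_that("forward and Viterbi match exhaustive path enumeration on toy models", {
  set.seed(33)
  for (L in 1:3) {
    hmm <- toy_hmm(L = L, seed = 100 + L)
    for (n in 1:4) {
      for (rep in 1:3) {
        s <- rand_seq(n, c("A", "C", "D", "E", "F", "G"))
        fwd <- forward_score(hmm, s)
        vit <- viterbi_decode(hmm, s)$bits
        expect_equal(fwd, oracle_phmm_bits(hmm, s, "sum"),
                     tolerance = 1e-6, info = paste("fwd L", L, s))
        expect_equal(vit, oracle_phmm_bits(hmm, s, "max"),
                     tolerance = 1e-6, info = paste("vit L", L, s))
        expect_lte(vit, fwd + 1e-9)
      }
    }
  }
})

test_that("the model conserves probability mass over short sequences", {
  hmm <- toy_hmm(L = 2, seed = 55)
  alpha <- colnames(hmm$match_emissions)
  for (n in 1:2) {
    combos <- expand.grid(rep(list(alpha), n), stringsAsFactors = FALSE)
    total <- 0
    for (i in seq_len(nrow(combos))) {
      s <- paste(unlist(combos[i, ]), collapse = "")
      bits <- forward_score(hmm, s)
      ln_odds <- bits * log(2)
      p_null_em <- prod(hmm$background[match(unlist(combos[i, ]),
                                             colnames(hmm$match_emissions))])
      p_seq <- exp(ln_odds) * p_null_em * hmm$r_loop^n * (1 - hmm$r_loop)
      total <- total + p_seq
    }
    expect_equal(total, oracle_phmm_length_mass(hmm, n), tolerance = 1e-6)
  }
})

test_that("scores ignore ids and Viterbi recovers consensus span", {
  hmm <- toy_hmm(L = 3, seed = 60)
  s <- "ACD"
  named <- Biostrings::AAStringSet(c(whatever = s))
  expect_equal(forward_score(hmm, s), forward_score(hmm, named[1]))

  # a sequence equal to the core-model consensus decodes across its span
  core <- core_hmms()$ncore
  cons <- apply(core$match_emissions, 1, function(e) names(which.max(e)))
  v <- viterbi_decode(core, paste(cons, collapse = ""))
  expect_equal(v$start, 1L)
  expect_equal(v$end, core$L)
  expect_gt(v$bits, 0)

  # unrelated random sequences score below 0 bits nearly always
  set.seed(34)
  nulls <- vapply(1:100, function(i)
    viterbi_decode(core, rand_seq(200, colnames(core$match_emissions)))$bits,
    numeric(1))
  expect_gte(mean(nulls < 0), 0.95)
})

test_that("E-value calibration is reproducible, monotone and centred", {
  gen <- flagellin_training()$gen
  core <- core_hmms()$ncore
  h1 <- calibrate_evalues(core, gen$records, n_shuffles = 100, seed = 9)
  h2 <- calibrate_evalues(core, gen$records, n_shuffles = 100, seed = 9)
  expect_identical(h1$calibration, h2$calibration)
  expect_error(calibrate_evalues(core, gen$records, n_shuffles = 50),
               ">= 100")

  # monotone decreasing in bits
  ev <- hmm_evalue(h1, c(-5, 0, 5, 50))
  expect_true(all(diff(ev) < 0))

  # the median shuffled score maps to an E-value near n_db / 2
  set.seed(9)
  seqs <- as.character(gen$records)
  idx <- rep_len(seq_along(seqs), 100)
  scores <- vapply(idx, function(i) {
    v <- sample(strsplit(seqs[i], "")[[1]])
    forward_score(core, paste(v[seq_len(min(400, length(v)))], collapse = ""))
  }, numeric(1))
  ev_med <- hmm_evalue(h1, median(scores))
  expect_gt(ev_med, length(seqs) / 2 / 1.5)
  expect_lt(ev_med, length(seqs) / 2 * 1.5)
})

test_that("scanning finds planted copies, rejects nulls, and never overlaps", {
  cfg <- oceanospirillales_preset(seed = 40, n_taxa = 6)
  gen <- generate_flagellins(cfg)
  iv <- gen$truth$intervals
  de <- iv[iv$segment %in% c("de1", "de2"), ]
  seqs <- as.character(gen$records)
  inst <- setNames(substr(seqs[de$id], de$start, de$end),
                   paste0(de$id, ".", de$segment))
  hmm <- build_hmm(progressive_msa(inst), name = "de")
  hmm <- calibrate_evalues(hmm, gen$records, 100, seed = 2)
  hits <- scan_hmm(hmm, gen$records, 0.1)

  for (id in unique(de$id)) {
    planted <- de[de$id == id, ]
    got <- hits[hits$id == id, ]
    expect_equal(nrow(got), 2, info = id)
    for (i in 1:2) {
      ov <- max(0, min(got$end[i], planted$end[i]) -
                  max(got$start[i], planted$start[i]) + 1)
      expect_gte(ov / (planted$end[i] - planted$start[i] + 1), 0.8)
    }
    # non-overlap + bounds
    expect_lt(got$end[1], got$start[2])
    expect_lte(got$end[2], nchar(seqs[id]))
  }

  # sequences with no planted copy produce no hits at E < 0.1
  set.seed(41)
  null_rec <- Biostrings::AAStringSet(setNames(
    vapply(1:20, function(i) rand_seq(600, colnames(hmm$match_emissions)),
           character(1)), paste0("n", 1:20)))
  nh <- scan_hmm(hmm, null_rec, 0.1)
  expect_lte(nrow(nh), 1)
})
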