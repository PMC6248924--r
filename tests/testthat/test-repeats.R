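scheme <- scoring_scheme()

test_that("tandem repeat calling recovers planted duplications tightly", {
  set.seed(71)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ncore <- rand_seq(100, alpha); ccore <- rand_seq(80, alpha)
  R <- rand_seq(60, alpha)
  mid <- rand_seq(30, alpha)
  s <- paste0(ncore, R, mid, R, ccore)
  insert <- c(101, 100 + 60 + 30 + 60)
  rp <- find_tandem_repeats(s, insert, scheme, min_score = 60)
  expect_equal(nrow(rp), 1)
  expect_lte(abs(rp$start1 - 101), 3)
  expect_lte(abs(rp$end1 - 160), 3)
  expect_lte(abs(rp$start2 - 191), 3)
  expect_lte(abs(rp$end2 - 250), 3)
  expect_gte(rp$identity, 0.95)
  # tandem order and containment invariants
  expect_lt(rp$end1, rp$start2)
  expect_gte(rp$start1, insert[1])
  expect_lte(rp$end2, insert[2])
})

test_that("repeat-free inserts yield empty results, short inserts too", {
  set.seed(72)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  thr <- repeat_null_threshold(rand_seq(160, alpha), scheme, 20, n = 50,
                               seed = 72)
  hits <- vapply(1:50, function(i) {
    s <- rand_seq(160, alpha)
    nrow(find_tandem_repeats(s, c(1, 160), scheme, min_score = thr))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)

  # insert shorter than twice the minimum repeat length: empty, no error
  expect_equal(nrow(find_tandem_repeats("MKVLAAGFKRMKVLAAGFKR", c(1, 20),
                                        scheme, min_score = 10,
                                        min_len = 20)), 0)
})

test_that("iterative discovery pools tandem seeds and finds single copies", {
  # 4 tandem-DE leaves and 2 single-DE leaves from the same generator:
  # the tandem pairs seed the model, the singles must be found by scanning
  cfg <- synthetic_config(seed = 73, n_taxa = 6, divergence = 0.1,
                          de_length = 180,
                          insert_model = c(rep("tandem_DE", 4),
                                           rep("single_DE", 2)))
  gen <- generate_flagellins(cfg)
  iv <- gen$truth$intervals
  seqs <- as.character(gen$records)
  tand <- iv[iv$segment == "de1" & iv$id %in% paste0("t", 1:4), ]
  tand2 <- iv[iv$segment == "de2" & iv$id %in% paste0("t", 1:4), ]
  seed_pairs <- data.frame(id = tand$id, start1 = tand$start,
                           end1 = tand$end, start2 = tand2$start,
                           end2 = tand2$end)
  res <- iterative_de_discovery(gen$records, seed_pairs, 0.1,
                                max_iter = 4, scheme, seed = 73)
  expect_true(res$converged)
  expect_lte(res$n_iterations, 3)
  expect_equal(tail(res$new_per_iteration, 1), 0L)
  # all 10 planted copies present (8 tandem + 2 singles)
  planted <- iv[iv$segment %in% c("de1", "de2"), ]
  expect_equal(nrow(res$instances), nrow(planted))
  for (i in seq_len(nrow(planted))) {
    match_i <- res$instances[res$instances$id == planted$id[i] &
                               pmin(res$instances$end, planted$end[i]) -
                                 pmax(res$instances$start,
                                      planted$start[i]) >= 0, ]
    expect_gte(nrow(match_i), 1)
  }
})

test_that("a tandem-only dataset converges with a final empty iteration", {
  cfg <- synthetic_config(seed = 74, n_taxa = 4, divergence = 0.08,
                          de_length = 160, insert_model = "tandem_DE")
  gen <- generate_flagellins(cfg)
  iv <- gen$truth$intervals
  d1 <- iv[iv$segment == "de1", ]; d2 <- iv[iv$segment == "de2", ]
  seed_pairs <- data.frame(id = d1$id, start1 = d1$start, end1 = d1$end,
                           start2 = d2$start, end2 = d2$end)
  res <- iterative_de_discovery(gen$records, seed_pairs, 0.1,
                                max_iter = 4, scheme, seed = 74)
  expect_true(res$converged)
  expect_equal(res$new_per_iteration[res$n_iterations], 0L)
  # the instance set never shrank
  expect_gte(nrow(res$instances), 2 * nrow(seed_pairs))
  expect_error(iterative_de_discovery(gen$records, seed_pairs[0, ], 0.1),
               "non-empty")
})

test_that("DX detection follows the two-copy contract", {
  copies <- data.frame(start = c(200, 400), end = c(330, 530))
  expect_equal(unname(detect_dx(copies)), c(331, 399))
  # abutting copies: no DX
  expect_null(detect_dx(data.frame(start = c(200, 331), end = c(330, 460))))
  # a single copy: absent by contract
  expect_null(detect_dx(data.frame(start = 200, end = 330)))
  # short gap below min length
  expect_null(detect_dx(data.frame(start = c(200, 340), end = c(330, 470)),
                        min_dx_length = 20))
})

test_that("planted DX and glycine regions are recovered", {
  cfg <- oceanospirillales_preset(seed = 75, n_taxa = 4, divergence = 0.08)
  gen <- generate_flagellins(cfg)
  iv <- gen$truth$intervals
  seqs <- as.character(gen$records)
  for (id in names(seqs)[1:2]) {
    tv <- iv[iv$id == id, ]
    de <- tv[tv$segment %in% c("de1", "de2"), ]
    dx_true <- tv[tv$segment == "dx", ]
    dx <- detect_dx(data.frame(start = de$start, end = de$end))
    expect_lte(abs(dx[["start"]] - dx_true$start), 3)
    expect_lte(abs(dx[["end"]] - dx_true$end), 3)
    gly_true <- tv[tv$segment == "gly", ]
    g <- glycine_rich_scan(seqs[[id]], dx, window = 11, min_fraction = 0.4)
    expect_gte(nrow(g), 1)
    best <- g[which.max(g$length), ]
    # the planted region is only 60% glycine, so window detection need
    # not blanket it; majority overlap demonstrates recovery
    ov <- min(best$end, gly_true$end) - max(best$start, gly_true$start) + 1
    expect_gte(ov / (gly_true$end - gly_true$start + 1), 0.5)
    expect_gte(best$fraction, 0.4)
    # hits stay inside DX
    expect_true(all(g$start >= dx[["start"]] & g$end <= dx[["end"]]))
  }
})

test_that("glycine scan saturates on poly-G and ignores background glycine", {
  set.seed(76)
  alpha <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "G")
  dx <- paste0(rand_seq(40, alpha), paste(rep("G", 35), collapse = ""),
               rand_seq(40, alpha))
  s <- paste0(rand_seq(50, alpha), dx, rand_seq(50, alpha))
  g <- glycine_rich_scan(s, c(51, 50 + nchar(dx)), window = 11,
                         min_fraction = 0.4)
  expect_equal(nrow(g), 1)
  expect_gte(g$length, 35)
  sgly <- substr(s, g$start, g$end)
  expect_gte(mean(strsplit(sgly, "")[[1]] == "G"), 35 / g$length)

  # background glycine frequency (~7%) essentially never triggers at 0.4:
  # P(>= 5 G in an 11-window) is ~5e-4, so a 115-aa stretch of ~105
  # windows false-alarms in only a few percent of draws
  miss <- vapply(1:100, function(i) {
    v <- sample(c("G", alpha), 115, replace = TRUE,
                prob = c(0.07, rep(0.93 / 19, 19)))
    nrow(glycine_rich_scan(paste(v, collapse = ""), c(1, 115), 11, 0.4))
  }, numeric(1))
  expect_gte(mean(miss == 0), 0.94)
})

test_that("architecture assembly validates order and rejects overlaps", {
  a <- assemble_architecture("g1", c(1, 180), c(700, 880),
                             de_copies = data.frame(start = c(181, 451),
                                                    end = c(330, 600)),
                             dx = c(331, 450), size_class = "giant")
  expect_true(a$ok)
  expect_equal(a$architecture, "Ncore-DE1-DX-DE2-Ccore")

  canon <- assemble_architecture("c1", c(1, 180), c(330, 500))
  expect_true(canon$ok)
  expect_equal(canon$architecture, "Ncore-Ccore")

  bad <- assemble_architecture("b1", c(1, 180), c(700, 880),
                               de_copies = data.frame(start = c(181, 300),
                                                      end = c(330, 460)))
  expect_false(bad$ok)
  expect_match(bad$reason, "overlap")

  baddx <- assemble_architecture("b2", c(1, 180), c(700, 880),
                                 de_copies = data.frame(start = 181,
                                                        end = 330),
                                 dx = c(340, 400))
  expect_false(baddx$ok)
  expect_match(baddx$reason, "two DE copies")
})
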