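#' Parameter-recovery benchmark on synthetic giant flagellins
#'
#' Runs the full pipeline on independently seeded replicates of the
#' giant-flagellin scenario (per replicate: 4 tandem-DE-plus-DX leaves, 1
#' single-DE leaf, 1 DE-free leaf, giant-preset geometry) and measures how
#' well the planted architecture is recovered: DE copy recovery rate and
#' boundary error, DX boundary error, and glycine-region detection.
#'
#' @param n_seeds number of replicates.
#' @param seed base seed; every source of randomness derives from it.
#' @param n_taxa leaves per replicate.
#' @return list: `de_recovery` (fraction of planted DE copies matched at
#'   >= 50% overlap), `de_boundary_median` (median absolute boundary error
#'   in aa over matched copies), `dx_boundary_median` (median per-side DX
#'   boundary error), `dx_recovery`, `gly_detection` (fraction of planted
#'   glycine regions overlapped by a reported hit), `n_copies_planted`,
#'   `n_seeds`.
#' @export
benchmark_recovery <- function(n_seeds = 100, seed = 1, n_taxa = 6) {
  anc <- seed + 500L
  train <- generate_flagellins(canonical_preset(
    seed = seed + 1000L, ancestor_seed = anc, n_taxa = 6, divergence = 0.08))
  flag_seed_msa <- progressive_msa(train$records)
  flgl_seed_msa <- progressive_msa(generate_decoys(synthetic_config(
    seed = seed + 1001L, ancestor_seed = anc, n_taxa = 6,
    divergence = 0.3), 6))

  models <- c(rep("tandem_DE_plus_DX", 4), "single_DE", "none")
  models <- rep_len(models, n_taxa)
  de_err <- c(); de_matched <- 0L; de_planted <- 0L
  dx_err <- c(); dx_found <- 0L; dx_planted <- 0L
  gly_found <- 0L; gly_planted <- 0L
  for (i in seq_len(n_seeds)) {
    gen <- generate_flagellins(oceanospirillales_preset(
      seed = seed + 2000L + i, ancestor_seed = anc, n_taxa = n_taxa,
      insert_model = models))
    res <- run_flagellin_pipeline(gen$records, flag_seed_msa, flgl_seed_msa,
                                  pipeline_config(seed = seed + i))
    iv <- gen$truth$intervals
    planted <- iv[iv$segment %in% c("de1", "de2"), ]
    inst <- if (is.null(res$de)) NULL else res$de$instances
    for (j in seq_len(nrow(planted))) {
      de_planted <- de_planted + 1L
      if (is.null(inst)) next
      cand <- inst[inst$id == planted$id[j], , drop = FALSE]
      if (nrow(cand) == 0) next
      ov <- pmin(cand$end, planted$end[j]) - pmax(cand$start,
                                                  planted$start[j]) + 1
      len <- planted$end[j] - planted$start[j] + 1
      k <- which.max(ov)
      if (ov[k] / len >= 0.5) {
        de_matched <- de_matched + 1L
        de_err <- c(de_err, abs(cand$start[k] - planted$start[j]),
                    abs(cand$end[k] - planted$end[j]))
      }
    }
    dxt <- iv[iv$segment == "dx", ]
    for (j in seq_len(nrow(dxt))) {
      dx_planted <- dx_planted + 1L
      got <- res$dx[res$dx$id == dxt$id[j], , drop = FALSE]
      if (nrow(got) == 0) next
      dx_found <- dx_found + 1L
      dx_err <- c(dx_err, abs(got$start[1] - dxt$start[j]),
                  abs(got$end[1] - dxt$end[j]))
    }
    glyt <- iv[iv$segment == "gly", ]
    for (j in seq_len(nrow(glyt))) {
      gly_planted <- gly_planted + 1L
      got <- res$glycine[res$glycine$id == glyt$id[j], , drop = FALSE]
      if (nrow(got) == 0) next
      ov <- pmin(got$end, glyt$end[j]) - pmax(got$start, glyt$start[j]) + 1
      if (any(ov > 0)) gly_found <- gly_found + 1L
    }
  }
  list(de_recovery = de_matched / de_planted,
       de_boundary_median = median(de_err),
       dx_recovery = dx_found / max(dx_planted, 1L),
       dx_boundary_median = median(dx_err),
       gly_detection = gly_found / max(gly_planted, 1L),
       n_copies_planted = de_planted, n_seeds = n_seeds)
}

#' Flagellin / FlgL-like classifier benchmark
#'
#' Trains the two family models on small seed sets and classifies fresh
#' draws from the same families at the configured divergence.
#'
#' @param n_per_class test sequences per family.
#' @param divergence expected substitutions/site from each family
#'   ancestor (default 0.3).
#' @param seed base seed.
#' @return list: `accuracy`, `hard_errors` (true flagellins called
#'   FlgL-like), `n` (total test sequences).
#' @export
benchmark_classifier <- function(n_per_class = 200, divergence = 0.3,
                                 seed = 1) {
  anc <- seed + 500L
  train <- generate_flagellins(canonical_preset(
    seed = seed + 1000L, ancestor_seed = anc, n_taxa = 6, divergence = 0.08))
  flag_hmm <- build_hmm(progressive_msa(train$records), name = "flagellin")
  flgl_hmm <- build_hmm(progressive_msa(generate_decoys(synthetic_config(
    seed = seed + 1001L, ancestor_seed = anc, n_taxa = 6,
    divergence = 0.3), 6)), name = "flgl")

  test_flag <- generate_flagellins(canonical_preset(
    seed = seed + 3000L, ancestor_seed = anc, n_taxa = n_per_class,
    divergence = divergence))
  test_dec <- generate_decoys(synthetic_config(
    seed = seed + 3001L, ancestor_seed = anc, n_taxa = 2,
    divergence = divergence), n_per_class)
  cf <- classify_flagellins(test_flag$records, flag_hmm, flgl_hmm)
  cd <- classify_flagellins(test_dec, flag_hmm, flgl_hmm)
  list(accuracy = (sum(cf$label == "flagellin") +
                     sum(cd$label == "flgL_like")) / (2 * n_per_class),
       hard_errors = sum(cf$label == "flgL_like"),
       n = 2L * n_per_class)
}

#' Vertical-transmission congruence benchmark
#'
#' Simulates tandem DE duplication at the root of a balanced species tree
#' and evolution of both copies down the tree, builds the DE-copy tree by
#' neighbor joining on pairwise p-distances, and asks how often each
#' post-duplication copy tree is Robinson-Foulds identical to the species
#' tree. Conditions give each internal branch ~20 expected substitutions
#' over a DE copy so a congruent history is resolvable.
#'
#' @param n_seeds replicates.
#' @param seed base seed.
#' @param n_taxa leaves.
#' @return list: `congruent_fraction` (replicates with normalised RF 0 for
#'   every copy tree), `mean_normalised_rf`, `n_seeds`.
#' @export
benchmark_congruence <- function(n_seeds = 100, seed = 1, n_taxa = 6) {
  hits <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- synthetic_config(seed = seed + 4000L + i, n_taxa = n_taxa,
                            tree_shape = "balanced", divergence = 0.25,
                            de_length = 260, insert_model = "tandem_DE")
    gen <- generate_flagellins(cfg)
    iv <- gen$truth$intervals
    de <- iv[iv$segment %in% c("de1", "de2"), ]
    seqs <- setNames(
      substr(as.character(gen$records)[de$id], de$start, de$end),
      paste0(de$id, "/", sub("de", "", de$segment), "half"))
    de_tree <- neighbor_joining(pairwise_pdistance(seqs))
    cmp <- de_congruence(de_tree, gen$truth$tree)
    hits[i] <- max(cmp$normalised)
  }
  list(congruent_fraction = mean(hits == 0),
       mean_normalised_rf = mean(hits), n_seeds = n_seeds)
}

#' Iterative DE discovery convergence benchmark
#'
#' Builds a tandem-only synthetic dataset, seeds discovery from the
#' planted tandem pairs, and reports the iteration trace: convergence is a
#' final iteration that adds zero new regions.
#'
#' @param seed base seed.
#' @param n_taxa leaves (all tandem-DE).
#' @return list: `converged`, `n_iterations`, `final_new_hits`,
#'   `new_per_iteration`.
#' @export
benchmark_convergence <- function(seed = 1, n_taxa = 5) {
  gen <- generate_flagellins(synthetic_config(
    seed = seed + 5000L, n_taxa = n_taxa, divergence = 0.1,
    de_length = 180, insert_model = "tandem_DE"))
  iv <- gen$truth$intervals
  d1 <- iv[iv$segment == "de1", ]; d2 <- iv[iv$segment == "de2", ]
  seed_pairs <- data.frame(id = d1$id, start1 = d1$start, end1 = d1$end,
                           start2 = d2$start, end2 = d2$end)
  res <- iterative_de_discovery(gen$records, seed_pairs,
                                evalue_threshold = 0.1, max_iter = 5,
                                seed = seed)
  list(converged = res$converged, n_iterations = res$n_iterations,
       final_new_hits = res$new_per_iteration[res$n_iterations],
       new_per_iteration = res$new_per_iteration)
}

#' Synthetic giant-flagellin stand-in and its architecture
#'
#' Builds a single synthetic stand-in for a giant flagellin of the
#' reported 1,020-aa scale (giant preset, zero divergence so the geometry
#' is exact) and runs repeat discovery on it: central insert measurement
#' against canonical core models, tandem repeat seeding, DX and glycine
#' detection. No real database sequence is involved; the stand-in is
#' generator output with known ground truth.
#'
#' @param seed base seed.
#' @return list: `length_aa`, `size_class`, `n_de_copies`, `has_dx`,
#'   `gly_hits`, `insert_len`.
#' @export
giant_standin_architecture <- function(seed = 1) {
  anc <- seed + 500L
  train <- generate_flagellins(canonical_preset(
    seed = seed + 1000L, ancestor_seed = anc, n_taxa = 6, divergence = 0.08))
  flag_seed_msa <- progressive_msa(train$records)
  cores <- core_models(trim_gap_columns(flag_seed_msa, 0.5)$msa, 180, 180)
  gen <- generate_flagellins(oceanospirillales_preset(
    seed = seed + 6000L, ancestor_seed = anc, n_taxa = 2, divergence = 0,
    indel_rate = 0))
  s <- as.character(gen$records[[1]])
  m <- measure_insert(s, cores$ncore, cores$ccore)
  thr <- repeat_null_threshold(substr(s, m$insert_start, m$insert_end),
                               seed = seed)
  rp <- find_tandem_repeats(s, c(m$insert_start, m$insert_end),
                            min_score = thr)
  n_de <- if (nrow(rp) == 0) 0L else 2L
  dx <- if (nrow(rp) == 1)
    detect_dx(data.frame(start = c(rp$start1, rp$start2),
                         end = c(rp$end1, rp$end2)))
  else NULL
  gly <- if (!is.null(dx)) glycine_rich_scan(s, dx) else
    data.frame(start = integer(0))
  list(length_aa = nchar(s), size_class = size_class(nchar(s)),
       n_de_copies = n_de, has_dx = !is.null(dx), gly_hits = nrow(gly),
       insert_len = m$insert_len)
}
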