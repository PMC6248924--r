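#' Run configuration for the full pipeline
#'
#' All thresholds in one validated object; the whole configuration is
#' embedded in the run summary for provenance.
#'
#' @param seed integer seed for every stochastic step (null thresholds,
#'   E-value calibration).
#' @param evalue_threshold HMM scan significance threshold (default 0.1,
#'   the scan significance rule for DE-region occurrence).
#' @param trim_max_gap occupancy trim threshold for the core alignment.
#' @param ambiguity_band classifier margin half-width (bits).
#' @param n_core_cols,c_core_cols core block widths for insert
#'   measurement.
#' @param dotplot_window Dotlet-style window (odd).
#' @param repeat_min_len minimum tandem repeat length / diagonal
#'   exclusion band.
#' @param null_n shuffles for the repeat-seeding null threshold.
#' @param calib_n shuffles for E-value calibration (>= 100).
#' @param min_dx_length minimum DX insert length.
#' @param gly_window,gly_min_fraction glycine scan window and threshold.
#' @param max_iter DE-discovery iteration cap.
#' @param out_dir optional output directory for stage TSVs and the JSON
#'   summary.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, evalue_threshold = 0.1,
                            trim_max_gap = 0.5, ambiguity_band = 2,
                            n_core_cols = 180, c_core_cols = 180,
                            dotplot_window = 15, repeat_min_len = 20,
                            null_n = 50, calib_n = 100, min_dx_length = 20,
                            gly_window = 11, gly_min_fraction = 0.4,
                            max_iter = 5, out_dir = NULL) {
  stopifnot(evalue_threshold > 0, trim_max_gap > 0, trim_max_gap <= 1,
            ambiguity_band >= 0, dotplot_window %% 2 == 1,
            repeat_min_len >= 5, calib_n >= 100, gly_window >= 5,
            gly_min_fraction > 0, gly_min_fraction <= 1, max_iter >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

# tiny FNV-1a over a string, for the provenance config hash; arithmetic
# kept inside double precision (32-bit state split into 16-bit halves)
fnv1a <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full giant-flagellin analysis
#'
#' Stages, in order: dual-HMM family classification; size classes and
#' central-insert measurement; tandem repeat seeding; iterative DE
#' discovery; DX and glycine-region detection; architecture assembly;
#' D0/D1 core phylogeny; insert annotation; DE-vs-core-tree congruence.
#' Identical inputs and config give identical outputs. A stage failure
#' halts the run with the stage name (and leaves a FAILED marker when
#' writing to disk).
#'
#' @param records input sequences (AAStringSet or named character).
#' @param flagellin_seed [flg_msa] of established true flagellins.
#' @param flgl_seed [flg_msa] of established FlgL-family proteins.
#' @param config a [pipeline_config()].
#' @return list with per-stage tables (`classification`, `inserts`,
#'   `repeats`, `de`, `dx`, `glycine`, `architectures`, `core_tree`,
#'   `annotated`, `congruence`) and a `summary` list.
#' @export
run_flagellin_pipeline <- function(records, flagellin_seed, flgl_seed,
                                   config = pipeline_config()) {
  seqs <- as_seqset(records)
  if (length(seqs) == 0) stop("empty input: no sequences to analyse")
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scheme <- scoring_scheme()
  res <- list()

  # family models + classification
  cls <- stage("classify", {
    flag_hmm <- build_hmm(flagellin_seed, name = "flagellin")
    flgl_hmm <- build_hmm(flgl_seed, name = "flgl")
    classify_flagellins(seqs, flag_hmm, flgl_hmm, config$ambiguity_band)
  })
  res$classification <- cls
  flag_ids <- cls$id[cls$label == "flagellin"]

  # size classes + central inserts
  insres <- stage("inserts", {
    trimmed <- trim_gap_columns(flagellin_seed, config$trim_max_gap)
    cores <- core_models(trimmed$msa, config$n_core_cols,
                         config$c_core_cols)
    list(cores = cores,
         table = measure_inserts(seqs[flag_ids], cores$ncore, cores$ccore))
  })
  res$core_hmms <- insres$cores
  ins <- insres$table
  res$inserts <- ins

  # tandem repeat seeding (null threshold computed once per run)
  reps <- stage("repeats", {
    ok <- ins[ins$status == "ok" &
                ins$insert_len >= 2 * config$repeat_min_len, , drop = FALSE]
    thr <- NA_real_
    pairs <- list()
    for (i in seq_len(nrow(ok))) {
      insseq <- substr(seqs[[ok$id[i]]], ok$insert_start[i], ok$insert_end[i])
      if (is.na(thr))
        thr <- repeat_null_threshold(insseq, scheme, config$repeat_min_len,
                                     n = config$null_n, seed = config$seed)
      tp <- find_tandem_repeats(seqs[[ok$id[i]]],
                                c(ok$insert_start[i], ok$insert_end[i]),
                                scheme, min_score = thr,
                                min_len = config$repeat_min_len)
      if (nrow(tp) > 0) pairs[[length(pairs) + 1]] <- cbind(id = ok$id[i], tp)
    }
    list(threshold = thr,
         pairs = if (length(pairs)) do.call(rbind, pairs)
                 else data.frame(id = character(0), start1 = integer(0),
                                 end1 = integer(0), start2 = integer(0),
                                 end2 = integer(0), score = numeric(0),
                                 identity = numeric(0)))
  })
  res$repeats <- reps$pairs

  # iterative DE discovery across the flagellin set
  de <- stage("de_discovery", {
    if (nrow(reps$pairs) == 0) NULL
    else iterative_de_discovery(seqs[flag_ids], reps$pairs,
                                config$evalue_threshold,
                                max_iter = config$max_iter, scheme = scheme,
                                seed = config$seed,
                                calib_n = config$calib_n)
  })
  res$de <- de

  # DX + glycine region per sequence with exactly two DE copies
  dxg <- stage("dx_glycine", {
    dx_rows <- list(); gly_rows <- list()
    if (!is.null(de)) {
      for (id in unique(de$instances$id)) {
        copies <- de$instances[de$instances$id == id, , drop = FALSE]
        dx <- detect_dx(copies, config$min_dx_length)
        if (is.null(dx)) next
        dx_rows[[length(dx_rows) + 1]] <-
          data.frame(id = id, start = unname(dx[1]), end = unname(dx[2]),
                     length = unname(dx[2] - dx[1] + 1L))
        g <- glycine_rich_scan(seqs[[id]], dx, config$gly_window,
                               config$gly_min_fraction)
        if (nrow(g) > 0)
          gly_rows[[length(gly_rows) + 1]] <- cbind(id = id, g)
      }
    }
    list(dx = if (length(dx_rows)) do.call(rbind, dx_rows)
              else data.frame(id = character(0), start = integer(0),
                              end = integer(0), length = integer(0)),
         gly = if (length(gly_rows)) do.call(rbind, gly_rows)
               else data.frame(id = character(0), start = integer(0),
                               end = integer(0), length = integer(0),
                               fraction = numeric(0)))
  })
  res$dx <- dxg$dx
  res$glycine <- dxg$gly

  # architectures
  arch <- stage("architectures", {
    rows <- list()
    for (i in seq_len(nrow(ins))) {
      if (ins$status[i] != "ok") next
      id <- ins$id[i]
      copies <- if (!is.null(de))
        de$instances[de$instances$id == id, c("start", "end"), drop = FALSE]
      else NULL
      dx <- res$dx[res$dx$id == id, , drop = FALSE]
      a <- assemble_architecture(
        id, c(ins$ncore_start[i], ins$ncore_end[i]),
        c(ins$ccore_start[i], ins$ccore_end[i]),
        de_copies = copies,
        dx = if (nrow(dx) > 0) c(dx$start[1], dx$end[1]) else NULL,
        size_class = ins$size_class[i])
      rows[[length(rows) + 1]] <- data.frame(
        id = id, ok = a$ok, architecture = a$architecture,
        n_de = if (is.null(copies)) 0L else nrow(copies),
        has_dx = nrow(dx) > 0, insert_len = ins$insert_len[i],
        length = ins$length[i], size_class = ins$size_class[i],
        reason = a$reason)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(id = character(0), ok = logical(0),
                    architecture = character(0), n_de = integer(0),
                    has_dx = logical(0), insert_len = integer(0),
                    length = integer(0), size_class = character(0),
                    reason = character(0))
  })
  res$architectures <- arch

  # D0/D1 core phylogeny
  tre <- stage("core_tree", {
    okins <- ins[ins$status == "ok", , drop = FALSE]
    if (nrow(okins) < 3) NULL else {
      core_seqs <- setNames(paste0(
        substr(seqs[okins$id], okins$ncore_start, okins$ncore_end),
        substr(seqs[okins$id], okins$ccore_start, okins$ccore_end)),
        okins$id)
      msa <- progressive_msa(core_seqs, scheme)
      trm <- trim_gap_columns(msa, config$trim_max_gap)
      dm <- core_distance_matrix(trm$msa, "poisson_corrected")
      neighbor_joining(dm)
    }
  })
  res$core_tree <- tre

  res$annotated <- stage("annotate", {
    if (is.null(tre)) NULL else annotate_inserts(tre, arch)
  })

  # DE-copy tree vs core tree congruence
  cong <- stage("congruence", {
    if (is.null(de) || is.null(tre)) NULL else {
      inst <- de$instances
      labs <- paste0(inst$id, "/", inst$origin)
      dup <- ave(seq_along(labs), labs, FUN = seq_along)
      labs <- ifelse(dup > 1, paste0(labs, ".", dup), labs)
      if (length(labs) < 4) NULL else {
        de_seqs <- setNames(substr(seqs[inst$id], inst$start, inst$end), labs)
        dm <- pairwise_pdistance(de_seqs, scheme)
        de_tree <- neighbor_joining(dm)
        list(de_tree = de_tree, table = de_congruence(de_tree, tre))
      }
    }
  })
  res$de_tree <- cong$de_tree
  cong <- cong$table
  res$congruence <- cong

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA)
  res$summary <- list(
    n_input = length(seqs),
    n_flagellin = sum(cls$label == "flagellin"),
    n_flgl_like = sum(cls$label == "flgL_like"),
    n_ambiguous = sum(cls$label == "ambiguous"),
    n_canonical = sum(ins$size_class == "canonical"),
    n_large = sum(ins$size_class == "large"),
    n_giant = sum(ins$size_class == "giant"),
    n_tandem_seed_pairs = nrow(reps$pairs),
    n_de_copies = if (is.null(de)) 0L else nrow(de$instances),
    de_iterations = if (is.null(de)) 0L else de$n_iterations,
    de_converged = if (is.null(de)) NA else de$converged,
    n_with_dx = nrow(res$dx),
    n_glycine_hits = nrow(res$glycine),
    congruence = cong,
    seed = config$seed,
    config = jsonlite::fromJSON(cfg_json),
    config_hash = fnv1a(cfg_json))

  if (!is.null(out_dir)) {
    write_tsv0(cls, file.path(out_dir, "classification.tsv"))
    write_tsv0(ins, file.path(out_dir, "inserts.tsv"))
    write_tsv0(reps$pairs, file.path(out_dir, "repeats.tsv"))
    if (!is.null(de)) {
      write_tsv0(de$instances, file.path(out_dir, "de_instances.tsv"))
      write_de_instances(seqs, de$instances,
                         file.path(out_dir, "de_instances.fasta"))
      write_hmm(de$hmm, file.path(out_dir, "de_model.hmm"))
    }
    write_tsv0(res$dx, file.path(out_dir, "dx.tsv"))
    write_tsv0(res$glycine, file.path(out_dir, "glycine.tsv"))
    write_tsv0(arch, file.path(out_dir, "architectures.tsv"))
    if (!is.null(tre)) {
      writeLines(write_newick(tre), file.path(out_dir, "core_tree.nwk"))
      writeLines(res$annotated$newick,
                 file.path(out_dir, "core_tree_annotated.nwk"))
      write_tsv0(res$annotated$legend, file.path(out_dir, "tree_legend.tsv"))
    }
    if (!is.null(cong)) write_tsv0(cong, file.path(out_dir, "congruence.tsv"))
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  res
}
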