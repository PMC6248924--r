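#' Score threshold for repeat seeding from a shuffled null
#'
#' 99th percentile of off-diagonal self-alignment scores of residue
#' shuffles of the insert — the score a repeat-free sequence of the same
#' composition reaches by chance. Computed once per run and reused.
#'
#' @param insert_seq the central-insert sequence.
#' @param scheme a [scoring_scheme()].
#' @param exclusion_band as in [self_offdiagonal_align()].
#' @param n number of shuffles.
#' @param q quantile (default 0.99).
#' @param seed RNG seed.
#' @return numeric threshold.
#' @export
repeat_null_threshold <- function(insert_seq, scheme = scoring_scheme(),
                                  exclusion_band = 20, n = 50, q = 0.99,
                                  seed = 1) {
  v <- strsplit(as_residues(insert_seq), "")[[1]]
  set.seed(seed)
  sc <- vapply(seq_len(n), function(i) {
    s <- paste(sample(v), collapse = "")
    self_offdiagonal_align(s, scheme, exclusion_band)$score
  }, numeric(1))
  as.numeric(quantile(sc, q, type = 1))
}

#' Find tandem repeat pairs inside a central insert
#'
#' Off-diagonal self-alignment restricted to the insert; an alignment
#' scoring at least `min_score` is reported as a tandem pair (upstream
#' copy first, copies never overlapping). Inserts shorter than twice the
#' minimum repeat length return an empty table, not an error.
#'
#' @param s the full sequence.
#' @param insert_interval c(start, end), 1-based closed, from
#'   [measure_insert()].
#' @param scheme a [scoring_scheme()].
#' @param min_score seeding threshold; see [repeat_null_threshold()].
#' @param min_len minimum repeat length, also the diagonal exclusion band.
#' @return data.frame: start1, end1, start2, end2, score, identity
#'   (coordinates on the full sequence).
#' @export
find_tandem_repeats <- function(s, insert_interval, scheme = scoring_scheme(),
                                min_score = 40, min_len = 20) {
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      score = numeric(0), identity = numeric(0))
  seqc <- as_residues(s)
  is <- insert_interval[1]; ie <- insert_interval[2]
  if (ie - is + 1 < 2 * min_len) return(empty)
  sub <- substr(seqc, is, ie)
  band <- min_len
  found <- FALSE
  for (try in 1:3) {
    al <- self_offdiagonal_align(sub, scheme, band)
    if (al$score < min_score) return(empty)
    q <- al$query_interval; b <- al$subject_interval
    if (q[2] < b[1]) { found <- TRUE; break }
    band <- band * 2 # periodic overlap: push the copies apart
    if (band >= nchar(sub)) return(empty)
  }
  if (!found) return(empty)
  cols <- al$columns
  v <- strsplit(sub, "")[[1]]
  # polish boundaries: the local optimum can ride the repeat diagonal into
  # flanking chance matches, so trim each end back to the first run of 3
  # consecutive identity columns
  idcol <- !is.na(cols$query) & !is.na(cols$subject) &
    v[ifelse(is.na(cols$query), 1L, cols$query)] ==
      v[ifelse(is.na(cols$subject), 1L, cols$subject)]
  run3 <- which(idcol & c(idcol[-1], FALSE) & c(idcol[-(1:2)], FALSE, FALSE))
  if (length(run3) == 0) return(empty)
  keep <- seq(min(run3), max(run3) + 2L)
  cols <- cols[keep, , drop = FALSE]
  q <- range(cols$query, na.rm = TRUE)
  b <- range(cols$subject, na.rm = TRUE)
  if (q[2] >= b[1]) return(empty)
  # recompute the trimmed score from the surviving columns
  both <- !is.na(cols$query) & !is.na(cols$subject)
  sc <- sum(scheme$substitution[cbind(v[cols$query[both]],
                                      v[cols$subject[both]])])
  gaps <- rle(ifelse(is.na(cols$query), "gq",
                     ifelse(is.na(cols$subject), "gs", "m")))
  sc <- sc - sum(vapply(which(gaps$values != "m"), function(i)
    scheme$gap_open + (gaps$lengths[i] - 1) * scheme$gap_extend, numeric(1)))
  if (sc < min_score) return(empty)
  ident <- mean(v[cols$query[both]] == v[cols$subject[both]])
  data.frame(start1 = is + q[1] - 1L, end1 = is + q[2] - 1L,
             start2 = is + b[1] - 1L, end2 = is + b[2] - 1L,
             score = sc, identity = ident)
}

#' Iterative DE-region discovery
#'
#' Implements the expand-and-refine loop: build an alignment of the
#' current DE instances, build and calibrate an HMM from it, scan all
#' records, pool novel non-overlapping hits, and repeat until an iteration
#' adds nothing new (or `max_iter` is reached, which sets `converged =
#' FALSE` instead of raising). The instance set grows monotonically.
#'
#' @param records all sequences under study.
#' @param seed_pairs data.frame of tandem pairs per id (columns id,
#'   start1, end1, start2, end2) seeding the first alignment.
#' @param evalue_threshold scan significance threshold (default 0.1).
#' @param max_iter iteration cap.
#' @param scheme a [scoring_scheme()].
#' @param seed RNG seed for E-value calibration.
#' @param calib_n shuffles for calibration.
#' @return list: `hmm` (final model), `instances` (data.frame id, start,
#'   end, origin), `n_iterations`, `converged`, `new_per_iteration`.
#' @export
iterative_de_discovery <- function(records, seed_pairs, evalue_threshold = 0.1,
                                   max_iter = 5, scheme = scoring_scheme(),
                                   seed = 1, calib_n = 100) {
  if (nrow(seed_pairs) == 0) stop("seed_pairs must be non-empty")
  seqs <- as_seqset(records)
  inst <- rbind(
    data.frame(id = seed_pairs$id, start = seed_pairs$start1,
               end = seed_pairs$end1, origin = "1half"),
    data.frame(id = seed_pairs$id, start = seed_pairs$start2,
               end = seed_pairs$end2, origin = "2half"))
  inst <- inst[order(match(inst$id, names(seqs)), inst$start), ]
  new_counts <- integer(0)
  hmm <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fasta <- setNames(
      substr(seqs[inst$id], inst$start, inst$end),
      paste0(inst$id, "/", inst$origin, ".", seq_len(nrow(inst))))
    msa <- progressive_msa(fasta, scheme)
    hmm <- build_hmm(msa, name = paste0("DE_iter", it))
    hmm <- calibrate_evalues(hmm, seqs, n_shuffles = calib_n,
                             seed = seed + it)
    hits <- scan_hmm(hmm, seqs, evalue_threshold)
    novel <- hits[!vapply(seq_len(nrow(hits)), function(i) {
      any(inst$id == hits$id[i] &
            pmin(inst$end, hits$end[i]) - pmax(inst$start, hits$start[i]) >= 0)
    }, logical(1)), , drop = FALSE]
    new_counts <- c(new_counts, nrow(novel))
    if (nrow(novel) == 0) { converged <- TRUE; break }
    inst <- rbind(inst,
                  data.frame(id = novel$id, start = novel$start,
                             end = novel$end, origin = "scan"))
    inst <- inst[order(match(inst$id, names(seqs)), inst$start), ]
  }
  rownames(inst) <- NULL
  list(hmm = hmm, instances = inst, n_iterations = length(new_counts),
       converged = converged, new_per_iteration = new_counts)
}

#' Export DE instances as FASTA
#'
#' Instance ids follow the `id/1half`, `id/2half` convention for copies
#' first seen as tandem pairs; HMM-scan discoveries carry `/scan`.
#'
#' @param records the source sequences.
#' @param instances instance table from [iterative_de_discovery()].
#' @param path output FASTA.
#' @export
write_de_instances <- function(records, instances, path) {
  seqs <- as_seqset(records)
  out <- Biostrings::AAStringSet(
    setNames(substr(seqs[instances$id], instances$start, instances$end),
             paste0(instances$id, "/", instances$origin)))
  # suffix duplicates so ids stay unique
  nm <- names(out)
  if (anyDuplicated(nm)) {
    dup <- ave(seq_along(nm), nm, FUN = seq_along)
    names(out) <- ifelse(dup > 1, paste0(nm, ".", dup), nm)
  }
  write_fasta(out, path)
}

#' DE-eXtension (DX) insert between two tandem DE copies
#'
#' The DX insert is the stretch strictly between DE copy 1 and DE copy 2,
#' reported only when exactly two copies are present and the gap reaches
#' `min_dx_length`; otherwise absent by contract (NULL).
#'
#' @param de_copies data.frame with columns start, end (one row per copy,
#'   in sequence order).
#' @param min_dx_length minimum DX length (default 20).
#' @return c(start, end) or NULL.
#' @export
detect_dx <- function(de_copies, min_dx_length = 20) {
  if (is.null(de_copies) || nrow(de_copies) != 2) return(NULL)
  o <- order(de_copies$start)
  gap_start <- de_copies$end[o[1]] + 1L
  gap_end <- de_copies$start[o[2]] - 1L
  if (gap_end - gap_start + 1L < min_dx_length) return(NULL)
  c(start = gap_start, end = gap_end)
}

#' Scan a DX insert for glycine-rich regions
#'
#' Slides a window across the DX interval, keeps windows whose glycine
#' fraction reaches `min_fraction`, and merges overlapping windows into
#' maximal intervals (the construct behind the conserved ~35 aa
#' glycine-rich region of the largest flagellins).
#'
#' @param s the full sequence.
#' @param dx_interval c(start, end) on the full sequence.
#' @param window sliding window width (>= 5).
#' @param min_fraction minimum glycine fraction per window (default 0.4).
#' @return data.frame: start, end, length, fraction (overall G fraction of
#'   each merged interval), coordinates on the full sequence.
#' @export
glycine_rich_scan <- function(s, dx_interval, window = 11,
                              min_fraction = 0.4) {
  if (window < 5) stop("window must be >= 5")
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fraction = numeric(0))
  seqc <- as_residues(s)
  ds <- dx_interval[1]; de <- dx_interval[2]
  len <- de - ds + 1
  if (len < window) return(empty)
  v <- strsplit(substr(seqc, ds, de), "")[[1]] == "G"
  cs <- cumsum(c(0, v))
  starts <- seq_len(len - window + 1)
  frac <- (cs[starts + window] - cs[starts]) / window
  hit <- frac >= min_fraction
  if (!any(hit)) return(empty)
  # merge overlapping qualifying windows
  runs <- rle(hit)
  pos <- cumsum(c(1, runs$lengths))
  out <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    w0 <- pos[i]; w1 <- pos[i + 1] - 1
    a <- w0; b <- w1 + window - 1
    out[[length(out) + 1]] <- data.frame(
      start = ds + a - 1L, end = ds + b - 1L, length = b - a + 1L,
      fraction = (cs[b + 1] - cs[a]) / (b - a + 1))
  }
  do.call(rbind, out)
}

#' Assemble and validate one flagellin architecture
#'
#' Orders the measured components (N-core, DE copies, optional DX,
#' C-core) and validates that they are non-overlapping and strictly
#' increasing. An invalid combination returns a structured rejection
#' naming the first violated constraint — components are never silently
#' trimmed.
#'
#' @param id sequence id.
#' @param n_core,c_core c(start, end) core hit intervals.
#' @param de_copies data.frame with start, end (0 or more rows).
#' @param dx c(start, end) or NULL.
#' @param size_class one of canonical/large/giant.
#' @return object of class `flg_architecture`: `ok`, `reason` (when
#'   rejected), component table, and a compact architecture string such as
#'   `"Ncore-DE1-DX-DE2-Ccore"`.
#' @export
assemble_architecture <- function(id, n_core, c_core, de_copies = NULL,
                                  dx = NULL, size_class = "canonical") {
  comp <- data.frame(component = "Ncore", start = n_core[1], end = n_core[2])
  if (!is.null(de_copies) && nrow(de_copies) > 0) {
    o <- order(de_copies$start)
    for (i in seq_along(o)) {
      comp <- rbind(comp, data.frame(component = paste0("DE", i),
                                     start = de_copies$start[o[i]],
                                     end = de_copies$end[o[i]]))
    }
  }
  if (!is.null(dx))
    comp <- rbind(comp, data.frame(component = "DX", start = dx[1],
                                   end = dx[2]))
  comp <- rbind(comp, data.frame(component = "Ccore", start = c_core[1],
                                 end = c_core[2]))
  comp <- comp[order(comp$start), ]
  rownames(comp) <- NULL
  reject <- function(reason) structure(
    list(id = id, ok = FALSE, reason = reason, components = comp,
         architecture = NA_character_, size_class = size_class),
    class = "flg_architecture")
  if (any(comp$end < comp$start)) {
    bad <- comp$component[which(comp$end < comp$start)[1]]
    return(reject(paste0("component ", bad, " has end < start")))
  }
  if (!is.null(dx)) {
    nde <- sum(startsWith(comp$component, "DE"))
    if (nde < 2) return(reject("DX present without two DE copies"))
    de1 <- comp[comp$component == "DE1", ]; de2 <- comp[comp$component == "DE2", ]
    if (!(dx[1] > de1$end && dx[2] < de2$start))
      return(reject("DX does not lie strictly between DE1 and DE2"))
  }
  if (nrow(comp) > 1) {
    for (i in seq_len(nrow(comp) - 1)) {
      if (comp$start[i + 1] <= comp$end[i])
        return(reject(paste0("components ", comp$component[i], " and ",
                             comp$component[i + 1], " overlap")))
    }
  }
  if (comp$component[1] != "Ncore" || comp$component[nrow(comp)] != "Ccore")
    return(reject("cores do not flank the architecture"))
  structure(list(id = id, ok = TRUE, reason = NA_character_,
                 components = comp,
                 architecture = paste(comp$component, collapse = "-"),
                 size_class = size_class),
            class = "flg_architecture")
}

#' @export
print.flg_architecture <- function(x, ...) {
  if (x$ok) cat("architecture ", x$id, ": ", x$architecture, " (",
                x$size_class, ")\n", sep = "")
  else cat("architecture ", x$id, ": REJECTED - ", x$reason, "\n", sep = "")
  invisible(x)
}
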