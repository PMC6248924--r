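#' Dual-HMM voting classifier: flagellin vs FlgL-like
#'
#' Scores every record under a flagellin profile HMM and a FlgL profile
#' HMM (both built from established family examples) and votes on the bit
#' score margin: flagellin if margin > +band, FlgL-like if margin < -band,
#' ambiguous otherwise (a margin of exactly 0 is always ambiguous).
#'
#' @param records sequences to classify.
#' @param flagellin_hmm,flgl_hmm the two family models (same background).
#' @param ambiguity_band margin half-width in bits (default 2).
#' @return data.frame: id, label, bits_flagellin, bits_flgl, margin.
#' @export
classify_flagellins <- function(records, flagellin_hmm, flgl_hmm,
                                ambiguity_band = 2) {
  seqs <- as_seqset(records)
  bf <- vapply(seqs, function(s) forward_score(flagellin_hmm, s), numeric(1))
  bl <- vapply(seqs, function(s) forward_score(flgl_hmm, s), numeric(1))
  margin <- bf - bl
  label <- ifelse(margin > ambiguity_band, "flagellin",
                  ifelse(margin < -ambiguity_band, "flgL_like", "ambiguous"))
  data.frame(id = names(seqs), label = label, bits_flagellin = unname(bf),
             bits_flgl = unname(bl), margin = unname(margin),
             row.names = NULL)
}

#' Flagellin size class
#'
#' Canonical at or below 800 aa, large above 800 aa, giant above 1,000 aa
#' (strict inequalities on residue count).
#'
#' @param x sequence lengths (numeric), sequences, or an `AAStringSet`.
#' @return character vector of `canonical` / `large` / `giant`.
#' @export
size_class <- function(x) {
  len <- if (is.numeric(x)) x
         else if (methods::is(x, "XStringSet")) Biostrings::width(x)
         else nchar(as_seqset(x))
  out <- ifelse(len > 1000, "giant", ifelse(len > 800, "large", "canonical"))
  unname(out)
}

#' Core models from a seed alignment
#'
#' Builds the N-terminal and C-terminal core profile HMMs from the leading
#' and trailing column blocks of a (trimmed) seed alignment of established
#' flagellins — the conserved regions that fold into the D0/D1 domains.
#'
#' @param seed_msa a [flg_msa] of full-length flagellins.
#' @param n_core_cols,c_core_cols number of leading/trailing columns taken
#'   as the N-core and C-core blocks.
#' @param ... passed to [build_hmm()].
#' @return list with `ncore` and `ccore` profile HMMs.
#' @export
core_models <- function(seed_msa, n_core_cols = 180, c_core_cols = 180, ...) {
  m <- as.matrix(seed_msa)
  W <- ncol(m)
  if (n_core_cols + c_core_cols > W)
    stop("core blocks exceed the alignment width")
  sub_msa <- function(cols, tag) {
    rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    flg_msa(seed_msa$ids, rows)
  }
  list(ncore = build_hmm(sub_msa(seq_len(n_core_cols)), name = "ncore", ...),
       ccore = build_hmm(sub_msa(seq(W - c_core_cols + 1, W)),
                         name = "ccore", ...))
}

#' Measure the hypervariable central insert of one flagellin
#'
#' Locates the N-core and C-core by Viterbi decoding and reports the
#' insert between them: `[n_core end + 1, c_core start - 1]` (1-based
#' closed; length 0 when the cores abut). A missing core hit yields a
#' no-call with the reason; cores out of order or overlapping raise an
#' error, never a silently clipped interval.
#'
#' @param s one sequence.
#' @param ncore_hmm,ccore_hmm core models from [core_models()].
#' @param min_bits minimum core bit score to accept a hit (default 0).
#' @return list: status ("ok" or the no-call reason), insert_start,
#'   insert_end, insert_len, n_core and c_core hit intervals.
#' @export
measure_insert <- function(s, ncore_hmm, ccore_hmm, min_bits = 0) {
  vn <- viterbi_decode(ncore_hmm, s)
  vc <- viterbi_decode(ccore_hmm, s)
  nocall <- function(reason) list(status = reason, insert_start = NA_integer_,
                                  insert_end = NA_integer_,
                                  insert_len = NA_integer_,
                                  n_core = c(NA_integer_, NA_integer_),
                                  c_core = c(NA_integer_, NA_integer_))
  if (is.na(vn$start) || vn$bits < min_bits) return(nocall("no N-core hit"))
  if (is.na(vc$start) || vc$bits < min_bits) return(nocall("no C-core hit"))
  if (vc$start <= vn$end)
    stop("core hits overlap or are out of order (N-core ends at ", vn$end,
         ", C-core starts at ", vc$start, ")")
  list(status = "ok",
       insert_start = vn$end + 1L, insert_end = vc$start - 1L,
       insert_len = vc$start - vn$end - 1L,
       n_core = c(vn$start, vn$end), c_core = c(vc$start, vc$end))
}

#' Measure inserts for a whole collection
#'
#' @param records sequences.
#' @inheritParams measure_insert
#' @return data.frame: id, status, insert_start, insert_end, insert_len,
#'   ncore_start, ncore_end, ccore_start, ccore_end, length, size_class.
#' @export
measure_inserts <- function(records, ncore_hmm, ccore_hmm, min_bits = 0) {
  seqs <- as_seqset(records)
  rows <- lapply(names(seqs), function(id) {
    r <- measure_insert(seqs[[id]], ncore_hmm, ccore_hmm, min_bits)
    data.frame(id = id, status = r$status, insert_start = r$insert_start,
               insert_end = r$insert_end, insert_len = r$insert_len,
               ncore_start = r$n_core[1], ncore_end = r$n_core[2],
               ccore_start = r$c_core[1], ccore_end = r$c_core[2],
               length = nchar(seqs[[id]]),
               size_class = size_class(nchar(seqs[[id]])))
  })
  do.call(rbind, rows)
}
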