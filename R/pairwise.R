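# sequences arrive as AAStringSet elements, plain strings, or named strings;
# normalise to one uppercase string
as_residues <- function(s) {
  if (methods::is(s, "XStringSet")) {
    if (length(s) != 1) stop("expected a single sequence")
    s <- as.character(s)
  } else if (methods::is(s, "XString")) s <- as.character(s)
  if (!is.character(s) || length(s) != 1) stop("expected a single sequence")
  s <- toupper(unname(s))
  if (!nzchar(s)) stop("empty sequence")
  s
}

align_result <- function(res, mode) {
  empty <- length(res$a_idx) == 0
  structure(list(
    score = res$score,
    # 1-based closed intervals; empty alignment reported as zero-length
    query_interval = if (empty) c(start = 1L, end = 0L)
                     else c(start = res$a_start + 1L, end = res$a_end + 1L),
    subject_interval = if (empty) c(start = 1L, end = 0L)
                       else c(start = res$b_start + 1L, end = res$b_end + 1L),
    columns = data.frame(query = ifelse(res$a_idx < 0, NA_integer_,
                                        res$a_idx + 1L),
                         subject = ifelse(res$b_idx < 0, NA_integer_,
                                          res$b_idx + 1L)),
    mode = mode), class = "flg_alignment")
}

#' @export
print.flg_alignment <- function(x, ...) {
  cat(x$mode, "alignment: score", x$score, "query",
      x$query_interval[1], "-", x$query_interval[2], "subject",
      x$subject_interval[1], "-", x$subject_interval[2], "\n")
  invisible(x)
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under `scheme`; ties are broken deterministically
#' (diagonal > up > left, earliest cell wins) so results are reproducible.
#' Intervals are 1-based closed; a sequence pair with no positive-scoring
#' residue pair returns score 0 and empty intervals.
#'
#' @param a,b sequences (strings or single-element `AAStringSet`s).
#' @param scheme a [scoring_scheme()].
#' @return a `flg_alignment` with `score`, `query_interval`,
#'   `subject_interval` and per-column index pairs.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  ai <- encode_seq(as_residues(a)); bi <- encode_seq(as_residues(b))
  P <- pair_score_matrix(ai, bi, scheme)
  align_result(cpp_align_matrix(P, scheme$gap_open, scheme$gap_extend,
                                TRUE, 0L), "local")
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' @inheritParams local_align
#' @return a `flg_alignment` spanning both sequences end to end.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  ai <- encode_seq(as_residues(a)); bi <- encode_seq(as_residues(b))
  P <- pair_score_matrix(ai, bi, scheme)
  align_result(cpp_align_matrix(P, scheme$gap_open, scheme$gap_extend,
                                FALSE, 0L), "global")
}

#' Windowed dot-plot of two sequences
#'
#' Entry (i, j) is the sum of substitution scores over the diagonal window
#' centred at (i, j), truncated at the edges; the Dotlet-style view used to
#' spot internal duplications.
#'
#' @inheritParams local_align
#' @param window odd window width, at most the shorter sequence length.
#' @return object of class `flg_dotplot`: the score matrix plus the window.
#' @export
dotplot <- function(a, b, window = 15, scheme = scoring_scheme()) {
  ai <- encode_seq(as_residues(a)); bi <- encode_seq(as_residues(b))
  if (window %% 2 == 0) stop("dot-plot window must be odd")
  if (window > min(length(ai), length(bi)))
    stop("window exceeds the shorter sequence")
  P <- pair_score_matrix(ai, bi, scheme)
  D <- cpp_dotplot(P, as.integer(window))
  structure(list(matrix = D, window = as.integer(window)),
            class = "flg_dotplot")
}

#' @export
print.flg_dotplot <- function(x, ...) {
  cat("flg_dotplot:", nrow(x$matrix), "x", ncol(x$matrix),
      "window", x$window, "\n")
  invisible(x)
}

#' Export a dot-plot matrix as TSV
#' @param dp a `flg_dotplot`.
#' @param path output path.
#' @export
write_dotplot <- function(dp, path) {
  write.table(dp$matrix, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Off-diagonal local self-alignment
#'
#' Aligns a sequence against itself with all cells within `exclusion_band`
#' of the main diagonal forbidden — the seed operation for tandem repeat
#' discovery: a strong off-diagonal alignment is an internal duplication.
#'
#' @param s the sequence.
#' @param scheme a [scoring_scheme()].
#' @param exclusion_band minimum |i - j| allowed (>= 1 and < sequence length).
#' @return a `flg_alignment`; the query interval is the upstream copy.
#' @export
self_offdiagonal_align <- function(s, scheme = scoring_scheme(),
                                   exclusion_band = 20) {
  si <- encode_seq(as_residues(s))
  if (exclusion_band < 1) stop("exclusion_band must be >= 1")
  if (exclusion_band >= length(si))
    stop("exclusion_band must be smaller than the sequence length")
  P <- pair_score_matrix(si, si, scheme)
  align_result(cpp_align_matrix(P, scheme$gap_open, scheme$gap_extend,
                                TRUE, as.integer(exclusion_band)), "local")
}
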