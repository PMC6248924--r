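#' @keywords internal
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' @keywords internal
AA21 <- c(AA20, "X")

# integer codes 0..20 for the C++ kernels; X = 20
encode_seq <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  idx <- match(v, AA21)
  if (anyNA(idx)) {
    bad <- v[is.na(idx)][1]
    stop("illegal residue character '", bad, "'")
  }
  idx - 1L
}

#' Affine-gap scoring scheme
#'
#' Bundles a symmetric substitution matrix over the 20 amino acids plus 'X'
#' with affine gap penalties. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`. 'X' scores 0 against everything so
#' masked residues are alignment-neutral.
#'
#' @param substitution 21 x 21 integer matrix with dimnames over
#'   `c(A..Y, X)`; default BLOSUM62 with the X row/column zeroed.
#' @param gap_open non-negative opening penalty (default 11).
#' @param gap_extend non-negative extension penalty (default 1), must not
#'   exceed `gap_open`.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = 11, gap_extend = 1) {
  if (is.null(substitution)) substitution <- blosum62x()
  stopifnot(is.matrix(substitution),
            nrow(substitution) == 21, ncol(substitution) == 21)
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  structure(list(substitution = substitution,
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

# BLOSUM62 restricted to the package alphabet, X scored 0 against all
blosum62x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62[AA20, AA20]
  M <- matrix(0L, 21, 21, dimnames = list(AA21, AA21))
  M[AA20, AA20] <- B
  M
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme: 21-letter substitution matrix, gap open",
      x$gap_open, "extend", x$gap_extend, "\n")
  invisible(x)
}

# cell score matrix for two encoded sequences
pair_score_matrix <- function(ai, bi, scheme) {
  S <- scheme$substitution
  S[cbind(rep(ai + 1L, times = length(bi)),
          rep(bi + 1L, each = length(ai)))] |>
    matrix(nrow = length(ai))
}
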