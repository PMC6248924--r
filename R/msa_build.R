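# normalise a collection of sequences to a named character vector
as_seqset <- function(records) {
  if (methods::is(records, "XStringSet")) {
    out <- toupper(as.character(records))
    names(out) <- names(records)
  } else if (is.character(records)) {
    out <- toupper(records)
  } else stop("records must be an AAStringSet or named character vector")
  if (is.null(names(out)) || any(!nzchar(names(out))))
    stop("every record needs a non-empty id")
  if (anyDuplicated(names(out)))
    stop("duplicate record id '", names(out)[duplicated(names(out))][1], "'")
  out
}

# residue counts per column of a character matrix profile (gaps uncounted)
profile_counts <- function(m) {
  C <- matrix(0, 21, ncol(m))
  for (a in seq_along(AA21)) C[a, ] <- colSums(m == AA21[a])
  C
}

# sum-of-pairs expected score between every column pair of two profiles;
# gaps score 0 against everything
profile_score_matrix <- function(Ca, Cb, na, nb, scheme) {
  (t(Ca) %*% scheme$substitution %*% Cb) / (na * nb)
}

merge_profiles <- function(pa, pb, scheme) {
  Ca <- profile_counts(pa$m); Cb <- profile_counts(pb$m)
  T <- profile_score_matrix(Ca, Cb, nrow(pa$m), nrow(pb$m), scheme)
  res <- cpp_align_matrix(T, scheme$gap_open, scheme$gap_extend, FALSE, 0L)
  na <- nrow(pa$m); nb <- nrow(pb$m)
  W <- length(res$a_idx)
  m <- matrix("-", na + nb, W)
  ka <- res$a_idx >= 0
  m[seq_len(na), which(ka)] <- pa$m[, res$a_idx[ka] + 1L, drop = FALSE]
  kb <- res$b_idx >= 0
  m[na + seq_len(nb), which(kb)] <- pb$m[, res$b_idx[kb] + 1L, drop = FALSE]
  list(ids = c(pa$ids, pb$ids), m = m)
}

#' Pairwise p-distance matrix from global alignments
#'
#' Fraction of mismatching residues over the aligned (gap-free) columns of
#' each affine-gap global alignment. Used as guide-tree distances and for
#' DE-copy trees.
#'
#' @param records sequences (>= 2).
#' @param scheme a [scoring_scheme()].
#' @return symmetric labelled matrix with zero diagonal.
#' @export
pairwise_pdistance <- function(records, scheme = scoring_scheme()) {
  seqs <- as_seqset(records)
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    al <- global_align(seqs[i], seqs[j], scheme)
    cols <- al$columns
    both <- !is.na(cols$query) & !is.na(cols$subject)
    p <- if (sum(both) == 0) 1
         else mean(chars[[i]][cols$query[both]] != chars[[j]][cols$subject[both]])
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Progressive multiple sequence alignment
#'
#' Aligns sequences progressively along an average-linkage guide tree built
#' from pairwise global-alignment p-distances; profiles are merged with an
#' affine-gap global aligner whose column score is the mean pairwise
#' substitution score (gaps score 0). Deterministic: no randomness, and row
#' order in the result equals input order.
#'
#' @param records an `AAStringSet` or named character vector (>= 2).
#' @param scheme a [scoring_scheme()].
#' @return a [flg_msa].
#' @export
progressive_msa <- function(records, scheme = scoring_scheme()) {
  seqs <- as_seqset(records)
  n <- length(seqs)
  if (n < 2) stop("progressive_msa needs at least 2 records")
  profs <- lapply(seq_len(n), function(i)
    list(ids = names(seqs)[i],
         m = matrix(strsplit(seqs[i], "")[[1]], nrow = 1)))
  if (n == 2) {
    merged <- merge_profiles(profs[[1]], profs[[2]], scheme)
  } else {
    D <- pairwise_pdistance(seqs, scheme)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    node <- vector("list", n - 1)
    for (k in seq_len(n - 1)) {
      pick <- function(x) if (x < 0) profs[[-x]] else node[[x]]
      node[[k]] <- merge_profiles(pick(hc$merge[k, 1]),
                                  pick(hc$merge[k, 2]), scheme)
    }
    merged <- node[[n - 1]]
  }
  ord <- match(names(seqs), merged$ids)
  flg_msa(merged$ids[ord],
          apply(merged$m[ord, , drop = FALSE], 1, paste, collapse = ""))
}

#' Remove gap-heavy alignment columns
#'
#' Drops every column whose gap fraction exceeds `max_gap_fraction` (the
#' occupancy trim applied before building core models and distance
#' matrices). The returned index map gives, for each kept column, its
#' original column number, so trimmed coordinates can be mapped back.
#'
#' @param msa a [flg_msa].
#' @param max_gap_fraction maximum tolerated gap fraction in (0, 1].
#' @return list with `msa` (trimmed [flg_msa]) and `kept_columns`
#'   (integer map trimmed -> original column).
#' @export
trim_gap_columns <- function(msa, max_gap_fraction = 0.5) {
  if (max_gap_fraction <= 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in (0, 1]")
  m <- as.matrix(msa)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= max_gap_fraction)
  if (length(keep) == 0) stop("trimming removed all columns")
  out <- flg_msa(msa$ids, apply(m[, keep, drop = FALSE], 1, paste,
                                collapse = ""))
  list(msa = out, kept_columns = keep)
}
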