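new_profile_hmm <- function(name, L, match_emissions, background,
                            tMM, tMI, tMD, tIM, tII, tDM, tDD,
                            r_loop = 350 / 351, match_cols = NULL,
                            calibration = NULL) {
  hmm <- structure(list(name = name, L = as.integer(L),
                        match_emissions = match_emissions,
                        insert_emissions = background,
                        background = background,
                        tMM = tMM, tMI = tMI, tMD = tMD,
                        tIM = tIM, tII = tII, tDM = tDM, tDD = tDD,
                        r_loop = r_loop, match_cols = match_cols,
                        calibration = calibration),
                   class = "profile_hmm")
  validate_profile_hmm(hmm)
  hmm
}

validate_profile_hmm <- function(hmm) {
  stopifnot(hmm$L >= 1, nrow(hmm$match_emissions) == hmm$L,
            ncol(hmm$match_emissions) == 20)
  if (any(hmm$match_emissions <= 0) || any(hmm$background <= 0))
    stop("all probabilities must be positive (pseudocounted)")
  if (any(abs(rowSums(hmm$match_emissions) - 1) > 1e-9))
    stop("match emission rows must sum to 1")
  if (abs(sum(hmm$background) - 1) > 1e-9)
    stop("background must sum to 1")
  if (hmm$L > 1) {
    trs <- cbind(hmm$tMM + hmm$tMI + hmm$tMD, hmm$tIM + hmm$tII,
                 hmm$tDM + hmm$tDD)
    if (any(abs(trs - 1) > 1e-9))
      stop("transition distributions must sum to 1")
  }
  invisible(hmm)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$name, "': ", x$L, " match states",
      if (!is.null(x$calibration)) ", calibrated" else "", "\n", sep = "")
  invisible(x)
}

# Henikoff position-based sequence weights, normalised to mean 1
henikoff_weights <- function(m) {
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- col[col != "-"]
    if (length(res) == 0) next
    tab <- table(res)
    r <- length(tab)
    nz <- col != "-"
    w[nz] <- w[nz] + 1 / (r * as.numeric(tab[col[nz]]))
  }
  if (all(w == 0)) w[] <- 1
  w / mean(w[w > 0])
}

#' Build a profile HMM from a multiple alignment
#'
#' Columns with gap fraction at most `match_column_rule` become match
#' states. Sequences are weighted by the Henikoff position-based scheme;
#' emissions mix the weighted counts with `background` at
#' `pseudocount_weight`, and transition counts get Laplace pseudocounts, so
#' every probability is strictly positive. Insert states emit the
#' background, so inserted residues are score-neutral.
#'
#' @param msa a [flg_msa].
#' @param match_column_rule maximum gap fraction for a match column
#'   (default 0.5).
#' @param pseudocount_weight total background pseudocount per emission row
#'   (default 1.0).
#' @param background length-20 residue frequency vector (default uniform).
#' @param name model name token.
#' @return a `profile_hmm`.
#' @export
build_hmm <- function(msa, match_column_rule = 0.5, pseudocount_weight = 1.0,
                      background = NULL, name = "model") {
  if (is.null(background)) background <- rep(1 / 20, 20)
  background <- background / sum(background)
  m <- as.matrix(msa)
  gapfrac <- colMeans(m == "-")
  mcols <- which(gapfrac <= match_column_rule)
  L <- length(mcols)
  if (L == 0) stop("no match columns under the match column rule")
  w <- henikoff_weights(m)

  me <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    col <- m[, mcols[k]]
    for (a in seq_along(AA20)) {
      sel <- col == AA20[a]
      if (any(sel)) me[k, a] <- sum(w[sel])
    }
  }
  me <- me + pseudocount_weight * matrix(background, L, 20, byrow = TRUE)
  me <- me / rowSums(me)

  # transition counts along each row's match/insert/delete path
  is_match <- logical(ncol(m)); is_match[mcols] <- TRUE
  cnt <- list(MM = numeric(L - 1), MI = numeric(L - 1), MD = numeric(L - 1),
              IM = numeric(L - 1), II = numeric(L - 1),
              DM = numeric(L - 1), DD = numeric(L - 1))
  if (L > 1) {
    for (r in seq_len(nrow(m))) {
      prev <- NULL # c(state, node): state in M/I/D
      k <- 0L
      for (j in seq_len(ncol(m))) {
        ch <- m[r, j]
        if (is_match[j]) {
          k <- k + 1L
          st <- if (ch == "-") "D" else "M"
          if (!is.null(prev) && prev[2] == k - 1L && k >= 2L) {
            key <- paste0(prev[1], st)
            if (key %in% names(cnt)) cnt[[key]][k - 1L] <-
                cnt[[key]][k - 1L] + w[r]
          }
          prev <- c(st, k)
        } else if (ch != "-") {
          if (!is.null(prev) && k >= 1L && k <= L - 1L) {
            key <- paste0(prev[1], "I")
            if (key %in% names(cnt)) cnt[[key]][k] <- cnt[[key]][k] + w[r]
          }
          prev <- c("I", k)
        }
      }
    }
  }
  norm3 <- function(a, b, d) {
    s <- a + b + d; list(a / s, b / s, d / s)
  }
  tM <- norm3(cnt$MM + 1, cnt$MI + 1, cnt$MD + 1)
  sI <- cnt$IM + 1 + cnt$II + 1
  sD <- cnt$DM + 1 + cnt$DD + 1
  new_profile_hmm(name = name, L = L, match_emissions = me,
                  background = background,
                  tMM = tM[[1]], tMI = tM[[2]], tMD = tM[[3]],
                  tIM = (cnt$IM + 1) / sI, tII = (cnt$II + 1) / sI,
                  tDM = (cnt$DM + 1) / sD, tDD = (cnt$DD + 1) / sD,
                  match_cols = mcols)
}

# log-space parameters for the C++ kernels (uniform local entry, uniform
# exit folded into the match transitions)
hmm_params <- function(hmm) {
  L <- hmm$L
  lodds <- matrix(0, L, 21)
  lodds[, 1:20] <- log(hmm$match_emissions /
                         matrix(hmm$background, L, 20, byrow = TRUE))
  p_end <- 1 / (L - seq_len(L) + 1) # uniform exit over remaining nodes
  keep <- 1 - p_end
  z <- if (L > 1) seq_len(L - 1) else integer(0)
  list(lodds = lodds,
       lnBM = rep(log(1 / L), L),
       lnNB = log(1 - hmm$r_loop),
       lME = log(p_end),
       lMM = log(hmm$tMM * keep[z]), lMI = log(hmm$tMI * keep[z]),
       lMD = log(hmm$tMD * keep[z]),
       lIM = log(hmm$tIM), lII = log(hmm$tII),
       lDM = log(hmm$tDM), lDD = log(hmm$tDD),
       ln_r = log(hmm$r_loop))
}

#' Forward log-odds score of a sequence under a profile HMM
#'
#' log2 of P(sequence | model, uni-hit local mode) over P(sequence |
#' background null), summed over all state paths in log space.
#'
#' @param hmm a `profile_hmm`.
#' @param s a sequence.
#' @return bit score (finite scalar).
#' @export
forward_score <- function(hmm, s) {
  p <- hmm_params(hmm)
  xi <- encode_seq(as_residues(s))
  cpp_phmm_forward(xi, p$lodds, p$lnBM, p$lnNB, p$lME, p$lMM, p$lMI, p$lMD,
                   p$lIM, p$lII, p$lDM, p$lDD, p$ln_r)
}

#' Viterbi decoding: best state path and hit envelope
#'
#' Returns the single best local state path (ties broken M > D > I) with
#' its bit score and the 1-based residue interval emitted by core
#' match/insert states — the "hit" the scanner reports.
#'
#' @inheritParams forward_score
#' @return list with `bits`, `start`, `end`, `node_start`, `node_end` and a
#'   `path` data frame (state M/I/D, model node, sequence position).
#' @export
viterbi_decode <- function(hmm, s) {
  p <- hmm_params(hmm)
  xi <- encode_seq(as_residues(s))
  r <- cpp_phmm_viterbi(xi, p$lodds, p$lnBM, p$lnNB, p$lME, p$lMM, p$lMI,
                        p$lMD, p$lIM, p$lII, p$lDM, p$lDD, p$ln_r)
  list(bits = r$bits, start = r$start, end = r$end,
       node_start = r$node_start, node_end = r$node_end,
       path = data.frame(state = c("M", "I", "D")[r$path_state],
                         node = r$path_node,
                         pos = ifelse(r$path_pos == 0, NA_integer_,
                                      r$path_pos)))
}

#' Calibrate E-values from a shuffled-sequence null
#'
#' Fits a Gumbel (EVD) by the method of moments to forward bit scores of
#' residue-shuffled database sequences; E-value of a hit with score b is
#' then `n_db * P(score >= b)` under the fit. Reproducible given `seed`.
#'
#' @param hmm a `profile_hmm`.
#' @param records the database the model will be scanned against.
#' @param n_shuffles number of shuffles (>= 100).
#' @param seed RNG seed.
#' @param max_len shuffled sequences longer than this are truncated; keeps
#'   calibration cost bounded for giant sequences.
#' @return the hmm with `$calibration` set (`mu`, `beta`, `n_db`).
#' @export
calibrate_evalues <- function(hmm, records, n_shuffles = 100, seed = 1,
                              max_len = 400) {
  if (n_shuffles < 100) stop("n_shuffles must be >= 100")
  seqs <- as_seqset(records)
  set.seed(seed)
  idx <- rep_len(seq_along(seqs), n_shuffles)
  scores <- vapply(idx, function(i) {
    v <- strsplit(seqs[i], "")[[1]]
    v <- sample(v)
    if (length(v) > max_len) v <- v[seq_len(max_len)]
    forward_score(hmm, paste(v, collapse = ""))
  }, numeric(1))
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-8) stop("degenerate null score variance")
  beta <- s * sqrt(6) / pi
  mu <- mean(scores) - 0.57721566490153286 * beta
  hmm$calibration <- list(mu = mu, beta = beta, n_db = length(seqs))
  hmm
}

#' E-value of a bit score under a calibrated model
#' @param hmm calibrated `profile_hmm`.
#' @param bits bit score(s).
#' @return E-value(s), monotone decreasing in `bits`.
#' @export
hmm_evalue <- function(hmm, bits) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("model is not calibrated; run calibrate_evalues()")
  cal$n_db * (-expm1(-exp(-(bits - cal$mu) / cal$beta)))
}

#' Scan sequences for non-overlapping domain hits
#'
#' Greedy iterative decoding per sequence: decode the best remaining hit
#' (Viterbi envelope and bit score), mask it with 'X' (score-neutral) and
#' repeat until the next hit's E-value exceeds `evalue_threshold`. The
#' Viterbi score is the score of the single best hit, which is exactly
#' what the greedy stopping rule must test once earlier hits are masked.
#' Hits are reported in sequence order with 1-based closed intervals.
#'
#' @param hmm calibrated `profile_hmm`.
#' @param records database sequences.
#' @param evalue_threshold significance threshold (default 0.1).
#' @param max_hits per-sequence cap on reported hits.
#' @param min_hit_len envelopes shorter than this stop the iteration.
#' @return data.frame with columns id, start, end, bits, evalue.
#' @export
scan_hmm <- function(hmm, records, evalue_threshold = 0.1, max_hits = 10,
                     min_hit_len = 10) {
  seqs <- as_seqset(records)
  out <- list()
  for (id in names(seqs)) {
    v <- strsplit(seqs[[id]], "")[[1]]
    taken <- integer(0)
    for (h in seq_len(max_hits)) {
      s <- paste(v, collapse = "")
      vit <- viterbi_decode(hmm, s)
      bits <- vit$bits
      ev <- hmm_evalue(hmm, bits)
      if (!is.finite(bits) || ev > evalue_threshold) break
      if (is.na(vit$start) || vit$end - vit$start + 1 < min_hit_len) break
      span <- vit$start:vit$end
      if (any(span %in% taken)) break
      out[[length(out) + 1]] <- data.frame(
        id = id, start = vit$start, end = vit$end, bits = bits, evalue = ev)
      taken <- c(taken, span)
      v[span] <- "X"
    }
  }
  if (length(out) == 0)
    return(data.frame(id = character(0), start = integer(0),
                      end = integer(0), bits = numeric(0),
                      evalue = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(match(res$id, names(seqs)), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
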