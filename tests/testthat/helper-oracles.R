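# Independent brute-force oracles. These deliberately avoid the package's
# dynamic-programming code paths: alignments are enumerated as explicit
# index pairings, HMM scores as explicit state paths.

# All gapped alignments of a and b enumerated as strictly increasing index
# vectors; affine gap runs between consecutive columns (and, for global
# mode, at the unaligned ends) cost open + (len-1) * extend.
oracle_align_score <- function(a, b, scheme, local = TRUE) {
  av <- strsplit(toupper(a), "")[[1]]; bv <- strsplit(toupper(b), "")[[1]]
  S <- scheme$substitution
  go <- scheme$gap_open; ge <- scheme$gap_extend
  n <- length(av); m <- length(bv)
  gapcost <- function(k) if (k <= 0) 0 else go + (k - 1) * ge
  best <- if (local) 0 else -(gapcost(n) + gapcost(m)) # empty alignment
  subsets <- function(v, k) if (k == 0) list(integer(0)) else
    utils::combn(v, k, simplify = FALSE)
  for (k in seq_len(min(n, m))) {
    for (i in subsets(seq_len(n), k)) for (j in subsets(seq_len(m), k)) {
      sc <- sum(S[cbind(av[i], bv[j])])
      sc <- sc - sum(vapply(diff(i) - 1L, gapcost, numeric(1))) -
        sum(vapply(diff(j) - 1L, gapcost, numeric(1)))
      if (!local)
        sc <- sc - gapcost(i[1] - 1L) - gapcost(n - i[k]) -
          gapcost(j[1] - 1L) - gapcost(m - j[k])
      if (sc > best) best <- sc
    }
  }
  best
}

# Explicit path enumeration for the uni-hit local profile HMM: DFS through
# N -> B -> {M,I,D} -> E -> C generating every complete path; each path's
# odds is the product of its transitions and match emission odds over the
# null transition mass. mode "sum" = forward bits, "max" = Viterbi bits.
#
# State convention inside core(): `pos` is the index of the residue the
# state consumes on arrival (M, I) or the next residue to be consumed (D).
oracle_phmm_bits <- function(hmm, s, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  x <- strsplit(toupper(s), "")[[1]]
  n <- length(x); L <- hmm$L
  r <- hmm$r_loop
  bg <- hmm$background
  aa20 <- colnames(hmm$match_emissions)
  eodds <- function(k, ch) {
    if (ch == "X") return(1)
    hmm$match_emissions[k, ch] / bg[match(ch, aa20)]
  }
  p_end <- 1 / (L - seq_len(L) + 1)
  acc <- new.env(); acc$vals <- numeric(0)
  finish <- function(emitted, w) { # E reached; C flank emits the rest
    rest <- n - emitted
    if (rest < 0 || w == 0) return()
    acc$vals <- c(acc$vals, w * r^rest * (1 - r))
  }
  core <- function(state, k, pos, w) {
    if (w == 0) return()
    if (state == "M") {
      if (pos > n) return()
      w <- w * eodds(k, x[pos])
      finish(pos, w * p_end[k])
      if (k < L) {
        core("M", k + 1, pos + 1, w * hmm$tMM[k] * (1 - p_end[k]))
        core("I", k, pos + 1, w * hmm$tMI[k] * (1 - p_end[k]))
        core("D", k + 1, pos + 1, w * hmm$tMD[k] * (1 - p_end[k]))
      }
    } else if (state == "I") {
      if (pos > n) return()
      core("M", k + 1, pos + 1, w * hmm$tIM[k])
      core("I", k, pos + 1, w * hmm$tII[k])
    } else { # D: consumes nothing
      if (k == L) { finish(pos - 1, w); return() }
      core("M", k + 1, pos, w * hmm$tDM[k])
      core("D", k + 1, pos, w * hmm$tDD[k])
    }
  }
  if (n >= 1) for (f1 in 0:(n - 1)) {
    w0 <- r^f1 * (1 - r) # N self-loops, then N -> B
    for (k in seq_len(L)) core("M", k, f1 + 1, w0 / L)
  }
  if (length(acc$vals) == 0) return(-Inf)
  odds <- acc$vals / (r^n * (1 - r))
  if (mode == "sum") log2(sum(odds)) else log2(max(odds))
}

# total probability that the model emits exactly n residues (emissions
# marginalised out), by the same explicit path enumeration
oracle_phmm_length_mass <- function(hmm, n) {
  L <- hmm$L; r <- hmm$r_loop
  p_end <- 1 / (L - seq_len(L) + 1)
  total <- new.env(); total$p <- 0
  finish <- function(emitted, w) {
    rest <- n - emitted
    if (rest < 0) return()
    total$p <- total$p + w * r^rest * (1 - r)
  }
  core <- function(state, k, consumed, w) {
    if (w < 1e-300) return()
    if (state == "M") {
      if (consumed + 1 > n) return()
      consumed <- consumed + 1
      finish(consumed, w * p_end[k])
      if (k < L) {
        core("M", k + 1, consumed, w * hmm$tMM[k] * (1 - p_end[k]))
        core("I", k, consumed, w * hmm$tMI[k] * (1 - p_end[k]))
        core("D", k + 1, consumed, w * hmm$tMD[k] * (1 - p_end[k]))
      }
    } else if (state == "I") {
      if (consumed + 1 > n) return()
      consumed <- consumed + 1
      core("M", k + 1, consumed, w * hmm$tIM[k])
      core("I", k, consumed, w * hmm$tII[k])
    } else {
      if (k == L) { finish(consumed, w); return() }
      core("M", k + 1, consumed, w * hmm$tDM[k])
      core("D", k + 1, consumed, w * hmm$tDD[k])
    }
  }
  if (n >= 1) for (f1 in 0:(n - 1)) {
    w0 <- r^f1 * (1 - r)
    for (k in seq_len(L)) core("M", k, f1, w0 / L)
  }
  total$p
}

# brute-force Robinson-Foulds: cut every internal edge and flood each side
oracle_rf <- function(ta, tb) {
  splits <- function(tree) {
    tr <- ape::unroot(tree)
    labs <- tr$tip.label
    ntip <- length(labs)
    adj <- split(c(tr$edge[, 2], tr$edge[, 1]),
                 c(tr$edge[, 1], tr$edge[, 2]))
    out <- character(0)
    for (e in seq_len(nrow(tr$edge))) {
      a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
      if (b <= ntip) next
      seen <- b; queue <- b
      while (length(queue)) {
        nd <- queue[1]; queue <- queue[-1]
        for (nb in adj[[as.character(nd)]]) {
          if (nd == b && nb == a) next # do not cross the cut edge
          if (!(nb %in% seen)) { seen <- c(seen, nb); queue <- c(queue, nb) }
        }
      }
      side <- labs[seen[seen <= ntip]]
      if (length(side) <= 1 || length(side) >= ntip - 1) next
      if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
      out <- c(out, paste(sort(side), collapse = "|"))
    }
    unique(out)
  }
  sa <- splits(ta); sb <- splits(tb)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

# random residue string over a reduced alphabet
rand_seq <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
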