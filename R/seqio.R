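#' Read protein sequences from FASTA
#'
#' Wraps [Biostrings::readAAStringSet()] with the validation this pipeline
#' relies on: ids (header up to the first whitespace) must be unique and
#' non-empty, residues are upcased and must come from the 20-letter amino
#' acid alphabet plus 'X'. Other ambiguity codes are rejected so downstream
#' dynamic programming stays well defined.
#'
#' @param path path to a FASTA file (wrapped or single-line records).
#' @return an [Biostrings::AAStringSet] named by id, with the remainder of
#'   each header in `mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("FASTA format error: empty file ", path)
  badline <- illegal_residue_line(path)
  if (!is.na(badline))
    stop("illegal residue character near line ", badline, " of ", path)
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e)
                  stop("FASTA format error in ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  if (length(x) == 0) stop("FASTA format error: no records in ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (any(!nzchar(ids))) stop("FASTA format error: empty id in ", path)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate sequence id '", dup, "' in ", path)
  }
  seqs <- toupper(as.character(x))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# locate the first file line carrying a residue outside the alphabet
illegal_residue_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pat <- paste0("[^", paste(AA21, collapse = ""), "[:space:]]")
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    if (grepl(pat, toupper(lines[i]))) return(i)
  }
  NA_integer_
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param x an `AAStringSet` (or named character vector) of sequences.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  desc <- S4Vectors::mcols(x)$description
  nm <- names(x)
  if (!is.null(desc) && any(nzchar(desc)))
    names(x) <- ifelse(nzchar(desc), paste(nm, desc), nm)
  Biostrings::writeXStringSet(x, filepath = path, width = 60)
  names(x) <- nm
  invisible(path)
}

#' Multiple alignment container
#'
#' A light container for a gapped protein alignment: unique row ids and
#' equal-length gapped rows over the package alphabet plus '-'.
#'
#' @param ids character vector of unique row ids.
#' @param rows character vector of gapped sequences, same length as `ids`.
#' @return object of class `flg_msa`.
#' @export
flg_msa <- function(ids, rows) {
  ids <- unname(ids)
  rows <- unname(toupper(rows))
  if (length(ids) != length(rows)) stop("ids and rows differ in length")
  if (length(rows) < 2) stop("an alignment needs at least 2 rows")
  if (anyDuplicated(ids)) stop("duplicate row id '", ids[duplicated(ids)][1], "'")
  w <- unique(nchar(rows))
  if (length(w) != 1) {
    off <- ids[which(nchar(rows) != nchar(rows)[1])[1]]
    stop("ragged alignment: row '", off, "' has a different length")
  }
  bad <- grepl(paste0("[^-", paste(AA21, collapse = ""), "]"), rows)
  if (any(bad)) stop("illegal character in alignment row '", ids[which(bad)[1]], "'")
  ung <- gsub("-", "", rows, fixed = TRUE)
  if (any(!nzchar(ung)))
    stop("row '", ids[which(!nzchar(ung))[1]], "' is all gaps")
  structure(list(ids = ids, rows = rows, width = w), class = "flg_msa")
}

#' @export
print.flg_msa <- function(x, ...) {
  cat("flg_msa:", length(x$ids), "rows x", x$width, "columns\n")
  invisible(x)
}

#' @export
as.matrix.flg_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, ""))
  rownames(m) <- x$ids
  m
}

#' Read a multiple alignment
#'
#' `aligned-fasta` is FASTA whose records carry '-' gaps; `clustal` is the
#' ClustalX/Clustal W interleaved dialect (conservation lines are ignored,
#' blocks are concatenated per id), parsed via [seqinr::read.alignment()].
#'
#' @param path input file.
#' @param dialect `"aligned-fasta"` or `"clustal"`.
#' @return a [flg_msa].
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "aligned-fasta") {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^>", lines)
    if (length(hdr) < 2) stop("alignment needs at least 2 rows: ", path)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    to <- c(hdr[-1] - 1L, length(lines))
    rows <- vapply(seq_along(hdr), function(i) {
      paste(lines[seq(hdr[i] + 1L, to[i])], collapse = "")
    }, character(1))
    rows <- gsub("[[:space:]]", "", rows)
  } else {
    aln <- seqinr::read.alignment(path, format = "clustal")
    ids <- aln$nam
    rows <- toupper(unlist(aln$seq))
  }
  flg_msa(ids, rows)
}

#' Write a multiple alignment as aligned FASTA
#' @param msa a [flg_msa].
#' @param path output path.
#' @export
write_alignment <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(msa$ids)) {
    writeLines(paste0(">", msa$ids[i]), con)
    row <- msa$rows[i]
    starts <- seq(1, nchar(row), by = 60)
    writeLines(substring(row, starts, pmin(starts + 59, nchar(row))), con)
  }
  invisible(path)
}

#' Ungap alignment rows
#' @param msa a [flg_msa].
#' @return named character vector of ungapped sequences.
#' @export
msa_ungap <- function(msa) {
  setNames(gsub("-", "", msa$rows, fixed = TRUE), msa$ids)
}

#' Read a Newick tree
#'
#' Accepts either a Newick string or a file path; parentheses are balance
#' checked first so malformed input fails with the offending position.
#'
#' @param x Newick text (contains "(") or a path.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  txt <- if (grepl("\\(", x)) x else paste(readLines(x, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0) stop("Newick parse error: unbalanced ')' at position ", i)
  }
  if (depth != 0) stop("Newick parse error: ", depth, " unclosed '(' at end of input")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error in input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label '", tr$tip.label[duplicated(tr$tip.label)][1], "'")
  tr
}

#' Write a tree as Newick text
#' @param tree an [ape::phylo] tree.
#' @param path optional output file.
#' @return the Newick string, invisibly if written to `path`.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Serialize a profile HMM to plain text
#'
#' Key-value header (name, length, background, flank loop probability,
#' calibration if present) followed by per-node emission and transition
#' probability rows. [read_hmm()] restores the object exactly.
#'
#' @param hmm a `profile_hmm`.
#' @param path output file.
#' @export
write_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, digits = 17, format = "g"), collapse = " ")
  writeLines(c("FLAGELLARCH_HMM 1",
               paste("NAME", hmm$name),
               paste("LENG", hmm$L),
               paste("ALPH", paste(AA20, collapse = "")),
               paste("RLOOP", num(hmm$r_loop)),
               paste("BG", num(hmm$background))), con)
  if (!is.null(hmm$calibration))
    writeLines(paste("CALIB", num(c(hmm$calibration$mu, hmm$calibration$beta,
                                    hmm$calibration$n_db))), con)
  for (k in seq_len(hmm$L)) {
    writeLines(paste("MATCH", k, num(hmm$match_emissions[k, ])), con)
  }
  tr <- cbind(hmm$tMM, hmm$tMI, hmm$tMD, hmm$tIM, hmm$tII, hmm$tDM, hmm$tDD)
  if (hmm$L > 1) for (k in seq_len(hmm$L - 1)) {
    writeLines(paste("TRANS", k, num(tr[k, ])), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a profile HMM written by [write_hmm()]
#' @param path input file.
#' @return a `profile_hmm`.
#' @export
read_hmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "FLAGELLARCH_HMM"))
    stop("not a flagellarch HMM file: ", path)
  kv <- strsplit(lines, "[[:space:]]+")
  key <- vapply(kv, `[`, character(1), 1)
  getv <- function(k) as.numeric(kv[[which(key == k)[1]]][-1])
  L <- as.integer(getv("LENG"))
  me <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA20))
  for (i in which(key == "MATCH")) {
    v <- as.numeric(kv[[i]][-1]); me[as.integer(v[1]), ] <- v[-1]
  }
  tMM <- tMI <- tMD <- tIM <- tII <- tDM <- tDD <- numeric(max(L - 1, 0))
  for (i in which(key == "TRANS")) {
    v <- as.numeric(kv[[i]][-1]); k <- as.integer(v[1])
    tMM[k] <- v[2]; tMI[k] <- v[3]; tMD[k] <- v[4]
    tIM[k] <- v[5]; tII[k] <- v[6]; tDM[k] <- v[7]; tDD[k] <- v[8]
  }
  hmm <- new_profile_hmm(name = kv[[which(key == "NAME")[1]]][2], L = L,
                         match_emissions = me, background = getv("BG"),
                         tMM = tMM, tMI = tMI, tMD = tMD, tIM = tIM,
                         tII = tII, tDM = tDM, tDD = tDD,
                         r_loop = getv("RLOOP"))
  if (any(key == "CALIB")) {
    v <- getv("CALIB")
    hmm$calibration <- list(mu = v[1], beta = v[2], n_db = v[3])
  }
  hmm
}

# shared TSV writer: tab-separated, no quoting, with header
write_tsv0 <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
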