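#' Configuration for the synthetic flagellin generator
#'
#' Defines the evolutionary scenario the generator emulates: conserved
#' N-/C-terminal cores (the D0/D1 regions), a hypervariable central insert
#' that may carry 0, 1 or 2 tandem DE copies and an optional glycine-rich
#' DX insert between them, evolved along a known tree. Identical configs
#' generate byte-identical output.
#'
#' @param seed integer RNG seed.
#' @param n_taxa number of leaves.
#' @param tree_shape `"yule"` (birth-death simulation) or `"balanced"`.
#' @param divergence expected substitutions per site from root to tip.
#' @param core_n_length,core_c_length core segment lengths (aa).
#' @param plain_insert_length central insert of DE-free (canonical)
#'   leaves (aa).
#' @param de_length DE repeat unit length (aa).
#' @param dx_length DX insert length including the glycine region (aa).
#' @param dx_gly_length,dx_gly_fraction glycine-rich region length and its
#'   glycine frequency.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_mean_len mean indel length (geometric).
#' @param insert_model one of `"none"`, `"single_DE"`, `"tandem_DE"`,
#'   `"tandem_DE_plus_DX"`, either a single value for all leaves or a
#'   vector of length `n_taxa` (leaf order t1..tn).
#' @param decoy_length,shared_block FlgL-like decoy total length and the
#'   N-terminal block shared with flagellins (emulating the common
#'   pf00669 helical region).
#' @param background length-20 residue frequencies (default uniform).
#' @param ancestor_seed seed for the ancestral family segments (defaults
#'   to `seed`). Two configs sharing `ancestor_seed` but differing in
#'   `seed` draw fresh, independently evolved sequences from the same
#'   family — the train/test split used for classifier benchmarks.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_taxa = 8,
                             tree_shape = c("yule", "balanced"),
                             divergence = 0.1,
                             core_n_length = 180, core_c_length = 180,
                             plain_insert_length = 135,
                             de_length = 150, dx_length = 120,
                             dx_gly_length = 35, dx_gly_fraction = 0.6,
                             indel_rate = 0.005, indel_mean_len = 3,
                             insert_model = "tandem_DE_plus_DX",
                             decoy_length = 470, shared_block = 60,
                             background = NULL, ancestor_seed = NULL) {
  if (is.null(ancestor_seed)) ancestor_seed <- seed
  tree_shape <- match.arg(tree_shape)
  if (is.null(background)) background <- rep(1 / 20, 20)
  background <- background / sum(background)
  lens <- c(core_n_length, core_c_length, plain_insert_length, de_length,
            dx_length, dx_gly_length, decoy_length, shared_block)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (dx_gly_length >= dx_length)
    stop("dx_gly_length must be smaller than dx_length")
  if (divergence < 0) stop("divergence must be >= 0")
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  models <- c("none", "single_DE", "tandem_DE", "tandem_DE_plus_DX")
  if (!all(insert_model %in% models))
    stop("unknown insert_model: ",
         paste(setdiff(insert_model, models), collapse = ", "))
  if (!length(insert_model) %in% c(1L, n_taxa))
    stop("insert_model must have length 1 or n_taxa")
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 tree_shape = tree_shape, divergence = divergence,
                 core_n_length = core_n_length,
                 core_c_length = core_c_length,
                 plain_insert_length = plain_insert_length,
                 de_length = de_length, dx_length = dx_length,
                 dx_gly_length = dx_gly_length,
                 dx_gly_fraction = dx_gly_fraction,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 insert_model = insert_model,
                 decoy_length = decoy_length, shared_block = shared_block,
                 background = background,
                 ancestor_seed = as.integer(ancestor_seed)),
            class = "synthetic_config")
}

#' Canonical flagellin preset (~495 aa, FliC-like geometry)
#' @param ... overrides passed to [synthetic_config()].
#' @export
canonical_preset <- function(...) {
  args <- modifyList(list(insert_model = "none", plain_insert_length = 135),
                     list(...))
  do.call(synthetic_config, args)
}

#' Giant-flagellin preset (tandem DE + DX, ~1,020 aa leaves)
#' @param ... overrides passed to [synthetic_config()].
#' @export
oceanospirillales_preset <- function(...) {
  args <- modifyList(list(insert_model = "tandem_DE_plus_DX",
                          de_length = 260, dx_length = 140), list(...))
  do.call(synthetic_config, args)
}

draw_bg <- function(n, config) sample(AA20, n, replace = TRUE,
                                      prob = config$background)

# ancestral segments; deterministic in config$seed and shared with the
# decoy generator so both families carry the same N-terminal block
ancestral_segments <- function(config) {
  set.seed(config$ancestor_seed)
  gly_n <- config$dx_gly_length
  pre_n <- (config$dx_length - gly_n) %/% 2
  post_n <- config$dx_length - gly_n - pre_n
  gly <- ifelse(runif(gly_n) < config$dx_gly_fraction, "G",
                draw_bg(gly_n, config))
  list(ncore = draw_bg(config$core_n_length, config),
       ccore = draw_bg(config$core_c_length, config),
       insert = draw_bg(config$plain_insert_length, config),
       de = draw_bg(config$de_length, config),
       dx_pre = draw_bg(max(pre_n, 1), config),
       gly = gly,
       dx_post = draw_bg(max(post_n, 1), config),
       decoy_rest = draw_bg(max(config$decoy_length - config$shared_block, 1),
                            config))
}

make_balanced_tree <- function(n) {
  lab <- paste0("t", seq_len(n))
  build <- function(v) {
    if (length(v) == 1) return(v)
    h <- ceiling(length(v) / 2)
    paste0("(", build(v[1:h]), ":1,", build(v[(h + 1):length(v)]), ":1)")
  }
  ape::read.tree(text = paste0(build(lab), ";"))
}

sim_tree <- function(config) {
  tr <- if (config$tree_shape == "balanced") make_balanced_tree(config$n_taxa)
        else ape::rphylo(config$n_taxa, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(config$n_taxa))
  depth <- ape::node.depth.edgelength(tr)[seq_len(config$n_taxa)]
  md <- mean(depth)
  tr$edge.length <- if (md > 0 && config$divergence > 0)
    tr$edge.length * config$divergence / md else tr$edge.length * 0
  tr
}

# one branch of evolution: substitutions then length-confined indels
mutate_branch <- function(v, t, config, min_len = 5) {
  n <- length(v)
  if (t > 0 && n > 0) {
    p <- 1 - exp(-t)
    hit <- which(runif(n) < p)
    if (length(hit) > 0) {
      for (i in hit) {
        v[i] <- sample(setdiff(AA20, v[i]), 1)
      }
    }
  }
  n_ev <- rpois(1, config$indel_rate * t * length(v))
  for (e in seq_len(n_ev)) {
    len <- rgeom(1, 1 / config$indel_mean_len) + 1L
    if (runif(1) < 0.5) { # insertion
      pos <- sample(0:length(v), 1)
      v <- append(v, draw_bg(len, config), after = pos)
    } else if (length(v) - len >= min_len) { # deletion, segment preserved
      pos <- sample(seq_len(length(v) - len + 1), 1)
      v <- v[-(pos:(pos + len - 1L))]
    }
  }
  v
}

# evolve one segment along the whole tree; returns per-node sequences
evolve_tree <- function(anc, tree, config) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- anc
  edges <- tree$edge[order(tree$edge[, 2]), , drop = FALSE]
  # preorder: parents always precede children in ape's post-reorder? walk
  # explicitly from the root
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  walk <- function(node) {
    for (e in kids[[as.character(node)]]) {
      ch <- tree$edge[e, 2]
      seqs[[ch]] <<- mutate_branch(seqs[[node]], tree$edge.length[e], config)
      if (ch > ntip) walk(ch)
    }
  }
  walk(root)
  seqs
}

# evolve from a given internal node downwards, starting from start_seq
evolve_subtree <- function(start_seq, tree, node, config) {
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[node]] <- start_seq
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  walk <- function(nd) {
    ke <- kids[[as.character(nd)]]
    if (is.null(ke)) return()
    for (e in ke) {
      ch <- tree$edge[e, 2]
      seqs[[ch]] <<- mutate_branch(seqs[[nd]], tree$edge.length[e], config)
      if (ch > ntip) walk(ch)
    }
  }
  walk(node)
  seqs
}

#' Generate a synthetic flagellin dataset with ground truth
#'
#' Draws ancestral core, insert, DE and DX segments from the background
#' frequencies (glycine-enriched inside the DX glycine region), evolves
#' each segment along the simulated tree by per-site substitutions and
#' geometric-length indels confined to their segment, duplicates the DE
#' segment at the most recent common ancestor of the tandem leaves, and
#' assembles each leaf according to its insert model. Ground truth tracks
#' every planted boundary through the indels.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_flagellins`: `records`
#'   (AAStringSet), `truth` (list: `intervals` data.frame with 1-based
#'   closed per-segment coordinates, `tree`, `models`, `config`).
#' @export
generate_flagellins <- function(config) {
  anc <- ancestral_segments(config)
  set.seed(config$seed + 1L)
  tree <- sim_tree(config)
  ntip <- config$n_taxa
  models <- rep_len(config$insert_model, ntip)
  names(models) <- tree$tip.label

  segs <- list()
  for (nm in c("ncore", "ccore", "insert", "dx_pre", "gly", "dx_post"))
    segs[[nm]] <- evolve_tree(anc[[nm]], tree, config)
  de_run <- evolve_tree(anc$de, tree, config)

  tandem <- which(models %in% c("tandem_DE", "tandem_DE_plus_DX"))
  de2_run <- NULL
  if (length(tandem) > 0) {
    dup_node <- if (length(tandem) >= 2)
      ape::getMRCA(tree, tree$tip.label[tandem])
    else tree$edge[tree$edge[, 2] == tandem, 1]
    de2_run <- evolve_subtree(de_run[[dup_node]], tree, dup_node, config)
  }

  seq_out <- character(ntip)
  rows <- list()
  for (i in seq_len(ntip)) {
    id <- tree$tip.label[i]
    model <- models[[id]]
    parts <- list(ncore = segs$ncore[[i]])
    if (model == "none") {
      parts$insert <- segs$insert[[i]]
    } else if (model == "single_DE") {
      parts$de1 <- de_run[[i]]
    } else if (model == "tandem_DE") {
      parts$de1 <- de_run[[i]]
      parts$de2 <- de2_run[[i]]
    } else {
      parts$de1 <- de_run[[i]]
      parts$dx_pre <- segs$dx_pre[[i]]
      parts$gly <- segs$gly[[i]]
      parts$dx_post <- segs$dx_post[[i]]
      parts$de2 <- de2_run[[i]]
    }
    parts$ccore <- segs$ccore[[i]]
    lens <- vapply(parts, length, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seq_out[i] <- paste(unlist(parts), collapse = "")
    df <- data.frame(id = id, segment = names(parts), start = starts,
                     end = ends)
    if (model == "tandem_DE_plus_DX") {
      dxs <- df$start[df$segment == "dx_pre"]
      dxe <- df$end[df$segment == "dx_post"]
      df <- rbind(df, data.frame(id = id, segment = "dx", start = dxs,
                                 end = dxe))
    }
    rows[[i]] <- df
  }
  intervals <- do.call(rbind, rows)
  rownames(intervals) <- NULL
  records <- Biostrings::AAStringSet(setNames(seq_out, tree$tip.label))
  S4Vectors::mcols(records)$description <- unname(models)
  structure(list(records = records,
                 truth = list(intervals = intervals, tree = tree,
                              models = models, config = config)),
            class = "synthetic_flagellins")
}

#' @export
print.synthetic_flagellins <- function(x, ...) {
  cat("synthetic_flagellins:", length(x$records), "leaves, models:",
      paste(unique(x$truth$models), collapse = ", "), "\n")
  invisible(x)
}

#' Generate FlgL-like decoy sequences
#'
#' Decoys share the flagellin N-terminal helical block (the pf00669
#' region both families carry) but are otherwise drawn from an
#' independent FlgL-like ancestor, then evolved independently to the
#' configured divergence.
#'
#' @param config a [synthetic_config()]; `divergence` sets how far each
#'   decoy drifts from the FlgL ancestor.
#' @param n number of decoys.
#' @return AAStringSet of decoys (`decoy1` ...), description "flgl_like".
#' @export
generate_decoys <- function(config, n) {
  anc <- ancestral_segments(config)
  set.seed(config$seed + 2L)
  ancestor <- c(anc$ncore[seq_len(min(config$shared_block,
                                      length(anc$ncore)))],
                anc$decoy_rest)
  out <- vapply(seq_len(n), function(i)
    paste(mutate_branch(ancestor, config$divergence, config), collapse = ""),
    character(1))
  rec <- Biostrings::AAStringSet(setNames(out, paste0("decoy", seq_len(n))))
  S4Vectors::mcols(rec)$description <- rep("flgl_like", n)
  rec
}
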