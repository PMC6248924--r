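# Shared synthetic fixtures, built once per test run and cached.
.fixture_cache <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, builder(), envir = .fixture_cache)
  .fixture_cache[[name]]
}

# canonical flagellin training set (FliC-like geometry) + its alignment
flagellin_training <- function() fixture("flagellin_training", function() {
  cfg <- canonical_preset(seed = 101, n_taxa = 6, divergence = 0.08)
  gen <- generate_flagellins(cfg)
  list(cfg = cfg, gen = gen, msa = progressive_msa(gen$records))
})

# FlgL-like decoy training set sharing the N-terminal helical block
flgl_training <- function() fixture("flgl_training", function() {
  cfg <- flagellin_training()$cfg
  dec <- generate_decoys(synthetic_config(
    seed = cfg$seed, n_taxa = cfg$n_taxa, divergence = 0.3,
    insert_model = "none"), 6)
  list(records = dec, msa = progressive_msa(dec))
})

family_hmms <- function() fixture("family_hmms", function() {
  list(flagellin = build_hmm(flagellin_training()$msa, name = "flagellin"),
       flgl = build_hmm(flgl_training()$msa, name = "flgl"))
})

core_hmms <- function() fixture("core_hmms", function() {
  trimmed <- trim_gap_columns(flagellin_training()$msa, 0.5)
  core_models(trimmed$msa, 180, 180)
})

# a tiny 2-match-state toy model with distinctive emissions, for the
# exhaustive path-enumeration checks
toy_hmm <- function(L = 2, seed = 7) {
  set.seed(seed)
  rows <- replicate(4, paste(sample(c("A", "C", "D", "E", "F", "G"),
                                    L, replace = TRUE),
                             collapse = ""))
  # duplicated residues per column make emissions informative
  msa <- flg_msa(paste0("r", 1:4), rows)
  build_hmm(msa, name = "toy")
}
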