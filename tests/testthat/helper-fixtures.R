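# Hand-built fixtures shared across test files. All data are constructed in
# code; nothing is read from disk except what the tests themselves write to
# tempdirs.

# 5-taxon taxonomy: root(1) -> clade(2) -> sp3, sp4 ; root -> sp5
toy_taxonomy <- function() {
  taxonomy(data.frame(
    tax_id = 1:5, parent_id = c(1L, 1L, 2L, 2L, 1L),
    name = c("root", "cladeA", "sp3", "sp4", "sp5"),
    rank = c("no rank", "clade", "species", "species", "species")))
}

# Minimal database with a nested OG pair and one in-paralog:
#   sp3 carries P3a and P3b (in-paralogs of each other w.r.t. P4/P5 is
#   deliberate: P3b pairs with P4 but not with P5).
toy_db <- function() {
  tx <- toy_taxonomy()
  proteins <- data.frame(
    protein_id = c("P3a", "P3b", "P4", "P5"),
    tax_id = c(3L, 3L, 4L, 5L),
    sequence = c("MKVLAAGHEW", "MKVLAAGHEW", "MKVLAAGHEW", "MKVMAAGHEW"),
    stringsAsFactors = FALSE)
  ogs <- data.frame(
    og_id = c("OG1@2", "OG1@1"), level = c(2L, 1L),
    description = c("toy family at cladeA", "toy family at root"),
    cog_categories = c("J", "J"), stringsAsFactors = FALSE)
  ogs$members <- list(c("P3a", "P3b", "P4"), c("P3a", "P3b", "P4", "P5"))
  orthologs <- data.frame(
    protein_a = c("P3a", "P3b", "P3a"),
    protein_b = c("P4", "P4", "P5"), stringsAsFactors = FALSE)
  annotations <- data.frame(
    protein_id = c("P3a", "P3b", "P4", "P5", "P3a", "P4"),
    source = c("GO", "GO", "GO", "GO", "name", "name"),
    stringsAsFactors = FALSE)
  annotations$terms <- list(c("GO:1", "GO:2"), c("GO:9"),
                            c("GO:2", "GO:3"), c("GO:1"),
                            "tufA", "tufA")
  ref_db(tx, proteins, ogs, orthologs, annotations)
}

# a tiny domain model: exact-match motif PSSM, +5 match / -2 mismatch
toy_model <- function(motif, model_id = "PF0001", clan_id = "CLX",
                      ga_frac = 0.6) {
  aa <- strsplit(motif, "", fixed = TRUE)[[1]]
  L <- length(aa)
  alphabet <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
  pssm <- matrix(-2L, L, 20L, dimnames = list(NULL, alphabet))
  pssm[cbind(seq_len(L), match(aa, alphabet))] <- 5L
  list(model_id = model_id, clan_id = clan_id, length = L, pssm = pssm,
       ga_threshold = ga_frac * 5 * L)
}

random_protein <- function(n) {
  alphabet <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_contig <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small benchmark used by several test files (cached per test run)
.small_bm_env <- new.env()
small_benchmark <- function(seed = 11L) {
  key <- as.character(seed)
  if (is.null(.small_bm_env[[key]]))
    .small_bm_env[[key]] <- emit_benchmark(sim_params(
      n_species = 8L, n_families = 12L, root_length = 120L, seed = seed))
  .small_bm_env[[key]]
}
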