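# Shared builders for small models and corpora used across test files.

tiny_seq_encoder <- function(seed = 1L, ...) {
  init_encoder(encoder_config("tiny", "sequence", ...), seed = seed)
}

tiny_str_encoder <- function(seed = 2L, ...) {
  init_encoder(encoder_config("tiny", "structure", ...), seed = seed)
}

# very small encoder for gradient-heavy tests
micro_seq_encoder <- function(seed = 1L) {
  init_encoder(encoder_config("custom", "sequence", n_layers = 2L,
                              embed_dim = 16L, ffn_dim = 24L, n_heads = 2L),
               seed = seed)
}

# a fast corpus: short proteins, few families
small_corpus <- function(seed = 5L, n_families = 4L, per = 6L,
                         lengths = c(30L, 60L)) {
  generate_proteins(synth_config(n_families = n_families,
                                 proteins_per_family = per,
                                 length_range = lengths, seed = seed))
}

embedding_matrix <- function(model, records, level = "protein", ...) {
  as.matrix(embed_records(model, records, level = level, ...)[, -1])
}

# minimal PDB text with three A-chain residues (one with altloc duplicates)
# and one B-chain residue; synthetic fixture built in code
write_mini_pdb <- function(path, occA = 0.60, occB = 0.40) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000  -1.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    sprintf("ATOM      4  CA ALYS A   3       7.600   0.000   0.000%6.2f  0.00           C", occA),
    sprintf("ATOM      5  CA BLYS A   3       7.700   0.000   0.000%6.2f  0.00           C", occB),
    "ATOM      6  CA  VAL B   1       1.000   2.000   3.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
  path
}

random_rotation <- function(seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}
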