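# Small in-code fixtures shared across test files.

# A tiny two-sample cohort with two shared programs and one private program
# per sample; cheap enough to regenerate wherever needed.
tiny_config <- function(seed = 11L, ...) {
  cohort_config(
    n_samples = 2, cells_per_sample = 150, n_genes = 400,
    n_shared_programs = 2, n_private_programs_per_sample = 1,
    genes_per_program = 25, seed = seed, ...
  )
}

# Deterministic dense matrix with dimnames for IO / scoring tests.
toy_matrix <- function(n_genes = 6, n_cells = 3, seed = 5L) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 8), n_genes, n_cells)
  dimnames(m) <- list(sprintf("g%d", seq_len(n_genes)),
                      sprintf("c%d", seq_len(n_cells)))
  m
}
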