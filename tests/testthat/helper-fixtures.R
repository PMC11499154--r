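# Shared fixtures, all built in code.
library(data.table)

# A small, fast configuration used by most pipeline-level tests.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_real_cells = 100L,
                   n_noise_barcodes = 400L, n_samples = 3L,
                   reads_per_real_cell = 400, reads_per_noise_barcode = 8,
                   n_clonotypes = 60L, dominant_clone_size = 10L,
                   umi_error_rate = 0.02, multiplet_rate = 0.02)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# The noiseless world: every stochastic corruption turned off.
clean_config <- function(seed = 1L, ...) {
  tiny_config(seed = seed, umi_error_rate = 0, multiplet_rate = 0,
              tag_noise_rate = 0, frac_cd8 = 1, ...)
}

# One (cell, feature) UMI group as a molecule table.
umi_group <- function(umis, reads, cell = "c1", feature = "G1") {
  n <- length(umis)
  as_molecule_table(data.frame(cell_label = rep(cell, n), umi = umis,
                               feature = rep(feature, n),
                               reads = as.integer(reads),
                               stringsAsFactors = FALSE))
}

# A deterministic counts-stage expression matrix.
make_gex <- function(values, sample_id = "S1", cells = NULL, genes = NULL,
                     stage = "counts") {
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(nrow(values)))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(values)))
  dimnames(values) <- list(cells, genes)
  gex_matrix(values, sample_id = sample_id, stage = stage)
}

# Re-tag a matrix as cpm-stage without normalizing (for transform tests).
cpm_stamp <- function(m) {
  gex_matrix(unclass(m), sample_id = attr(m, "sample_id"), stage = "cpm")
}

# Deterministic distinct DNA strings (base-4 encoding of 0..n-1).
random_dna_fixture <- function(n, len = 6L) {
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (p in len:1) {
      digits[p] <- i %% 4L
      i <- i %/% 4L
    }
    paste0(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
}

# Random UMI groups over a small alphabet so Hamming-1 pairs are common.
random_umi_group <- function(k, len = 4L) {
  repeat {
    umis <- unique(replicate(k, paste0(
      sample(c("A", "C", "G"), len, replace = TRUE), collapse = "")))
    if (length(umis) == k) break
  }
  list(umis = umis, reads = sample.int(20L, k, replace = TRUE))
}
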