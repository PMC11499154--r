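#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The defaults describe the demo world the pipeline is tested against:
#' roughly 5000 real cells carrying ~3000 clonotypes with a single planted
#' dominant clonotype of 14 cells, 99.9% CD8+CD4-FOXP3- cells, a clearly
#' bimodal barcode-rank curve (real cells receive ~100x the reads of noise
#' barcodes), and low-rate substitution errors on UMIs.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so identical configurations give byte-identical outputs.
#' @param n_real_cells Number of real cells.
#' @param n_noise_barcodes Number of noise (ambient/debris) barcodes.
#' @param n_samples Number of multiplexed samples (sample tags).
#' @param reads_per_real_cell Expected total reads per real cell.
#' @param reads_per_noise_barcode Expected total reads per noise barcode;
#'   must be smaller than `reads_per_real_cell`.
#' @param umi_length UMI length in bases over \{A,C,G,T\}.
#' @param umi_error_rate Per-molecule probability of spawning one
#'   substitution-error UMI at Hamming distance 1.
#' @param n_clonotypes Target number of planted clonotypes (cells left over
#'   after the planted sizes are exhausted become extra singleton
#'   clonotypes, so the realized number can differ slightly).
#' @param dominant_clone_size Cell count of the planted dominant clonotype;
#'   all other clone sizes are truncated at `dominant_clone_size - 2`, which
#'   guarantees a strictly unique dominant clonotype.
#' @param clone_size_power Exponent of the discrete power law the remaining
#'   clone sizes are drawn from.
#' @param frac_cd8 Fraction of cells planted as CD8+CD4-FOXP3-.
#' @param multiplet_rate Probability that a (non-dominant) cell is a
#'   multiplet carrying two sample tags.
#' @param tag_noise_rate Fraction of a singlet cell's sample-tag reads that
#'   land on non-winner tags.
#' @param panel_genes Targeted panel gene names; must contain "CD8", "CD4"
#'   and "FOXP3".
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_real_cells = 100, n_noise_barcodes = 900)
#' @export
sim_config <- function(seed = 42L,
                       n_real_cells = 5000L,
                       n_noise_barcodes = 5000L,
                       n_samples = 3L,
                       reads_per_real_cell = 2000,
                       reads_per_noise_barcode = 20,
                       umi_length = 8L,
                       umi_error_rate = 0.02,
                       n_clonotypes = 3000L,
                       dominant_clone_size = 14L,
                       clone_size_power = 2.2,
                       frac_cd8 = 0.999,
                       multiplet_rate = 0.02,
                       tag_noise_rate = 0.1,
                       panel_genes = default_panel_genes()) {
  cfg <- list(
    seed = as.integer(seed),
    n_real_cells = as.integer(n_real_cells),
    n_noise_barcodes = as.integer(n_noise_barcodes),
    n_samples = as.integer(n_samples),
    reads_per_real_cell = as.numeric(reads_per_real_cell),
    reads_per_noise_barcode = as.numeric(reads_per_noise_barcode),
    umi_length = as.integer(umi_length),
    umi_error_rate = as.numeric(umi_error_rate),
    n_clonotypes = as.integer(n_clonotypes),
    dominant_clone_size = as.integer(dominant_clone_size),
    clone_size_power = as.numeric(clone_size_power),
    frac_cd8 = as.numeric(frac_cd8),
    multiplet_rate = as.numeric(multiplet_rate),
    tag_noise_rate = as.numeric(tag_noise_rate),
    panel_genes = as.character(panel_genes)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default targeted gene panel
#'
#' A small immune panel containing the three gate markers plus common
#' T-cell genes. Only CD8/CD4/FOXP3 carry planted structure; the remaining
#' genes are overdispersed filler.
#' @return Character vector of gene names.
#' @export
default_panel_genes <- function() {
  c("CD8", "CD4", "FOXP3",
    "CD3E", "CD3D", "GZMB", "PRF1", "IFNG", "TNF", "IL2RA",
    "LAG3", "PDCD1", "CCL5", "NKG7", "KLRD1", "GNLY", "CST7",
    "HLA-A", "B2M", "ACTB")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, name, detail) {
    if (!isTRUE(ok)) stop_invariant(name, detail)
  }
  for (p in c("umi_error_rate", "frac_cd8", "multiplet_rate",
              "tag_noise_rate")) {
    chk(is.finite(cfg[[p]]) && cfg[[p]] >= 0 && cfg[[p]] <= 1,
        p, "must be a probability in [0, 1]")
  }
  chk(cfg$reads_per_real_cell > cfg$reads_per_noise_barcode,
      "reads_per_real_cell > reads_per_noise_barcode",
      sprintf("%g is not > %g", cfg$reads_per_real_cell,
              cfg$reads_per_noise_barcode))
  chk(cfg$reads_per_noise_barcode > 0, "reads_per_noise_barcode",
      "must be positive")
  chk(cfg$n_real_cells >= 1L, "n_real_cells", "must be >= 1")
  chk(cfg$n_noise_barcodes >= 0L, "n_noise_barcodes", "must be >= 0")
  chk(cfg$n_samples >= 2L, "n_samples", "need >= 2 samples to demultiplex")
  chk(cfg$umi_length >= 4L, "umi_length", "must be >= 4 bases")
  chk(cfg$n_clonotypes >= 1L, "n_clonotypes", "must be >= 1")
  chk(cfg$dominant_clone_size >= 3L,
      "dominant_clone_size >= max other clone sizes + 2",
      "dominant_clone_size must be >= 3 so smaller clones (size >= 1) exist")
  chk(cfg$dominant_clone_size <= cfg$n_real_cells, "dominant_clone_size",
      "cannot exceed n_real_cells")
  chk(cfg$clone_size_power > 1, "clone_size_power", "must be > 1")
  chk(all(c("CD8", "CD4", "FOXP3") %in% cfg$panel_genes), "panel_genes",
      "must include CD8, CD4 and FOXP3")
  chk(!anyDuplicated(cfg$panel_genes), "panel_genes",
      "gene names must be unique")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d real cells + %d noise barcodes, %d samples",
              x$n_real_cells, x$n_noise_barcodes, x$n_samples),
      sprintf("dominant clonotype of %d cells among ~%d clonotypes",
              x$dominant_clone_size, x$n_clonotypes),
      sprintf("seed %d", x$seed), sep = "\n  ")
  invisible(x)
}
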