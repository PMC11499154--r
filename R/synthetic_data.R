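#' Generate a molecule-level table with planted ground truth
#'
#' Emulates the substrate of a targeted single-cell run after read collapse:
#' one record per observed molecule, keyed by (cell label, UMI, feature,
#' reads). Features are panel genes plus sample tags (`SampleTagNN`). Each
#' true molecule may spawn one substitution-error UMI at Hamming distance 1
#' with probability `umi_error_rate`; error reads are carved out of the
#' parent so that read totals are conserved and the RSEC parent rule
#' (reads(parent) >= 2*reads(child) - 1) provably reattaches every error.
#' Noise barcodes receive read totals far below real cells, producing a
#' bimodal barcode-rank curve with a knee at rank `n_real_cells`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `molecules` (a `molecule_table`
#'   \link[data.table]{data.table} with columns cell_label, umi, feature,
#'   reads) and `truth` (a `ground_truth` list; see Details).
#'
#' @details The ground truth records: `real_cells`, `cell_to_sample` (sample
#'   id or `"multiplet"` for every real cell), `clonotype_of_cell`,
#'   `dominant_clonotype_id`, `true_affinity` (per clonotype, in \[0,1\];
#'   the dominant clonotype's affinity is planted in the medium range
#'   0.4-0.7), `cd8_pos`, `true_umi_parent` (observed UMI -> true UMI per
#'   cell and feature), `barcode_totals` (planted gene-read totals per
#'   barcode), `tag_totals` (planted sample-tag read totals),
#'   `multiplet_samples`, `tag_names` and `sample_ids`.
#' @export
generate_molecule_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101L))

  n_real <- config$n_real_cells
  n_noise <- config$n_noise_barcodes
  real_cells <- sprintf("cell_%06d", seq_len(n_real))
  noise_cells <- if (n_noise > 0L) sprintf("bg_%06d", seq_len(n_noise))
                 else character(0)
  sample_ids <- paste0("S", seq_len(config$n_samples))
  tag_names <- sprintf("SampleTag%02d", seq_len(config$n_samples))

  ## ---- planted clonotype structure -------------------------------------
  dom <- config$dominant_clone_size
  smax <- dom - 2L
  avail <- n_real - dom
  other_sizes <- integer(0)
  if (avail > 0L && config$n_clonotypes > 1L) {
    pr <- seq_len(smax)^(-config$clone_size_power)
    draw <- sample(seq_len(smax), config$n_clonotypes - 1L,
                   replace = TRUE, prob = pr)
    cs <- cumsum(draw)
    keep <- cs <= avail
    other_sizes <- draw[keep]
    left <- avail - sum(other_sizes)
    if (left > 0L) other_sizes <- c(other_sizes, rep(1L, left))
  } else if (avail > 0L) {
    other_sizes <- rep(1L, avail)
  }
  sizes <- c(dom, other_sizes)
  clono_ids <- sprintf("CT%06d", seq_along(sizes))
  dominant_id <- clono_ids[1L]
  clonotype_of_cell <- sample(rep(clono_ids, times = sizes))
  names(clonotype_of_cell) <- real_cells
  dom_cells <- real_cells[clonotype_of_cell == dominant_id]

  true_affinity <- stats::runif(length(clono_ids), 0.05, 0.95)
  names(true_affinity) <- clono_ids
  # the dominant clonotype gets a medium planted affinity
  true_affinity[dominant_id] <- stats::runif(1, 0.4, 0.7)

  ## ---- CD8 status; dominant cells are planted as effectors -------------
  cd8_pos <- stats::runif(n_real) < config$frac_cd8
  names(cd8_pos) <- real_cells
  cd8_pos[dom_cells] <- TRUE

  ## ---- sample-of-origin and multiplets (never in the dominant clone) ---
  cell_to_sample <- sample(sample_ids, n_real, replace = TRUE)
  names(cell_to_sample) <- real_cells
  non_dom <- setdiff(real_cells, dom_cells)
  is_mult <- non_dom[stats::runif(length(non_dom)) < config$multiplet_rate]
  multiplet_samples <- data.table(cell_label = character(0),
                                  sample_a = character(0),
                                  sample_b = character(0))
  if (length(is_mult)) {
    pairs <- t(vapply(is_mult, function(cl) sample(sample_ids, 2L),
                      character(2)))
    multiplet_samples <- data.table(cell_label = is_mult,
                                    sample_a = pairs[, 1L],
                                    sample_b = pairs[, 2L])
    cell_to_sample[is_mult] <- "multiplet"
  }

  ## ---- per-barcode read totals -----------------------------------------
  tot_real <- pmax(1, round(config$reads_per_real_cell *
                              exp(stats::rnorm(n_real, 0, 0.25))))
  tot_noise <- pmax(1, round(config$reads_per_noise_barcode *
                               exp(stats::rnorm(n_noise, 0, 0.5))))
  barcode_totals <- c(tot_real, tot_noise)
  names(barcode_totals) <- c(real_cells, noise_cells)

  ## ---- gene molecules ---------------------------------------------------
  gene_w <- stats::rexp(length(config$panel_genes)) + 0.1
  mol_gene <- make_molecules(
    labels = c(real_cells, noise_cells),
    totals = barcode_totals,
    mean_mol_reads = c(rep(40, n_real), rep(10, n_noise)),
    features = config$panel_genes, feature_prob = gene_w,
    umi_length = config$umi_length)

  ## ---- sample-tag molecules --------------------------------------------
  tag_tot <- pmax(20, round(0.05 * config$reads_per_real_cell))
  tag_counts <- tag_read_composition(
    real_cells, cell_to_sample, multiplet_samples, sample_ids, tag_names,
    tag_total = tag_tot, tag_noise_rate = config$tag_noise_rate)
  if (n_noise > 0L) {
    amb <- stats::rpois(n_noise, 2)
    keep <- amb > 0L
    if (any(keep)) {
      tag_counts <- rbind(tag_counts, data.table(
        cell_label = noise_cells[keep],
        feature = sample(tag_names, sum(keep), replace = TRUE),
        reads = amb[keep]))
    }
  }
  tag_counts <- tag_counts[reads > 0L]
  tag_totals_dt <- tag_counts[, .(reads = sum(reads)), by = cell_label]
  tag_totals <- stats::setNames(tag_totals_dt$reads,
                                tag_totals_dt$cell_label)
  mol_tag <- split_into_molecules(tag_counts, mean_mol_reads = 10,
                                  umi_length = config$umi_length)

  molecules <- rbind(mol_gene, mol_tag)
  # collapse accidental UMI collisions within a (cell, feature) group
  molecules <- molecules[, .(reads = sum(reads)),
                         by = .(cell_label, umi, feature)]

  ## ---- substitution-error UMIs -----------------------------------------
  parent_map <- molecules[, .(cell_label, feature, umi, parent_umi = umi)]
  if (config$umi_error_rate > 0) {
    cand <- which(molecules$reads >= 3L &
                    stats::runif(nrow(molecules)) < config$umi_error_rate)
    if (length(cand)) {
      par <- molecules[cand]
      # error reads <= floor(parent/3) keep the final parent at
      # >= 2 * child - 1 reads, so RSEC provably reattaches the error
      cap <- pmax(1L, par$reads %/% 3L)
      err_reads <- pmin(1L + as.integer(floor(stats::runif(length(cand)) *
                                                cap)), cap)
      pos <- sample.int(config$umi_length, length(cand), replace = TRUE)
      err <- data.table(cell_label = par$cell_label,
                        umi = mutate_base(par$umi, pos),
                        feature = par$feature, reads = err_reads,
                        parent_umi = par$umi, row = cand)
      # drop spawns colliding with an existing UMI or with another spawn
      hit <- molecules[err, on = .(cell_label, feature, umi), which = TRUE]
      err <- err[is.na(hit)]
      err <- unique(err, by = c("cell_label", "feature", "umi"))
      if (nrow(err)) {
        # carve the error reads out of the parents, append the error rows
        molecules[err$row, reads := reads - err$reads]
        molecules <- rbind(molecules,
                           err[, .(cell_label, umi, feature, reads)])
        parent_map <- rbind(parent_map,
                            err[, .(cell_label, feature, umi, parent_umi)])
      }
    }
  }

  setorder(molecules, cell_label, feature, umi)
  molecules <- new_molecule_table(molecules)

  truth <- structure(list(
    real_cells = real_cells,
    cell_to_sample = cell_to_sample,
    clonotype_of_cell = clonotype_of_cell,
    dominant_clonotype_id = dominant_id,
    true_affinity = true_affinity,
    cd8_pos = cd8_pos,
    true_umi_parent = parent_map,
    barcode_totals = barcode_totals,
    tag_totals = tag_totals,
    multiplet_samples = multiplet_samples,
    tag_names = tag_names,
    sample_ids = sample_ids,
    clone_sizes = stats::setNames(sizes, clono_ids)
  ), class = "ground_truth")

  list(molecules = molecules, truth = truth)
}

# Split per-barcode read totals into molecules with gamma-weighted sizes;
# totals are conserved exactly and every molecule has >= 1 read.
make_molecules <- function(labels, totals, mean_mol_reads, features,
                           feature_prob, umi_length) {
  tot <- as.integer(totals[labels])
  n_mol <- pmax(1L, pmin(stats::rpois(length(tot), tot / mean_mol_reads),
                         tot))
  dt <- data.table(cell_label = rep(labels, n_mol),
                   total = rep(tot, n_mol))
  dt[, w := stats::rgamma(.N, shape = 4)]
  dt[, reads := fix_counts(total[1L], w), by = cell_label]
  dt[, feature := sample(features, .N, replace = TRUE,
                         prob = feature_prob)]
  dt[, umi := random_dna(.N, umi_length)]
  dt[, .(cell_label, umi, feature, reads)]
}

# As make_molecules, but splitting per-(cell, feature) read counts.
split_into_molecules <- function(counts, mean_mol_reads, umi_length) {
  tot <- as.integer(counts$reads)
  n_mol <- pmax(1L, pmin(stats::rpois(length(tot), tot / mean_mol_reads),
                         tot))
  dt <- data.table(cell_label = rep(counts$cell_label, n_mol),
                   feature = rep(counts$feature, n_mol),
                   total = rep(tot, n_mol))
  dt[, w := stats::rgamma(.N, shape = 4)]
  dt[, grp := rleid(cell_label, feature)]
  dt[, reads := fix_counts(total[1L], w), by = grp]
  dt[, umi := random_dna(.N, umi_length)]
  dt[, .(cell_label, umi, feature, reads)]
}

# Integer partition of `total` proportional to weights w, each part >= 1.
fix_counts <- function(total, w) {
  m <- length(w)
  if (m == 1L) return(as.integer(total))
  r <- pmax(1L, as.integer(floor(total * w / sum(w))))
  d <- as.integer(total - sum(r))
  while (d != 0L) {
    if (d > 0L) {
      i <- which.max(w)
      r[i] <- r[i] + d
      d <- 0L
    } else {
      i <- which.max(r)
      take <- min(r[i] - 1L, -d)
      if (take == 0L) break
      r[i] <- r[i] - take
      d <- d + take
    }
  }
  r
}

# Per-(cell, tag) read counts: singlets put ~(1 - tag_noise_rate) of tag
# reads on the winner tag; multiplets put >= 40% on each of two tags.
tag_read_composition <- function(real_cells, cell_to_sample,
                                 multiplet_samples, sample_ids, tag_names,
                                 tag_total, tag_noise_rate) {
  k <- length(tag_names)
  tag_of_sample <- stats::setNames(tag_names, sample_ids)
  shares <- matrix(0, nrow = length(real_cells), ncol = k,
                   dimnames = list(real_cells, tag_names))
  singl <- names(cell_to_sample)[cell_to_sample != "multiplet"]
  if (length(singl)) {
    win <- tag_of_sample[cell_to_sample[singl]]
    off <- if (k > 1L) tag_noise_rate / (k - 1L) else 0
    shares[singl, ] <- off
    shares[cbind(singl, win)] <- 1 - tag_noise_rate
  }
  if (nrow(multiplet_samples)) {
    ml <- multiplet_samples$cell_label
    rest <- if (k > 2L) 0.1 / (k - 2L) else 0
    shares[ml, ] <- rest
    shares[cbind(ml, tag_of_sample[multiplet_samples$sample_a])] <- 0.45
    shares[cbind(ml, tag_of_sample[multiplet_samples$sample_b])] <- 0.45
  }
  reads <- round(shares * tag_total)
  data.table(cell_label = rep(real_cells, k),
             feature = rep(tag_names, each = length(real_cells)),
             reads = as.integer(reads))
}

# Substitute the base at position `pos` of each UMI with a different base.
mutate_base <- function(umi, pos) {
  old <- substr(umi, pos, pos)
  new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1L), character(1))
  out <- umi
  substr(out, pos, pos) <- new
  out
}

#' Generate a synthetic AIRR rearrangement table
#'
#' One productive TRA and one productive TRB row per real cell, with
#' identical (v_call, j_call, junction_aa, sequence_aa) within a clonotype
#' and distinct chains across clonotypes. V/J names are drawn from an
#' IMGT-style vocabulary (e.g. `"TRBV19*01"`); CDR3 junctions are 10-18
#' amino acids, C...F bounded. Optional chain dropout and low-count second
#' chains exercise the pairing rules; both default to 0, the clean contract
#' the planted ground truth is stated in.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_molecule_table()] under the same
#'   config.
#' @param chain_dropout Probability that a cell loses one random chain.
#' @param second_chain_rate Probability that a cell gains a second TRA row
#'   with duplicate_count 0 (below any primary chain).
#' @return An `airr_table` data.table with columns cell_id, locus, v_call,
#'   j_call, junction_aa, sequence_aa, duplicate_count, productive.
#' @export
generate_airr_table <- function(config, truth, chain_dropout = 0,
                                second_chain_rate = 0) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(derive_seed(config$seed, 202L))
  clono <- sort(unique(truth$clonotype_of_cell))
  nc <- length(clono)

  trav <- sprintf("TRAV%d*01", 1:41)
  traj <- sprintf("TRAJ%d*01", 1:56)
  trbv <- sprintf("TRBV%d*01", 1:30)
  trbj <- sprintf("TRBJ%d-%d*01", rep(1:2, each = 6), rep(1:6, 2))

  junc <- function(n) {
    out <- paste0("C", random_aa(sample(8:16, n, replace = TRUE)), "F")
    while (anyDuplicated(out)) {
      d <- which(duplicated(out))
      out[d] <- paste0("C", random_aa(sample(8:16, length(d),
                                             replace = TRUE)), "F")
    }
    out
  }
  ja <- junc(nc)
  jb <- junc(nc)
  chains <- data.table(
    clonotype_id = clono,
    tra_v = sample(trav, nc, replace = TRUE),
    tra_j = sample(traj, nc, replace = TRUE),
    tra_junction = ja,
    tra_seq = paste0(random_aa(rep(20L, nc)), ja, random_aa(rep(8L, nc))),
    trb_v = sample(trbv, nc, replace = TRUE),
    trb_j = sample(trbj, nc, replace = TRUE),
    trb_junction = jb,
    trb_seq = paste0(random_aa(rep(20L, nc)), jb, random_aa(rep(8L, nc))))

  cells <- truth$real_cells
  ct <- truth$clonotype_of_cell[cells]
  idx <- match(ct, chains$clonotype_id)
  n <- length(cells)
  rows <- rbind(
    data.table(cell_id = cells, locus = "TRA",
               v_call = chains$tra_v[idx], j_call = chains$tra_j[idx],
               junction_aa = chains$tra_junction[idx],
               sequence_aa = chains$tra_seq[idx],
               duplicate_count = 1L + stats::rpois(n, 3),
               productive = TRUE),
    data.table(cell_id = cells, locus = "TRB",
               v_call = chains$trb_v[idx], j_call = chains$trb_j[idx],
               junction_aa = chains$trb_junction[idx],
               sequence_aa = chains$trb_seq[idx],
               duplicate_count = 1L + stats::rpois(n, 3),
               productive = TRUE))

  if (chain_dropout > 0) {
    dropped <- cells[stats::runif(n) < chain_dropout]
    if (length(dropped)) {
      locus_drop <- sample(c("TRA", "TRB"), length(dropped), replace = TRUE)
      rows <- rows[!data.table(cell_id = dropped, locus = locus_drop),
                   on = .(cell_id, locus)]
    }
  }
  if (second_chain_rate > 0) {
    extra_cells <- cells[stats::runif(n) < second_chain_rate]
    if (length(extra_cells)) {
      other <- vapply(truth$clonotype_of_cell[extra_cells], function(ci) {
        sample(setdiff(chains$clonotype_id, ci), 1L)
      }, character(1))
      oi <- match(other, chains$clonotype_id)
      rows <- rbind(rows, data.table(
        cell_id = extra_cells, locus = "TRA",
        v_call = chains$tra_v[oi], j_call = chains$tra_j[oi],
        junction_aa = chains$tra_junction[oi],
        sequence_aa = chains$tra_seq[oi],
        duplicate_count = 0L, productive = TRUE))
    }
  }
  setorder(rows, cell_id, locus, -duplicate_count)
  as_airr_table(rows)
}

#' Generate synthetic per-sample gene-expression count matrices
#'
#' One cells-by-genes count matrix per sample. Planted CD8+ cells have
#' CD8 > 0 and CD4 = FOXP3 = 0; the remaining cells have CD8 = 0 and
#' CD4 > 0. All other panel genes follow an overdispersed
#' negative-binomial law. Multiplet cells are placed in the first of their
#' two samples (the demultiplexer is expected to remove them downstream).
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [generate_molecule_table()].
#' @return A list of [gex_matrix()] objects (stage `"counts"`), one per
#'   sample.
#' @export
generate_gex_matrices <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  set.seed(derive_seed(config$seed, 303L))
  genes <- config$panel_genes
  other <- setdiff(genes, c("CD8", "CD4", "FOXP3"))
  mu_other <- stats::setNames(stats::rlnorm(length(other), log(8), 0.8),
                              other)

  sample_of <- truth$cell_to_sample
  if (nrow(truth$multiplet_samples)) {
    sample_of[truth$multiplet_samples$cell_label] <-
      truth$multiplet_samples$sample_a
  }
  lapply(truth$sample_ids, function(s) {
    cells <- names(sample_of)[sample_of == s]
    n <- length(cells)
    m <- matrix(0L, nrow = n, ncol = length(genes),
                dimnames = list(cells, genes))
    for (g in other) {
      m[, g] <- stats::rnbinom(n, mu = mu_other[g], size = 2)
    }
    pos <- truth$cd8_pos[cells]
    m[pos, "CD8"] <- 1L + stats::rnbinom(sum(pos), mu = 19, size = 8)
    if (any(!pos)) {
      m[!pos, "CD4"] <- 1L + stats::rnbinom(sum(!pos), mu = 14, size = 8)
      m[!pos, "FOXP3"] <- stats::rpois(sum(!pos), 0.5)
    }
    gex_matrix(m, sample_id = s, stage = "counts")
  })
}

#' Generate a synthetic LDH cytotoxicity plate
#'
#' Constructs optical densities (arbitrary absorbance units) such that the
#' percent-cytotoxicity formula recovers `true_pct` exactly when
#' `od_noise_sd = 0`. Baselines: effector-only 25, spontaneous lysis 30,
#' maximal lysis 150; the effector+target wells sit at
#' `25 + (150 - 30) * true_pct / 100`. Each condition is measured in
#' duplicate by default.
#'
#' @param true_pct True percent cytotoxicity in \[0, 100\].
#' @param od_noise_sd Gaussian noise SD added to each well (same units as
#'   the ODs); must be >= 0.
#' @param seed Integer seed.
#' @param replicates Wells per condition (>= 1).
#' @return A [cytotox_plate()].
#' @export
generate_cytotox_plate <- function(true_pct, od_noise_sd = 0, seed = 1L,
                                   replicates = 2L) {
  if (!is.finite(true_pct) || true_pct < 0 || true_pct > 100) {
    stop_invariant("true_pct", "must lie in [0, 100]")
  }
  if (!is.finite(od_noise_sd) || od_noise_sd < 0) {
    stop_invariant("od_noise_sd", "noise SD must be >= 0")
  }
  set.seed(as.integer(seed))
  base <- c(effector_plus_target = 25 + (150 - 30) * true_pct / 100,
            effector_only = 25, max_lysis = 150, spontaneous = 30)
  noisy <- function(v) pmax(0, rep(v, replicates) +
                              stats::rnorm(replicates, 0, od_noise_sd))
  cytotox_plate(od_effector_plus_target = noisy(base[1L]),
                od_effector_only = noisy(base[2L]),
                od_max_lysis = noisy(base[3L]),
                od_spontaneous = noisy(base[4L]))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:",
      sprintf("%d real cells, %d clonotypes (dominant %s: %d cells)",
              length(x$real_cells), length(x$clone_sizes),
              x$dominant_clonotype_id,
              x$clone_sizes[[x$dominant_clonotype_id]]),
      sprintf("%d multiplets, %d samples", nrow(x$multiplet_samples),
              length(x$sample_ids)),
      sep = "\n  ")
  invisible(x)
}
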