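ERGO_COLUMNS <- c("TRA", "TRB", "Peptide", "MHC", "TRAV", "TRAJ", "TRBV",
                  "TRBJ", "T-Cell-Type", "cell_index")

#' Binding records for TCR-peptide-MHC scoring
#'
#' One record per cell to be scored: CDR3 alpha/beta sequences, the target
#' peptide, MHC class, V/J gene names, T-cell type and a cell index for
#' later data-frame merging. Scores, when present, lie in \[0, 1\] (0 = no
#' affinity, 1 = maximum affinity).
#'
#' @param cell_index Character vector of cell ids.
#' @param cdr3a,cdr3b CDR3 amino-acid sequences (beta is mandatory; alpha
#'   may be empty).
#' @param peptide Target peptide (single value or per record).
#' @param mhc_class "MHC-I" or "MHC-II".
#' @param va,ja,vb,jb V/J gene names.
#' @param t_cell_type "CD8" or "CD4".
#' @param score Optional numeric scores in \[0, 1\].
#' @return A `binding_records` data.table.
#' @export
binding_records <- function(cell_index, cdr3a, cdr3b, peptide,
                            mhc_class = "MHC-I", va = "", ja = "",
                            vb = "", jb = "", t_cell_type = "CD8",
                            score = NA_real_) {
  dt <- data.table(cell_index = as.character(cell_index),
                   cdr3a = as.character(cdr3a),
                   cdr3b = as.character(cdr3b),
                   peptide = as.character(peptide),
                   mhc_class = mhc_class, va = va, ja = ja, vb = vb,
                   jb = jb, t_cell_type = t_cell_type,
                   score = as.numeric(score))
  if (nrow(dt)) {
    if (any(!nzchar(dt$peptide))) {
      stop_invariant("peptide non-empty", "empty peptide")
    }
    sc <- dt$score[!is.na(dt$score)]
    if (any(sc < 0 | sc > 1)) {
      stop_invariant("score in [0, 1]", "score outside [0, 1]")
    }
  }
  setattr(dt, "class", c("binding_records", "data.table", "data.frame"))
  dt
}

#' Write the scorer input CSV
#'
#' Emits the documented input dialect of the external binding-score
#' predictor: columns TRA, TRB, Peptide, MHC, TRAV, TRAJ, TRBV, TRBJ,
#' T-Cell-Type, plus a trailing `cell_index` column for later merging. A
#' missing CDR3 beta is an error (alpha may be empty).
#'
#' @param records A `binding_records` table.
#' @param path Output path.
#' @export
write_ergo_input <- function(records, path) {
  stopifnot(inherits(records, "binding_records"))
  if (nrow(records) && any(!nzchar(records$cdr3b))) {
    stop("CDR3 beta (cdr3b) is mandatory for every record")
  }
  out <- records[, .(TRA = cdr3a, TRB = cdr3b, Peptide = peptide,
                     MHC = mhc_class, TRAV = va, TRAJ = ja, TRBV = vb,
                     TRBJ = jb, `T-Cell-Type` = t_cell_type,
                     cell_index = cell_index)]
  fwrite(out, path)
  invisible(path)
}

#' Read the scorer output CSV
#'
#' Expects the input dialect of [write_ergo_input()] plus a `Score`
#' column. Scores must be numeric and within \[0, 1\] (boundaries
#' inclusive); a violating row is reported by its row number.
#'
#' @param path Path to the scored CSV.
#' @return A `binding_records` table with `score` populated.
#' @export
read_ergo_output <- function(path) {
  dt <- fread(path)
  if (!"Score" %in% names(dt)) {
    stop("scorer output is missing the required column: Score")
  }
  sc <- suppressWarnings(as.numeric(dt$Score))
  bad <- which(is.na(sc) & !is.na(dt$Score) | sc < 0 | sc > 1)
  if (length(bad)) {
    stop("invalid score in row(s) ", paste(bad, collapse = ", "),
         ": scores must be numeric and in [0, 1]")
  }
  binding_records(cell_index = dt$cell_index, cdr3a = dt$TRA,
                  cdr3b = dt$TRB, peptide = dt$Peptide,
                  mhc_class = dt$MHC, va = dt$TRAV, ja = dt$TRAJ,
                  vb = dt$TRBV, jb = dt$TRBJ,
                  t_cell_type = dt$`T-Cell-Type`, score = sc)
}

#' Deterministic surrogate binding scorer
#'
#' Stands in for the external neural-network predictor so the pipeline is
#' testable offline. When a true affinity is supplied per record, the score
#' is `clamp(truth + Gaussian(0, noise_sd))`; otherwise a deterministic
#' hash of (CDR3 beta, peptide) under `seed` provides a reproducible
#' pseudo-score. All scores lie in \[0, 1\], and with `noise_sd = 0`
#' ranking by surrogate score equals ranking by true affinity.
#'
#' @param records A `binding_records` table.
#' @param true_affinity Optional numeric vector (length 1 or nrow) of true
#'   affinities in \[0, 1\].
#' @param noise_sd Gaussian noise SD on the truth-based score.
#' @param seed Integer seed.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
surrogate_score <- function(records, true_affinity = NULL, noise_sd = 0.05,
                            seed = 1L) {
  stopifnot(inherits(records, "binding_records"))
  n <- nrow(records)
  if (n == 0L) return(numeric(0))
  if (!is.null(true_affinity)) {
    truth <- rep_len(as.numeric(true_affinity), n)
    set.seed(as.integer(seed))
    s <- truth + stats::rnorm(n, 0, noise_sd)
  } else {
    s <- hash_unit(paste(records$cdr3b, records$peptide, sep = "|"),
                   seed = seed)
  }
  pmin(1, pmax(0, s))
}
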