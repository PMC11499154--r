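AIRR_REQUIRED_COLS <- c("cell_id", "locus", "v_call", "j_call",
                        "junction_aa", "sequence_aa", "duplicate_count",
                        "productive")

#' AIRR rearrangement tables
#'
#' The package works with a subset of the AIRR Rearrangement TSV schema:
#' one row per receptor-chain rearrangement with columns `cell_id`, `locus`
#' (TRA or TRB), `v_call`, `j_call`, `junction_aa`, `sequence_aa`
#' (full-length chain amino acids), `duplicate_count` and `productive`.
#' Non-productive rows are retained but flagged.
#'
#' @param x A data.frame-like object with the required columns.
#' @return A validated `airr_table` data.table.
#' @export
as_airr_table <- function(x) {
  dt <- as.data.table(x)
  miss <- setdiff(AIRR_REQUIRED_COLS, names(dt))
  if (length(miss)) {
    stop("AIRR table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dt <- dt[, AIRR_REQUIRED_COLS, with = FALSE]
  dt[, duplicate_count := as.integer(duplicate_count)]
  if (is.character(dt$productive)) {
    dt[, productive := productive %in% c("T", "TRUE", "true")]
  }
  if (nrow(dt)) {
    if (!all(dt$locus %in% c("TRA", "TRB"))) {
      stop_invariant("locus in {TRA, TRB}", "unknown locus value")
    }
    if (any(dt$productive & !nzchar(dt$junction_aa))) {
      stop_invariant("junction_aa non-empty on productive rows",
                     "empty junction on a productive row")
    }
    if (any(dt$duplicate_count < 0L)) {
      stop_invariant("duplicate_count >= 0", "negative duplicate_count")
    }
  }
  setattr(dt, "class", c("airr_table", "data.table", "data.frame"))
  dt
}

#' Read an AIRR rearrangement TSV
#'
#' @param path Path to a tab-separated file whose header contains the
#'   required columns (see [as_airr_table()]); a missing column is an
#'   error naming the column.
#' @return An `airr_table`.
#' @export
read_airr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- names(fread(path, sep = "\t", nrows = 0L))
  chr <- intersect(c("cell_id", "locus", "v_call", "j_call", "junction_aa",
                     "sequence_aa"), hdr)
  dt <- fread(path, sep = "\t", colClasses = list(character = chr))
  as_airr_table(dt)
}

#' Write an AIRR rearrangement TSV
#'
#' The `productive` column is serialised as `T`/`F` per the AIRR TSV
#' convention; `write_airr(read_airr(f))` round-trips canonical files
#' byte-identically.
#'
#' @param airr An `airr_table`.
#' @param path Output path.
#' @export
write_airr <- function(airr, path) {
  dt <- copy(as_airr_table(airr))
  dt[, productive := ifelse(productive, "T", "F")]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Build paired-chain clonotypes
#'
#' For each cell, the productive TRA row and productive TRB row with the
#' highest `duplicate_count` are paired (ties broken to the
#' lexicographically smallest `sequence_aa`). Cells lacking either chain
#' are excluded and reported. Clonotype identity is, by default, the
#' full-length amino-acid pair plus V/J calls:
#' (TRA v_call, TRA j_call, TRA sequence_aa, TRB v_call, TRB j_call,
#' TRB sequence_aa).
#'
#' @param airr An `airr_table`.
#' @param cells Character vector of cell ids to cluster (e.g. gated CD8+
#'   cells); must be a subset of the cell ids present in `airr`.
#' @param key One of `"aa"` (default; V/J + full-length amino-acid
#'   sequences) or `"vjcdr3"` (V/J + CDR3 junction only). `"nt"` is not
#'   available because this AIRR subset carries no nucleotide sequences.
#' @return A `clonotype_table` data.table with columns tra_v, tra_j,
#'   tra_seq, trb_v, trb_j, trb_seq, cdr3a, cdr3b, n_cells, member_cells
#'   (list column), mean_binding_score, frac_effector, plus attribute
#'   `excluded_cells` (cells lacking a productive chain pair).
#' @export
build_clonotypes <- function(airr, cells, key = c("aa", "vjcdr3", "nt")) {
  key <- match.arg(key)
  if (key == "nt") {
    stop("key = \"nt\" is unavailable: the AIRR subset used here has no ",
         "nucleotide sequence columns; use \"aa\" or \"vjcdr3\"")
  }
  airr <- as_airr_table(airr)
  cells <- unique(as.character(cells))
  empty <- clonotype_table_skeleton()
  if (!length(cells)) {
    setattr(empty, "excluded_cells", character(0))
    return(empty)
  }
  sub <- airr[productive == TRUE & cell_id %in% cells]
  # best chain per (cell, locus): max duplicate_count, tie -> smallest seq
  setorder(sub, cell_id, locus, -duplicate_count, sequence_aa)
  best <- sub[, .SD[1L], by = .(cell_id, locus)]
  wide <- data.table::dcast(
    best, cell_id ~ locus,
    value.var = c("v_call", "j_call", "junction_aa", "sequence_aa"))
  for (cn in c("v_call_TRA", "j_call_TRA", "junction_aa_TRA",
               "sequence_aa_TRA", "v_call_TRB", "j_call_TRB",
               "junction_aa_TRB", "sequence_aa_TRB")) {
    if (!cn %in% names(wide)) wide[, (cn) := NA_character_]
  }
  paired <- wide[!is.na(sequence_aa_TRA) & !is.na(sequence_aa_TRB)]
  excluded <- sort(unique(setdiff(cells, paired$cell_id)))
  if (!nrow(paired)) {
    setattr(empty, "excluded_cells", excluded)
    return(empty)
  }
  if (key == "aa") {
    keycols <- c("v_call_TRA", "j_call_TRA", "sequence_aa_TRA",
                 "v_call_TRB", "j_call_TRB", "sequence_aa_TRB")
  } else {
    keycols <- c("v_call_TRA", "j_call_TRA", "junction_aa_TRA",
                 "v_call_TRB", "j_call_TRB", "junction_aa_TRB")
  }
  tbl <- paired[, .(
    tra_v = v_call_TRA[1L], tra_j = j_call_TRA[1L],
    tra_seq = sequence_aa_TRA[1L],
    trb_v = v_call_TRB[1L], trb_j = j_call_TRB[1L],
    trb_seq = sequence_aa_TRB[1L],
    cdr3a = junction_aa_TRA[1L], cdr3b = junction_aa_TRB[1L],
    n_cells = .N, member_cells = list(sort(cell_id))
  ), by = keycols][, (keycols) := NULL]
  tbl[, mean_binding_score := NA_real_]
  tbl[, frac_effector := NA_real_]
  setorder(tbl, -n_cells, tra_v, tra_j, tra_seq, trb_v, trb_j, trb_seq)
  setattr(tbl, "class", c("clonotype_table", "data.table", "data.frame"))
  setattr(tbl, "excluded_cells", excluded)
  tbl
}

clonotype_table_skeleton <- function() {
  tbl <- data.table(tra_v = character(0), tra_j = character(0),
                    tra_seq = character(0), trb_v = character(0),
                    trb_j = character(0), trb_seq = character(0),
                    cdr3a = character(0), cdr3b = character(0),
                    n_cells = integer(0), member_cells = list(),
                    mean_binding_score = numeric(0),
                    frac_effector = numeric(0))
  setattr(tbl, "class", c("clonotype_table", "data.table", "data.frame"))
  tbl
}

#' Annotate clonotypes with binding scores and effector fractions
#'
#' @param table A `clonotype_table`.
#' @param cell_scores Named numeric vector of per-cell binding scores (or
#'   NULL).
#' @param cell_effector Named logical vector flagging CD8+CD4-FOXP3- cells
#'   (or NULL).
#' @return The table with `mean_binding_score` and `frac_effector` filled
#'   for clonotypes whose member cells are covered.
#' @export
annotate_clonotypes <- function(table, cell_scores = NULL,
                                cell_effector = NULL) {
  tbl <- copy(table)
  if (!is.null(cell_scores)) {
    tbl[, mean_binding_score := vapply(member_cells, function(cc) {
      v <- cell_scores[cc]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))]
  }
  if (!is.null(cell_effector)) {
    tbl[, frac_effector := vapply(member_cells, function(cc) {
      v <- cell_effector[cc]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))]
  }
  setattr(tbl, "class", class(table))
  setattr(tbl, "excluded_cells", attr(table, "excluded_cells"))
  tbl
}

#' Filter and sort clonotypes by abundance
#'
#' Keeps clonotypes carried by at least `min_cells` cells, sorted by
#' descending cell count with ties broken by the clonotype key. Idempotent
#' and invariant to the input row order.
#'
#' @param table A `clonotype_table`.
#' @param min_cells Minimum member-cell count (>= 1).
#' @return The filtered, sorted `clonotype_table`.
#' @export
clonotype_abundance <- function(table, min_cells = 2L) {
  if (min_cells < 1L) stop("min_cells must be >= 1")
  tbl <- copy(table)[n_cells >= min_cells]
  setorder(tbl, -n_cells, tra_v, tra_j, tra_seq, trb_v, trb_j, trb_seq)
  setattr(tbl, "class", class(table))
  setattr(tbl, "excluded_cells", attr(table, "excluded_cells"))
  tbl
}

#' Select the dominant clonotype
#'
#' Candidates are clonotypes whose fraction of CD8+CD4-FOXP3- member cells
#' is at least `min_effector_frac` (clonotypes with no effector annotation
#' pass). Among candidates the winner maximises (n_cells,
#' mean_binding_score) lexicographically: cell count is the main criterion
#' and the predicted binding score breaks ties.
#'
#' @param table A non-empty `clonotype_table` with `mean_binding_score`
#'   present on the candidates.
#' @param min_effector_frac Minimum effector fraction (default 0.5,
#'   operationalising "predominantly" CD8+).
#' @return A list: `dominant` (one-row data.table), `n_cells`,
#'   `mean_binding_score`, and `report` (top 10 candidates with both
#'   criteria).
#' @export
select_dominant <- function(table, min_effector_frac = 0.5) {
  if (nrow(table) == 0L) stop("no dominant clonotype: table is empty")
  cand <- copy(table)[is.na(frac_effector) |
                        frac_effector >= min_effector_frac]
  if (nrow(cand) == 0L) {
    stop("no dominant clonotype: no candidate reaches an effector ",
         "fraction of ", min_effector_frac)
  }
  setorder(cand, -n_cells, -mean_binding_score, tra_v, tra_j, tra_seq,
           trb_v, trb_j, trb_seq, na.last = TRUE)
  top <- cand[1L]
  list(dominant = top,
       n_cells = top$n_cells,
       mean_binding_score = top$mean_binding_score,
       report = cand[seq_len(min(10L, nrow(cand))),
                     .(tra_v, tra_j, trb_v, trb_j, cdr3a, cdr3b, n_cells,
                       mean_binding_score, frac_effector)])
}

#' Write a clonotype table as TSV (list columns flattened)
#' @param table A `clonotype_table`.
#' @param path Output path.
#' @export
write_clonotypes <- function(table, path) {
  out <- copy(as.data.table(table))
  out[, member_cells := vapply(member_cells, paste, character(1),
                               collapse = ",")]
  fwrite(out, path, sep = "\t")
  invisible(path)
}
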