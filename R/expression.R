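#' Gene-expression matrices
#'
#' A `gex_matrix` is a dense cells-by-genes numeric matrix with a per-cell
#' `sample_id` attribute and a `stage` tag in \{counts, cpm, log2cpm\}.
#' Stage invariants: `counts` values are non-negative integers; after
#' `cpm` every non-zero cell row sums to 1e6; after `log2cpm` all values
#' are >= 0.
#'
#' @param values Numeric matrix, cells in rows (rownames = cell ids), genes
#'   in columns (colnames = gene names).
#' @param sample_id Sample id, length 1 or one per cell.
#' @param stage One of "counts", "cpm", "log2cpm".
#' @return A validated `gex_matrix`.
#' @export
gex_matrix <- function(values, sample_id, stage = "counts") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  stage <- match.arg(stage, c("counts", "cpm", "log2cpm"))
  if (length(sample_id) == 1L) {
    sample_id <- rep(sample_id, nrow(values))
  }
  stopifnot(length(sample_id) == nrow(values))
  if (any(values < 0)) stop_invariant("non-negative values",
                                      "negative entries present")
  structure(values, sample_id = as.character(sample_id), stage = stage,
            class = c("gex_matrix", "matrix", "array"))
}

#' @export
print.gex_matrix <- function(x, ...) {
  cat(sprintf("gex_matrix [%s]: %d cells x %d genes, %d sample(s)\n",
              attr(x, "stage"), nrow(x), ncol(x),
              length(unique(attr(x, "sample_id")))))
  invisible(x)
}

gex_stage <- function(m) attr(m, "stage")

require_stage <- function(m, stage, op) {
  if (!identical(gex_stage(m), stage)) {
    stop(op, " requires a matrix at stage \"", stage, "\", got \"",
         gex_stage(m), "\"")
  }
}

#' Merge per-sample expression matrices
#'
#' Row-concatenates matrices with identical gene panels and disjoint cell
#' ids, preserving each cell's sample id.
#'
#' @param matrices A list of [gex_matrix()] objects at the same stage.
#' @return A single merged `gex_matrix`.
#' @export
merge_gex <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  if (length(matrices) == 1L) return(matrices[[1L]])
  g0 <- colnames(matrices[[1L]])
  for (m in matrices[-1L]) {
    if (!identical(colnames(m), g0)) {
      d <- union(setdiff(colnames(m), g0), setdiff(g0, colnames(m)))
      stop("gene names differ between matrices; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  stages <- unique(vapply(matrices, gex_stage, character(1)))
  if (length(stages) != 1L) stop("matrices are at different stages")
  ids <- unlist(lapply(matrices, rownames))
  if (anyDuplicated(ids)) {
    stop("duplicate cell id(s) across samples: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- do.call(rbind, lapply(matrices, unclass))
  gex_matrix(vals,
             sample_id = unlist(lapply(matrices,
                                       function(m) attr(m, "sample_id"))),
             stage = stages)
}

#' Counts-per-million normalization
#'
#' Scales every cell row to a total of 1e6. All-zero rows are left all-zero
#' and reported with a warning.
#'
#' @param m A `gex_matrix` at stage "counts".
#' @return A `gex_matrix` at stage "cpm", with attribute `zero_rows`.
#' @export
cpm_normalize <- function(m) {
  require_stage(m, "counts", "cpm_normalize")
  if (any(m < 0)) stop("negative counts are not allowed")
  rs <- rowSums(m)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell row(s) left unnormalized")
  }
  scale_by <- ifelse(zero, 0, 1e6 / rs)
  out <- unclass(m) * scale_by
  res <- gex_matrix(out, sample_id = attr(m, "sample_id"), stage = "cpm")
  attr(res, "zero_rows") <- rownames(m)[zero]
  res
}

#' Zero-to-one log2 transform
#'
#' Maps every value v to `log2(max(v, 1))`: zeros (and sub-one values)
#' become exactly 0, so detected-vs-undetected is preserved on the log
#' scale.
#'
#' @param m A `gex_matrix` at stage "cpm".
#' @return A `gex_matrix` at stage "log2cpm".
#' @export
log2_zero_to_one <- function(m) {
  require_stage(m, "cpm", "log2_zero_to_one")
  out <- log2(pmax(unclass(m), 1))
  gex_matrix(out, sample_id = attr(m, "sample_id"), stage = "log2cpm")
}

#' Gate CD8+ effector T-cells
#'
#' Retains cells with CD8 above `cd8_min` and CD4/FOXP3 at or below their
#' ceilings, on the log2 CPM scale. The defaults (0/0/0) implement a
#' detected-versus-undetected gate.
#'
#' @param m A `gex_matrix` at stage "log2cpm" whose genes include CD8, CD4
#'   and FOXP3.
#' @param cd8_min Exclusive lower bound for CD8 expression.
#' @param cd4_max Inclusive upper bound for CD4 expression.
#' @param foxp3_max Inclusive upper bound for FOXP3 expression.
#' @return A list: `cells` (character vector of retained cell ids) and
#'   `report` (n_total, n_pass, cd8_fraction, thresholds).
#' @export
gate_cd8 <- function(m, cd8_min = 0, cd4_max = 0, foxp3_max = 0) {
  require_stage(m, "log2cpm", "gate_cd8")
  for (g in c("CD8", "CD4", "FOXP3")) {
    if (!g %in% colnames(m)) stop("marker gene absent from panel: ", g)
  }
  pass <- m[, "CD8"] > cd8_min & m[, "CD4"] <= cd4_max &
    m[, "FOXP3"] <= foxp3_max
  list(cells = rownames(m)[pass],
       report = list(n_total = nrow(m), n_pass = sum(pass),
                     cd8_fraction = mean(pass),
                     thresholds = c(cd8_min = cd8_min, cd4_max = cd4_max,
                                    foxp3_max = foxp3_max)))
}

#' Principal component analysis with explained-variance (scree) ratios
#'
#' Mean-centers the columns and returns PC scores together with the
#' fraction of total variance each component explains, in decreasing
#' order.
#'
#' @param m A `gex_matrix` at stage "log2cpm".
#' @param n_components Number of components to keep; at most
#'   `min(cells, genes)`.
#' @return An `embedding_result` list: `pc_scores` (cells x K),
#'   `explained_variance_ratio` (length K, non-increasing, sums to <= 1),
#'   and placeholders for the UMAP fields.
#' @export
pca_scree <- function(m, n_components = 4L) {
  require_stage(m, "log2cpm", "pca_scree")
  n_components <- as.integer(n_components)
  if (n_components > min(dim(m))) {
    stop("n_components (", n_components, ") exceeds min(cells, genes) = ",
         min(dim(m)))
  }
  pc <- stats::prcomp(unclass(m), center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  res <- list(pc_scores = pc$x[, seq_len(n_components), drop = FALSE],
              explained_variance_ratio = evr[seq_len(n_components)],
              umap_coords = NULL, n_pcs_used = NA_integer_,
              seed = NA_integer_)
  class(res) <- "embedding_result"
  res
}

#' UMAP embedding of the leading principal components
#'
#' Runs UMAP (via \pkg{uwot}) on the first `n_pcs` PC scores with a fixed
#' seed, 15 neighbours and min_dist 0.1 by default; identical seeds give
#' identical coordinates.
#'
#' @param pcs An `embedding_result` from [pca_scree()] with at least
#'   `n_pcs` components.
#' @param n_pcs Number of leading components to embed (default 4).
#' @param seed Integer seed (default 42).
#' @param n_neighbors,min_dist UMAP hyper-parameters; `n_neighbors` is
#'   clamped to the number of cells minus one.
#' @return The `embedding_result` with `umap_coords` (cells x 2),
#'   `n_pcs_used` and `seed` filled in.
#' @export
umap_embed <- function(pcs, n_pcs = 4L, seed = 42L, n_neighbors = 15L,
                       min_dist = 0.1) {
  stopifnot(inherits(pcs, "embedding_result"))
  if (n_pcs > ncol(pcs$pc_scores)) {
    stop("n_pcs (", n_pcs, ") exceeds the ", ncol(pcs$pc_scores),
         " available principal components")
  }
  x <- pcs$pc_scores[, seq_len(n_pcs), drop = FALSE]
  nn <- min(n_neighbors, nrow(x) - 1L)
  set.seed(as.integer(seed))
  coords <- uwot::umap(x, n_neighbors = nn, min_dist = min_dist,
                       n_threads = 1, n_sgd_threads = 0)
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("UMAP1", "UMAP2")
  pcs$umap_coords <- coords
  pcs$n_pcs_used <- as.integer(n_pcs)
  pcs$seed <- as.integer(seed)
  pcs
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf(
    "embedding_result: %d cells, %d PCs (%.1f%% variance)%s\n",
    nrow(x$pc_scores), ncol(x$pc_scores),
    100 * sum(x$explained_variance_ratio),
    if (is.null(x$umap_coords)) "" else
      sprintf(", UMAP on first %d PCs (seed %d)", x$n_pcs_used, x$seed)))
  invisible(x)
}

#' Read or write expression matrices as CSV
#'
#' CSV layout: first column `cell_id`, then one column per gene;
#' `sample_id` is carried in a second file-level column when writing the
#' long annotation form. These writers store the sample annotation as a
#' leading `sample_id` column.
#'
#' @param m A `gex_matrix`.
#' @param path File path.
#' @param stage Stage tag to assign on read.
#' @return `read_gex_csv` returns a `gex_matrix`.
#' @export
write_gex_csv <- function(m, path) {
  dt <- data.table(cell_id = rownames(m),
                   sample_id = attr(m, "sample_id"))
  dt <- cbind(dt, as.data.table(unclass(m)))
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_gex_csv
#' @export
read_gex_csv <- function(path, stage = "counts") {
  dt <- fread(path)
  vals <- as.matrix(dt[, !c("cell_id", "sample_id"), with = FALSE])
  rownames(vals) <- dt$cell_id
  gex_matrix(vals, sample_id = dt$sample_id, stage = stage)
}

#' Write an expression matrix as MatrixMarket with name sidecars
#'
#' Writes `<prefix>.mtx` (genes stay in columns), `<prefix>.cells.txt` and
#' `<prefix>.genes.txt`, plus `<prefix>.samples.txt` with the per-cell
#' sample ids. Requires the \pkg{Matrix} package.
#'
#' @param m A `gex_matrix`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_gex_mtx <- function(m, prefix) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MatrixMarket output")
  }
  sm <- Matrix::Matrix(unclass(m), sparse = TRUE)
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".cells.txt"))
  writeLines(colnames(m), paste0(prefix, ".genes.txt"))
  writeLines(attr(m, "sample_id"), paste0(prefix, ".samples.txt"))
  invisible(prefix)
}

#' @rdname write_gex_mtx
#' @param stage Stage tag to assign on read.
#' @export
read_gex_mtx <- function(prefix, stage = "counts") {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MatrixMarket input")
  }
  vals <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(vals) <- readLines(paste0(prefix, ".cells.txt"))
  colnames(vals) <- readLines(paste0(prefix, ".genes.txt"))
  gex_matrix(vals, sample_id = readLines(paste0(prefix, ".samples.txt")),
             stage = stage)
}
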