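#' Molecule tables
#'
#' A `molecule_table` is a data.table with one row per observed molecule:
#' `cell_label` (string), `umi` (fixed-length string over A/C/G/T),
#' `feature` (gene or sample-tag name) and `reads` (positive integer).
#' Invariants: no duplicate (cell_label, umi, feature) keys, reads >= 1,
#' all UMIs of equal length.
#'
#' @param x A data.frame-like object with the four columns above.
#' @return A validated `molecule_table`.
#' @export
as_molecule_table <- function(x) {
  dt <- as.data.table(x)
  req <- c("cell_label", "umi", "feature", "reads")
  miss <- setdiff(req, names(dt))
  if (length(miss)) {
    stop("molecule table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dt <- dt[, req, with = FALSE]
  dt[, reads := as.integer(reads)]
  validate_molecule_table(dt)
  setattr(dt, "class", c("molecule_table", "data.table", "data.frame"))
  dt
}

# Fast-path constructor for tables whose invariants hold by construction.
new_molecule_table <- function(dt) {
  setattr(dt, "class", c("molecule_table", "data.table", "data.frame"))
  dt
}

validate_molecule_table <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  if (any(dt$reads < 1L)) stop_invariant("reads >= 1", "found reads < 1")
  if (length(unique(nchar(dt$umi))) != 1L) {
    stop_invariant("all UMIs same length", "UMIs of unequal length")
  }
  if (anyDuplicated(dt, by = c("cell_label", "umi", "feature"))) {
    stop_invariant("no duplicate (cell_label, umi, feature) keys",
                   "duplicate molecule keys present")
  }
  invisible(dt)
}

#' Recursive substitution error correction (RSEC)
#'
#' Within each (cell_label, feature) group, a UMI `u` is merged into a
#' Hamming-distance-1 neighbour `v` whenever
#' `reads(v) >= 2 * reads(u) - 1`; the child's reads are added to the
#' parent and merging recurses until a fixpoint. At each step the child is
#' the mergeable UMI with the fewest reads (ties broken to the
#' lexicographically smallest UMI) and the parent is its eligible neighbour
#' with the most reads (same tie-break). Total reads are conserved within
#' every group and the number of UMIs never increases.
#'
#' @param molecules A `molecule_table` (see [as_molecule_table()]).
#' @return A corrected `molecule_table`.
#' @examples
#' m <- as_molecule_table(data.frame(
#'   cell_label = "c1", umi = c("AAAA", "AAAT"), feature = "G1",
#'   reads = c(10L, 1L)))
#' rsec_correct(m)  # collapses to a single AAAA molecule with 11 reads
#' @export
rsec_correct <- function(molecules) {
  molecules <- as_molecule_table(molecules)
  if (nrow(molecules) == 0L) return(molecules)
  dt <- copy(molecules)
  dt[, grp := .GRP, by = .(cell_label, feature)]
  dt[, row := .I]
  multi <- dt[, .N, by = grp][N >= 2L, grp]
  sub <- dt[grp %in% multi, .(grp, umi, row)]
  pairs <- if (nrow(sub)) {
    sub[sub, on = "grp", allow.cartesian = TRUE][umi < i.umi]
  } else sub[0L]
  if (nrow(pairs)) pairs <- pairs[hamming_dist(umi, i.umi) == 1L]
  if (!nrow(pairs)) {
    dt[, c("grp", "row") := NULL]
    setorder(dt, cell_label, feature, umi)
    return(new_molecule_table(dt))
  }

  # nodes are molecule row indices; edges connect Hamming-1 neighbours
  nodes <- sort(unique(c(pairs$row, pairs$i.row)))
  a <- match(pairs$row, nodes)
  b <- match(pairs$i.row, nodes)
  umis <- dt$umi[nodes]
  reads <- dt$reads[nodes]
  alive <- rep(TRUE, length(nodes))
  comp <- union_find(length(nodes), a, b)
  csize <- tabulate(comp)

  # fast path: two-node components have exactly one possible merge
  e2 <- which(csize[comp[a]] == 2L)
  if (length(e2)) {
    u <- a[e2]; v <- b[e2]
    swap <- reads[v] < reads[u] |
      (reads[v] == reads[u] & umis[v] < umis[u])
    child <- ifelse(swap, v, u)
    parent <- ifelse(swap, u, v)
    ok <- reads[parent] >= 2L * reads[child] - 1L
    reads[parent[ok]] <- reads[parent[ok]] + reads[child[ok]]
    alive[child[ok]] <- FALSE
  }

  # larger components: iterate the merge rule to a fixpoint
  big <- which(csize >= 3L)
  if (length(big)) {
    ecomp <- comp[a]
    e_by_comp <- split(seq_along(a), ecomp)
    n_by_comp <- split(seq_along(comp), comp)
    for (cid in big) {
      nb <- n_by_comp[[as.character(cid)]]
      eb <- e_by_comp[[as.character(cid)]]
      res <- collapse_component(umis[nb], reads[nb], nb, a[eb], b[eb])
      alive[nb] <- FALSE
      alive[nb[res$keep]] <- TRUE
      reads[nb[res$keep]] <- res$reads
    }
  }

  data.table::set(dt, i = nodes, j = "reads", value = as.integer(reads))
  out <- dt[c(setdiff(dt$row, nodes), nodes[alive]),
            .(cell_label, umi, feature, reads)]
  setorder(out, cell_label, feature, umi)
  new_molecule_table(out)
}

# Iterated union-find over edge lists (path halving).
union_find <- function(n, a, b) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i]); rb <- find(b[i])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# Fixpoint merge of one Hamming-1-connected component under the RSEC rule.
# umis/reads are the component's molecules; (ea, eb) are edge endpoints
# expressed in the id space of `ids`.
collapse_component <- function(umis, reads, ids, ea, eb) {
  k <- length(umis)
  pos <- match(c(ea, eb), ids)
  adj <- vector("list", k)
  e1 <- pos[seq_along(ea)]
  e2 <- pos[seq_along(eb) + length(ea)]
  for (i in seq_along(e1)) {
    adj[[e1[i]]] <- c(adj[[e1[i]]], e2[i])
    adj[[e2[i]]] <- c(adj[[e2[i]]], e1[i])
  }
  alive <- rep(TRUE, k)
  repeat {
    child <- NA_integer_; parent <- NA_integer_
    ord <- order(reads, umis)
    for (u in ord[alive[ord]]) {
      nb <- adj[[u]][alive[adj[[u]]]]
      ok <- nb[reads[nb] >= 2L * reads[u] - 1L & nb != u]
      if (length(ok)) {
        ok <- ok[order(-reads[ok], umis[ok])]
        child <- u; parent <- ok[1L]
        break
      }
    }
    if (is.na(child)) break
    reads[parent] <- reads[parent] + reads[child]
    alive[child] <- FALSE
  }
  list(keep = which(alive), reads = reads[alive])
}

#' Distribution-based error correction (DBEC)
#'
#' Per feature, the log2 read depths per molecule are split at the
#' exhaustive two-class threshold minimising the within-class sum of
#' squares (Otsu-style). If the two class means are separated by at least
#' `margin` log2 units, the low class is removed as error molecules;
#' otherwise the feature is left untouched. A feature's highest-read
#' molecule can never be removed. Intended to run on RSEC-corrected input.
#'
#' @param molecules A `molecule_table`.
#' @param margin Minimum separation of class means, in log2 units.
#' @return A list with `molecules` (kept), `removed` (molecule_table of
#'   removed error molecules) and `status` (per-feature data.table:
#'   feature, bimodal, threshold_log2, n_removed).
#' @export
dbec_filter <- function(molecules, margin = 1) {
  molecules <- as_molecule_table(molecules)
  if (nrow(molecules) == 0L) {
    return(list(molecules = molecules, removed = molecules,
                status = data.table(feature = character(0),
                                    bimodal = logical(0),
                                    threshold_log2 = numeric(0),
                                    n_removed = integer(0))))
  }
  dt <- copy(molecules)
  dt[, log2_reads := log2(reads)]
  st <- dt[, {
    s <- otsu_split(log2_reads)
    bim <- !is.na(s$threshold) && s$gap >= margin
    list(bimodal = bim,
         threshold_log2 = if (bim) s$threshold else NA_real_)
  }, by = feature]
  dt <- st[dt, on = "feature"]
  drop <- dt$bimodal & dt$log2_reads <= dt$threshold_log2
  keep_tab <- dt[!drop, .(cell_label, umi, feature, reads)]
  rm_tab <- dt[drop, .(cell_label, umi, feature, reads)]
  st <- merge(st, dt[drop, .(n_removed = .N), by = feature],
              by = "feature", all.x = TRUE)
  st[is.na(n_removed), n_removed := 0L]
  list(molecules = new_molecule_table(keep_tab),
       removed = new_molecule_table(rm_tab),
       status = st[])
}

# Exhaustive minimum within-class-SS split of a numeric vector. Returns the
# threshold (midpoint convention: low class = values <= threshold) and the
# gap between class means, or NA when no split between distinct values
# exists.
otsu_split <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(threshold = NA_real_, gap = NA_real_))
  v <- sort(v)
  if (v[1L] == v[n]) return(list(threshold = NA_real_, gap = NA_real_))
  cs <- cumsum(v)
  cs2 <- cumsum(v^2)
  k <- seq_len(n - 1L)
  ss_low <- cs2[k] - cs[k]^2 / k
  ss_high <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  ss <- ss_low + ss_high
  valid <- v[k] < v[k + 1L]
  ss[!valid] <- Inf
  kbest <- which.min(ss)
  mean_low <- cs[kbest] / kbest
  mean_high <- (cs[n] - cs[kbest]) / (n - kbest)
  list(threshold = v[kbest], gap = mean_high - mean_low)
}

#' Barcode-rank cell calling by second-derivative knee detection
#'
#' Cell labels are ranked by descending total reads; the curve of
#' (log10 rank, log10 cumulative read fraction) is optionally smoothed by a
#' centered moving average, and the knee is the rank minimising the
#' discrete second derivative (nonuniform three-point stencil). Labels
#' ranked at or before the knee are called as cells. If the minimum second
#' derivative is not below `-tol` there is no knee and every label is
#' returned. Output is invariant to the input row order (rank ties are
#' broken lexicographically by label).
#'
#' @param molecules A `molecule_table` (typically gene features after
#'   RSEC).
#' @param window Smoothing window for the centered moving average; the
#'   default 1 applies no smoothing, which locates the knee exactly on
#'   cleanly bimodal curves (see the methods vignette for why the default
#'   is not a wider window).
#' @param tol Knee tolerance: a knee requires min second derivative
#'   < `-tol`.
#' @return A `cell_call_result` list: `valid_labels` (character, ordered by
#'   rank), `rank_curve` (data.table: rank, cell_label, total_reads) and
#'   `inflection_rank` (integer, or `NA` when no knee was found).
#' @export
call_cells <- function(molecules, window = 1L, tol = 0.01) {
  molecules <- as_molecule_table(molecules)
  tot <- molecules[, .(total_reads = sum(reads)), by = cell_label]
  if (nrow(tot) < 3L) {
    stop("call_cells requires at least 3 distinct cell labels")
  }
  setorder(tot, -total_reads, cell_label)
  tot[, rank := .I]
  x <- log10(tot$rank)
  y <- log10(cumsum(tot$total_reads) / sum(tot$total_reads))
  ys <- moving_average(y, window)
  n <- length(ys)
  i <- 2L:(n - 1L)
  d2 <- rep(NA_real_, n)
  d2[i] <- 2 * ((ys[i + 1L] - ys[i]) / (x[i + 1L] - x[i]) -
                  (ys[i] - ys[i - 1L]) / (x[i] - x[i - 1L])) /
    (x[i + 1L] - x[i - 1L])
  kmin <- which.min(d2)
  if (!length(kmin) || !is.finite(d2[kmin]) || d2[kmin] >= -tol) {
    res <- list(valid_labels = tot$cell_label,
                rank_curve = tot[, .(rank, cell_label, total_reads)],
                inflection_rank = NA_integer_)
  } else {
    res <- list(valid_labels = tot$cell_label[seq_len(kmin)],
                rank_curve = tot[, .(rank, cell_label, total_reads)],
                inflection_rank = as.integer(kmin))
  }
  class(res) <- "cell_call_result"
  res
}

#' @export
print.cell_call_result <- function(x, ...) {
  cat(sprintf("cell_call_result: %d of %d labels called (knee at rank %s)\n",
              length(x$valid_labels), nrow(x$rank_curve),
              ifelse(is.na(x$inflection_rank), "none",
                     x$inflection_rank)))
  invisible(x)
}

#' Sample-tag demultiplexing with multiplet exclusion
#'
#' For each tag, a noise threshold is estimated as mean + 3 SD of the tag's
#' read counts over the called cells in which it is not the maximal tag. A
#' cell is assigned to the unique tag exceeding its threshold; two or more
#' such tags make it a `"multiplet"`, none an `"undetermined"`. A called
#' cell absent from the tag table is `"undetermined"`.
#'
#' @param tag_molecules A `molecule_table` whose features are sample-tag
#'   names.
#' @param valid_labels Non-empty character vector of called cell labels.
#' @param tag_to_sample Optional named vector mapping tag names to sample
#'   ids; by default cells are assigned the tag name itself.
#' @param thresholds Optional named numeric vector of per-tag noise
#'   thresholds, bypassing the mean + 3 SD estimate.
#' @return A `demux_result` list: `assignment` (named character: sample id,
#'   `"multiplet"` or `"undetermined"` per called cell) and `per_tag_noise`
#'   (named numeric thresholds).
#' @export
demultiplex <- function(tag_molecules, valid_labels, tag_to_sample = NULL,
                        thresholds = NULL) {
  tag_molecules <- as_molecule_table(tag_molecules)
  if (!length(valid_labels)) {
    stop("demultiplex requires a non-empty set of valid labels")
  }
  tags <- sort(unique(tag_molecules$feature))
  counts <- tag_molecules[cell_label %in% valid_labels,
                          .(reads = sum(reads)),
                          by = .(cell_label, feature)]
  cmat <- matrix(0, nrow = length(valid_labels), ncol = length(tags),
                 dimnames = list(valid_labels, tags))
  if (nrow(counts)) {
    cmat[cbind(counts$cell_label, counts$feature)] <- counts$reads
  }
  rowmax <- apply(cmat, 1L, max)
  if (is.null(thresholds)) {
    thresholds <- vapply(tags, function(tg) {
      not_max <- cmat[, tg] < rowmax | rowmax == 0
      v <- cmat[not_max, tg]
      if (length(v) < 2L) return(0)
      mean(v) + 3 * stats::sd(v)
    }, numeric(1))
  } else {
    if (!all(tags %in% names(thresholds))) {
      stop("thresholds must be named for every tag present")
    }
    thresholds <- thresholds[tags]
  }
  above <- sweep(cmat, 2L, thresholds, ">")
  n_above <- rowSums(above)
  assignment <- rep("undetermined", length(valid_labels))
  names(assignment) <- valid_labels
  single <- which(n_above == 1L)
  if (length(single)) {
    win <- tags[apply(above[single, , drop = FALSE], 1L, which)]
    if (!is.null(tag_to_sample)) win <- unname(tag_to_sample[win])
    assignment[single] <- win
  }
  assignment[n_above >= 2L] <- "multiplet"
  res <- list(assignment = assignment, per_tag_noise = thresholds)
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  tab <- table(ifelse(x$assignment %in% c("multiplet", "undetermined"),
                      x$assignment, "singlet"))
  cat("demux_result:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Read or write a molecule table as TSV
#' @param path File path.
#' @return `read_molecule_table` returns a `molecule_table`.
#' @export
read_molecule_table <- function(path) {
  as_molecule_table(fread(path, sep = "\t"))
}

#' @param molecules A `molecule_table`.
#' @rdname read_molecule_table
#' @export
write_molecule_table <- function(molecules, path) {
  fwrite(as_molecule_table(molecules), path, sep = "\t")
  invisible(path)
}
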