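#' Run the full clonotype-selection pipeline on synthetic data
#'
#' Composes simulate -> RSEC -> DBEC -> cell calling -> demultiplexing ->
#' expression normalization and CD8 gating -> paired-chain clonotype
#' construction -> surrogate binding scores -> dominant-clonotype
#' selection, and returns a machine-readable run report. All randomness is
#' funneled through `config$seed`, so identical configurations yield
#' identical reports.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, stage artifacts
#'   (molecule tables, AIRR TSV, clonotype table, demux report, report
#'   JSON) are written under it.
#' @param embed Compute PCA + UMAP on the gated expression matrix
#'   (disabled by default; the embedding does not influence clonotype
#'   selection and dominates the runtime at scale).
#' @param min_cells Abundance threshold reported as `n_clonotypes_ge2`
#'   uses 2 regardless; this threshold filters the candidate table passed
#'   to dominance selection.
#' @param min_effector_frac Passed to [select_dominant()].
#' @param score_noise_sd Noise SD of the surrogate binding scorer.
#' @param peptide Target peptide for the binding records.
#' @param n_pcs Number of PCs fed to UMAP when `embed = TRUE`.
#' @return A `run_report` list; see Details.
#'
#' @details The report contains the config echo, `n_cells_called`,
#'   `n_multiplets`, `n_undetermined`, `n_gated_cd8`, `cd8_fraction`,
#'   `n_clonotypes`, `n_clonotypes_ge2`, `n_unpaired_cells`, `dominant`
#'   (chain key, n_cells, mean binding score), per-stage `durations_sec`
#'   and the seed.
#' @export
run_pipeline <- function(config, out_dir = NULL, embed = FALSE,
                         min_cells = 1L, min_effector_frac = 0.5,
                         score_noise_sd = 0.05, peptide = "KVAELVHFL",
                         n_pcs = 4L) {
  stopifnot(inherits(config, "sim_config"))
  durations <- list()
  clock <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE)
    })
    durations[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  sim <- clock("simulate", generate_molecule_table(config))
  truth <- sim$truth
  is_tag <- sim$molecules$feature %in% truth$tag_names
  gene_mol <- new_molecule_table(sim$molecules[!is_tag])
  tag_mol <- new_molecule_table(sim$molecules[is_tag])

  gene_mol <- clock("rsec", rsec_correct(gene_mol))
  tag_mol <- clock("rsec_tags", rsec_correct(tag_mol))
  dbec <- clock("dbec", dbec_filter(gene_mol))

  calls <- clock("call_cells", call_cells(dbec$molecules))
  tag_map <- stats::setNames(truth$sample_ids, truth$tag_names)
  demux <- clock("demux",
                 demultiplex(tag_mol, calls$valid_labels,
                             tag_to_sample = tag_map))
  singlets <- names(demux$assignment)[
    !demux$assignment %in% c("multiplet", "undetermined")]

  airr <- clock("airr", generate_airr_table(config, truth))
  gex <- clock("gex", {
    mats <- generate_gex_matrices(config, truth)
    log2_zero_to_one(cpm_normalize(merge_gex(mats)))
  })
  gate <- clock("gate", gate_cd8(gex))
  gated_singlets <- intersect(gate$cells, singlets)

  clono <- clock("clonotypes", {
    tbl <- build_clonotypes(airr, gated_singlets)
    cell_of <- unlist(tbl$member_cells)
    ct <- truth$clonotype_of_cell[cell_of]
    scores <- surrogate_score(
      binding_records(cell_index = cell_of,
                      cdr3a = rep(tbl$cdr3a, tbl$n_cells),
                      cdr3b = rep(tbl$cdr3b, tbl$n_cells),
                      peptide = peptide),
      true_affinity = truth$true_affinity[ct],
      noise_sd = score_noise_sd, seed = derive_seed(config$seed, 404L))
    eff <- stats::setNames(rownames(gex) %in% gate$cells, rownames(gex))
    annotate_clonotypes(tbl, cell_scores = stats::setNames(scores, cell_of),
                        cell_effector = eff)
  })
  dominant <- clock("select_dominant", {
    select_dominant(clonotype_abundance(clono, min_cells),
                    min_effector_frac = min_effector_frac)
  })

  embedding <- NULL
  if (embed) {
    embedding <- clock("embed", {
      sub <- gex_matrix(unclass(gex)[gated_singlets, , drop = FALSE],
                        sample_id = attr(gex, "sample_id")[
                          match(gated_singlets, rownames(gex))],
                        stage = "log2cpm")
      pcs <- pca_scree(sub, n_components = max(n_pcs, 4L))
      umap_embed(pcs, n_pcs = n_pcs, seed = config$seed)
    })
  }

  report <- list(
    config = unclass(config),
    seed = config$seed,
    n_cells_called = length(calls$valid_labels),
    inflection_rank = calls$inflection_rank,
    n_multiplets = sum(demux$assignment == "multiplet"),
    n_undetermined = sum(demux$assignment == "undetermined"),
    n_gated_cd8 = gate$report$n_pass,
    cd8_fraction = gate$report$cd8_fraction,
    n_clonotypes = nrow(clono),
    n_clonotypes_ge2 = sum(clono$n_cells >= 2L),
    n_unpaired_cells = length(attr(clono, "excluded_cells")),
    dominant = list(
      tra_v = dominant$dominant$tra_v, tra_j = dominant$dominant$tra_j,
      trb_v = dominant$dominant$trb_v, trb_j = dominant$dominant$trb_j,
      cdr3a = dominant$dominant$cdr3a, cdr3b = dominant$dominant$cdr3b,
      n_cells = dominant$n_cells,
      mean_binding_score = dominant$mean_binding_score),
    durations_sec = durations)
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_molecule_table(gene_mol, file.path(out_dir, "molecules_gene.tsv"))
    write_molecule_table(tag_mol, file.path(out_dir, "molecules_tag.tsv"))
    write_airr(airr, file.path(out_dir, "rearrangements.airr.tsv"))
    write_clonotypes(clono, file.path(out_dir, "clonotypes.tsv"))
    fwrite(data.table(cell_label = names(demux$assignment),
                      assignment = demux$assignment),
           file.path(out_dir, "demux.tsv"), sep = "\t")
    write_run_report(report, file.path(out_dir, "report.json"))
    if (!is.null(embedding)) {
      fwrite(data.table(cell_id = rownames(embedding$umap_coords),
                        embedding$umap_coords),
             file.path(out_dir, "umap.csv"))
    }
  }
  attr(report, "truth") <- truth
  attr(report, "embedding") <- embedding
  attr(report, "dominant_cells") <- dominant$dominant$member_cells[[1L]]
  report
}

#' Serialize a run report as JSON
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_run_report <- function(report, path) {
  clean <- unclass(report)
  attr(clean, "truth") <- NULL
  attr(clean, "embedding") <- NULL
  jsonlite::write_json(clean, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$seed, "):\n",
      "  cells called:       ", x$n_cells_called, "\n",
      "  multiplets:         ", x$n_multiplets, "\n",
      "  gated CD8+:         ", x$n_gated_cd8,
      sprintf(" (%.2f%%)", 100 * x$cd8_fraction), "\n",
      "  clonotypes:         ", x$n_clonotypes,
      " (", x$n_clonotypes_ge2, " with >= 2 cells)\n",
      "  dominant clonotype: ", x$dominant$cdr3a, " / ", x$dominant$cdr3b,
      "\n",
      "    cells: ", x$dominant$n_cells,
      ", mean binding score: ",
      round(x$dominant$mean_binding_score, 3), "\n", sep = "")
  invisible(x)
}

#' Did a run recover the planted dominant clonotype?
#'
#' Compares the dominant clonotype of a run report against the planted
#' ground truth attached to it.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return TRUE when the reported dominant clonotype's member cells equal
#'   the planted dominant clonotype's cells.
#' @export
dominant_recovered <- function(report) {
  truth <- attr(report, "truth")
  if (is.null(truth)) stop("report carries no ground truth")
  dom_cells <- names(truth$clonotype_of_cell)[
    truth$clonotype_of_cell == truth$dominant_clonotype_id]
  setequal(attr(report, "dominant_cells"), dom_cells)
}

# Rebuild a sim_config from a report's config echo.
sim_config_from <- function(cfg) {
  do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
}

#' Load a pipeline configuration from JSON or YAML
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file whose top-level
#'   keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs; use JSON")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_config_from(cfg)
}
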