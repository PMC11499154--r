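make_airr <- function(...) {
  rows <- list(...)
  as_airr_table(rbindlist(lapply(rows, function(r) {
    as.data.table(utils::modifyList(list(
      cell_id = "c1", locus = "TRA", v_call = "TRAV1*01",
      j_call = "TRAJ4*01", junction_aa = "CAVRF",
      sequence_aa = "MAVRSEQ", duplicate_count = 1L, productive = TRUE),
      r))
  })))
}

test_that("AIRR files round-trip and reject missing columns", {
  cfg <- tiny_config(seed = 21)
  sim <- generate_molecule_table(cfg)
  airr <- generate_airr_table(cfg, sim$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr(airr, path)
  expect_no_warning(back <- read_airr(path))
  expect_identical(as.data.frame(back), as.data.frame(airr))
  # canonical files round-trip byte-identically
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_airr(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # header-only file parses to an empty table
  writeLines(paste(clonoscape:::AIRR_REQUIRED_COLS, collapse = "\t"), path)
  expect_equal(nrow(read_airr(path)), 0L)

  bad <- as.data.table(airr)[, junction_aa := NULL]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  fwrite(bad, tmp, sep = "\t")
  expect_error(read_airr(tmp), "junction_aa")
  expect_error(read_airr("/nonexistent/x.tsv"), "no such file")
})

test_that("build_clonotypes pairs chains and counts cells", {
  rows <- list()
  for (cell in c("c1", "c2", "c3")) {
    rows <- c(rows, list(
      list(cell_id = cell),
      list(cell_id = cell, locus = "TRB", v_call = "TRBV19*01",
           j_call = "TRBJ1-1*01", junction_aa = "CASSF",
           sequence_aa = "MBSSEQ")))
  }
  rows <- c(rows, list(
    list(cell_id = "c4", sequence_aa = "MOTHER", junction_aa = "CAXRF"),
    list(cell_id = "c4", locus = "TRB", v_call = "TRBV2*01",
         j_call = "TRBJ1-2*01", junction_aa = "CASYF",
         sequence_aa = "MBOTHER"),
    # c5 has only a TRB chain -> excluded and reported
    list(cell_id = "c5", locus = "TRB", v_call = "TRBV19*01",
         j_call = "TRBJ1-1*01", junction_aa = "CASSF",
         sequence_aa = "MBSSEQ")))
  airr <- do.call(make_airr, rows)
  tbl <- build_clonotypes(airr, c("c1", "c2", "c3", "c4", "c5"))
  expect_equal(tbl$n_cells, c(3L, 1L))
  expect_identical(attr(tbl, "excluded_cells"), "c5")
  # partition invariant: clustered + excluded = gated cells
  expect_equal(sum(tbl$n_cells) + length(attr(tbl, "excluded_cells")), 5L)
})

test_that("the highest-duplicate-count chain wins within a locus", {
  airr <- make_airr(
    list(cell_id = "c1", sequence_aa = "AAA", duplicate_count = 2L),
    list(cell_id = "c1", sequence_aa = "BBB", duplicate_count = 7L),
    list(cell_id = "c1", locus = "TRB", v_call = "TRBV1*01",
         j_call = "TRBJ1-1*01", junction_aa = "CASF",
         sequence_aa = "MB", duplicate_count = 3L))
  tbl <- build_clonotypes(airr, "c1")
  expect_equal(tbl$tra_seq, "BBB")
  # ties break to the lexicographically smallest sequence
  airr2 <- make_airr(
    list(cell_id = "c1", sequence_aa = "ZZZ", duplicate_count = 5L),
    list(cell_id = "c1", sequence_aa = "AAA", duplicate_count = 5L),
    list(cell_id = "c1", locus = "TRB", v_call = "TRBV1*01",
         j_call = "TRBJ1-1*01", junction_aa = "CASF",
         sequence_aa = "MB", duplicate_count = 3L))
  expect_equal(build_clonotypes(airr2, "c1")$tra_seq, "AAA")
  # non-productive chains never pair
  airr3 <- make_airr(
    list(cell_id = "c1"),
    list(cell_id = "c1", locus = "TRB", v_call = "TRBV1*01",
         j_call = "TRBJ1-1*01", junction_aa = "CASF",
         sequence_aa = "MB", productive = FALSE))
  expect_equal(nrow(build_clonotypes(airr3, "c1")), 0L)
  # empty cell set -> empty table
  expect_equal(nrow(build_clonotypes(airr, character(0))), 0L)
  # nucleotide keys are not available in this schema subset
  expect_error(build_clonotypes(airr, "c1", key = "nt"), "nt")
})

test_that("clonotype_abundance filters, sorts and is idempotent", {
  cfg <- tiny_config(seed = 22, clone_size_power = 2.2)
  sim <- generate_molecule_table(cfg)
  airr <- generate_airr_table(cfg, sim$truth)
  tbl <- build_clonotypes(airr, sim$truth$real_cells)
  # planted sizes are recovered exactly
  expect_setequal(tbl$n_cells, unname(sim$truth$clone_sizes))
  expect_equal(sort(tbl$n_cells), sort(unname(sim$truth$clone_sizes)))

  ab <- clonotype_abundance(tbl, min_cells = 2L)
  expect_true(all(ab$n_cells >= 2L))
  expect_true(!is.unsorted(rev(ab$n_cells)))
  expect_identical(as.data.frame(clonotype_abundance(ab, 2L)),
                   as.data.frame(ab))
  # order-invariance
  shuffled <- tbl[sample(nrow(tbl))]
  data.table::setattr(shuffled, "class", class(tbl))
  expect_identical(as.data.frame(clonotype_abundance(shuffled, 2L)),
                   as.data.frame(ab))
  # min_cells = 1 keeps every row
  expect_equal(nrow(clonotype_abundance(tbl, 1L)), nrow(tbl))
  expect_error(clonotype_abundance(tbl, 0L), "min_cells")
})

test_that("dominance: count first, binding score second", {
  tbl <- clonoscape:::clonotype_table_skeleton()
  add <- function(tbl, seq, n, score, frac = 1) {
    rbind(tbl, data.table(
      tra_v = "TRAV1*01", tra_j = "TRAJ1*01", tra_seq = paste0("A", seq),
      trb_v = "TRBV1*01", trb_j = "TRBJ1-1*01", trb_seq = paste0("B", seq),
      cdr3a = "CAF", cdr3b = "CBF", n_cells = as.integer(n),
      member_cells = list(sprintf("%s_%d", seq, seq_len(n))),
      mean_binding_score = score, frac_effector = frac))
  }
  t1 <- add(add(tbl, "x", 14, 0.55), "y", 9, 0.90)
  data.table::setattr(t1, "class", class(tbl))
  expect_equal(select_dominant(t1)$dominant$tra_seq, "Ax")
  # tie on count -> higher score wins
  t2 <- add(add(tbl, "x", 14, 0.55), "y", 14, 0.90)
  data.table::setattr(t2, "class", class(tbl))
  expect_equal(select_dominant(t2)$dominant$tra_seq, "Ay")
  # effector-fraction filter removes candidates
  t3 <- add(add(tbl, "x", 14, 0.55, frac = 0.2), "y", 9, 0.90)
  data.table::setattr(t3, "class", class(tbl))
  expect_equal(select_dominant(t3)$dominant$tra_seq, "Ay")
  expect_error(select_dominant(clonoscape:::clonotype_table_skeleton()),
               "empty")
  t4 <- add(tbl, "x", 5, 0.5, frac = 0.1)
  data.table::setattr(t4, "class", class(tbl))
  expect_error(select_dominant(t4), "no candidate")
})

test_that("zero-dropout dominance recovery across 100 seeds", {
  hits <- vapply(1:100, function(s) {
    cfg <- tiny_config(seed = s, n_real_cells = 60L,
                       n_noise_barcodes = 20L, reads_per_real_cell = 60,
                       reads_per_noise_barcode = 4, n_clonotypes = 25L,
                       dominant_clone_size = 8L, umi_error_rate = 0,
                       multiplet_rate = 0)
    sim <- generate_molecule_table(cfg)
    airr <- generate_airr_table(cfg, sim$truth)
    tbl <- build_clonotypes(airr, sim$truth$real_cells)
    sel <- select_dominant(tbl)
    dom_cells <- names(sim$truth$clonotype_of_cell)[
      sim$truth$clonotype_of_cell == sim$truth$dominant_clonotype_id]
    setequal(sel$dominant$member_cells[[1]], dom_cells)
  }, logical(1))
  expect_true(all(hits))
})
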