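test_that("RSEC collapses the documented example groups", {
  # simple parent/child pair
  out <- rsec_correct(umi_group(c("AAAA", "AAAT"), c(10, 1)))
  expect_equal(out$umi, "AAAA")
  expect_equal(out$reads, 11L)
  # recursive chain: AATT -> AAAT (3 >= 2*1-1), then AAAT:4 -> AAAA
  out2 <- rsec_correct(umi_group(c("AAAA", "AAAT", "AATT"), c(8, 3, 1)))
  expect_equal(out2$umi, "AAAA")
  expect_equal(out2$reads, 12L)
  # single UMI untouched
  out3 <- rsec_correct(umi_group("CCCC", 5))
  expect_equal(out3$reads, 5L)
  # ineligible parent: 3 < 2*2 - 1 is false, 3 >= 3 so it merges;
  # but 2 < 2*2 - 1 = 3 keeps this pair apart
  out4 <- rsec_correct(umi_group(c("GGGG", "GGGT"), c(2, 2)))
  expect_equal(nrow(out4), 2L)
})

test_that("RSEC rejects UMIs of unequal length", {
  bad <- data.frame(cell_label = "c", umi = c("AAAA", "AAA"),
                    feature = "G", reads = c(2L, 1L))
  expect_error(rsec_correct(bad), "equal length|same length")
})

test_that("RSEC matches the brute-force oracle on random small groups", {
  set.seed(421)
  for (i in seq_len(200)) {
    g <- random_umi_group(sample(2:6, 1))
    got <- as.data.frame(rsec_correct(umi_group(g$umis, g$reads)))
    want <- oracle_rsec_group(g$umis, g$reads)
    expect_identical(got$umi, want$umi)
    expect_identical(got$reads, as.integer(want$reads))
    # conservation and non-increasing UMI count
    expect_identical(sum(got$reads), as.integer(sum(g$reads)))
    expect_lte(nrow(got), length(g$umis))
  }
})

test_that("RSEC conserves reads per (cell, feature) group at scale", {
  sim <- generate_molecule_table(tiny_config(seed = 31,
                                             umi_error_rate = 0.05))
  before <- sim$molecules[, .(r = sum(reads)), by = .(cell_label, feature)]
  after <- rsec_correct(sim$molecules)[, .(r = sum(reads)),
                                       by = .(cell_label, feature)]
  merged <- merge(before, after, by = c("cell_label", "feature"))
  expect_true(all(merged$r.x == merged$r.y))
  expect_lte(nrow(rsec_correct(sim$molecules)), nrow(sim$molecules))
})

test_that("RSEC restores the planted molecule set", {
  sim <- generate_molecule_table(tiny_config(seed = 32,
                                             umi_error_rate = 0.08))
  corrected <- rsec_correct(sim$molecules)
  clean <- generate_molecule_table(tiny_config(seed = 32,
                                               umi_error_rate = 0))
  # comparing post-RSEC tables, since true Hamming-1 neighbours that
  # happen to satisfy the parent rule collapse in both worlds
  expect_identical(as.data.frame(corrected),
                   as.data.frame(rsec_correct(clean$molecules)))
})

test_that("DBEC removes a clearly separated low class", {
  m <- umi_group(c("AAAA", "AAAC", "AAAG", "CCCC", "GGGG", "TTTT"),
                 c(1, 1, 1, 9, 10, 11))
  res <- dbec_filter(m)
  expect_equal(sort(res$molecules$reads), c(9L, 10L, 11L))
  expect_equal(nrow(res$removed), 3L)
  expect_true(res$status$bimodal)
  # agreement with the exhaustive oracle
  low <- oracle_dbec_low_class(log2(c(1, 1, 1, 9, 10, 11)))
  expect_length(low, 3L)
})

test_that("DBEC leaves unimodal and degenerate features untouched", {
  m <- umi_group(c("AAAA", "AAAC", "AAAG", "CCCC"), c(5, 6, 5, 7))
  res <- dbec_filter(m)
  expect_equal(nrow(res$molecules), 4L)
  expect_equal(nrow(res$removed), 0L)
  expect_false(res$status$bimodal)
  single <- umi_group("AAAA", 3)
  res1 <- dbec_filter(single)
  expect_equal(nrow(res1$molecules), 1L)
  # empty table: empty result, no error
  res0 <- dbec_filter(umi_group(character(0), integer(0)))
  expect_equal(nrow(res0$molecules), 0L)
})

test_that("DBEC never removes a feature's top molecule", {
  set.seed(77)
  for (i in 1:50) {
    k <- sample(2:12, 1)
    reads <- sample(c(1:3, 30:60), k, replace = TRUE)
    m <- umi_group(random_umi_group(k, len = 6L)$umis, reads)
    res <- dbec_filter(m)
    expect_true(max(reads) %in% res$molecules$reads)
    # and matches the oracle's removal decision
    low <- oracle_dbec_low_class(log2(sort(reads)))
    expect_equal(nrow(res$removed), length(low))
  }
})

test_that("cell calling finds the planted knee exactly", {
  cfg <- sim_config(seed = 12, n_real_cells = 100L,
                    n_noise_barcodes = 900L, reads_per_real_cell = 2000,
                    reads_per_noise_barcode = 20, n_clonotypes = 60L)
  sim <- generate_molecule_table(cfg)
  gene_mol <- sim$molecules[!feature %in% sim$truth$tag_names]
  res <- call_cells(as_molecule_table(gene_mol))
  expect_length(res$valid_labels, 100L)
  expect_identical(res$inflection_rank, 100L)
  expect_setequal(res$valid_labels, sim$truth$real_cells)
})

test_that("cell calling handles flat curves and input order", {
  flat <- as_molecule_table(data.frame(
    cell_label = sprintf("c%02d", 1:20), umi = random_dna_fixture(20),
    feature = "G1", reads = 50L))
  res <- call_cells(flat)
  expect_length(res$valid_labels, 20L)
  expect_true(is.na(res$inflection_rank))

  cfg <- tiny_config(seed = 13)
  sim <- generate_molecule_table(cfg)
  shuffled <- sim$molecules[sample(.N)]
  expect_identical(call_cells(sim$molecules)$valid_labels,
                   call_cells(as_molecule_table(shuffled))$valid_labels)

  expect_error(call_cells(umi_group(c("AAAA", "AAAC"), c(5, 5))),
               "at least 3")
})

test_that("demultiplexing applies the threshold rule", {
  mk <- function(counts) {
    df <- do.call(rbind, lapply(names(counts), function(cell) {
      data.frame(cell_label = cell, umi = random_dna_fixture(3),
                 feature = c("S1", "S2", "S3"),
                 reads = counts[[cell]], stringsAsFactors = FALSE)
    }))
    as_molecule_table(df[df$reads > 0, ])
  }
  thr <- c(S1 = 5, S2 = 5, S3 = 5)
  m <- mk(list(cellA = c(50L, 1L, 0L), cellB = c(50L, 45L, 0L),
               cellC = c(0L, 0L, 1L)))
  res <- demultiplex(m, c("cellA", "cellB", "cellC", "cellD"),
                     thresholds = thr)
  expect_identical(unname(res$assignment["cellA"]), "S1")
  expect_identical(unname(res$assignment["cellB"]), "multiplet")
  expect_identical(unname(res$assignment["cellC"]), "undetermined")
  # a valid label absent from the tag table is undetermined, not an error
  expect_identical(unname(res$assignment["cellD"]), "undetermined")
  expect_error(demultiplex(m, character(0)), "non-empty")
})

test_that("estimated thresholds recover the planted sample of origin", {
  cfg <- clean_config(seed = 14)
  sim <- generate_molecule_table(cfg)
  tag_mol <- as_molecule_table(
    sim$molecules[feature %in% sim$truth$tag_names])
  res <- demultiplex(tag_mol, sim$truth$real_cells,
                     tag_to_sample = setNames(sim$truth$sample_ids,
                                              sim$truth$tag_names))
  expect_identical(res$assignment[sim$truth$real_cells],
                   sim$truth$cell_to_sample)
})

test_that("multiplet rate is recovered within 2 percentage points", {
  cfg <- sim_config(seed = 15, n_real_cells = 3000L,
                    n_noise_barcodes = 100L, reads_per_real_cell = 400,
                    reads_per_noise_barcode = 8, n_clonotypes = 900L,
                    multiplet_rate = 0.05)
  sim <- generate_molecule_table(cfg)
  tag_mol <- as_molecule_table(
    sim$molecules[feature %in% sim$truth$tag_names])
  res <- demultiplex(tag_mol, sim$truth$real_cells)
  rate <- mean(res$assignment == "multiplet")
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("molecule tables round-trip through TSV", {
  sim <- generate_molecule_table(tiny_config(seed = 16))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_molecule_table(sim$molecules, path)
  back <- read_molecule_table(path)
  expect_identical(as.data.frame(back), as.data.frame(sim$molecules))
})
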