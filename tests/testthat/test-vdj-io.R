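test_that("read_contigs validates and filters the dialect", {
  d <- withr::local_tempdir()
  f <- file.path(d, "contigs.csv")
  tbl <- dplyr::bind_rows(
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("BBB-1", "TRA", "TGTGCAGCCTTT"),
    toy_contig("CCC-1", "IGH", "TGTGCAGCGTTT"),
    toy_contig("DDD-1", "TRB", "TGTGCAGCTTTT") |>
      dplyr::mutate(is_cell = FALSE))
  write_contigs(tbl, f)
  expect_message(res <- read_contigs(f), "dropped 1 non-cell and 1")
  expect_equal(nrow(res), 2)
  expect_setequal(res$barcode, c("AAA-1", "BBB-1"))

  # single valid TRB row
  f2 <- file.path(d, "one.csv")
  write_contigs(toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"), f2)
  expect_equal(nrow(read_contigs(f2)), 1)

  # missing mandatory column is named in the error
  f3 <- file.path(d, "bad.csv")
  readr::write_csv(dplyr::select(tbl, -cdr3_nt), f3)
  expect_error(read_contigs(f3), "cdr3_nt",
               class = "tcrscreen_format_error")
})

test_that("unproductive contigs survive reading but not filter_productive", {
  d <- withr::local_tempdir()
  f <- file.path(d, "contigs.csv")
  tbl <- dplyr::bind_rows(
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("AAA-1", "TRA", "TGTGCAGCCTT", productive = FALSE))
  write_contigs(tbl, f)
  res <- read_contigs(f)
  expect_equal(nrow(res), 2)
  expect_equal(nrow(filter_productive(res)), 1)
})

test_that("fixture contig tables round-trip through write and read", {
  spec <- fixture("M1")
  orig <- spec$conditions[["TMG-1"]]$contigs
  d <- withr::local_tempdir()
  f <- file.path(d, "roundtrip.csv")
  write_contigs(orig, f)
  back <- suppressMessages(read_contigs(f))
  expect_equal(as.data.frame(back), as.data.frame(orig))
})

test_that("filter_productive keeps the highest-UMI duplicate", {
  dup <- dplyr::bind_rows(
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT", umis = 3,
               contig_id = "c1"),
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT", umis = 7,
               contig_id = "c2"))
  out <- filter_productive(dup)
  expect_equal(nrow(out), 1)
  expect_equal(out$umis, 7L)
  expect_equal(nrow(filter_productive(dup[0, ])), 0)
})

test_that("group_cells assigns paired, mixed and undetectable status", {
  tbl <- dplyr::bind_rows(
    # one beta, two distinct alphas: paired dual-alpha cell
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("AAA-1", "TRA", "TGTGCAGCCTTT"),
    toy_contig("AAA-1", "TRA", "TGTGCTGCCTTT"),
    # two distinct betas: mixed
    toy_contig("BBB-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("BBB-1", "TRB", "TGTCAAGCATTT"),
    # alpha only: undetectable
    toy_contig("CCC-1", "TRA", "TGTGCAGCGTTT"),
    # two identical-CDR3 beta contigs (allelic duplicate): paired
    toy_contig("DDD-1", "TRB", "TGTGCAGCTTTT", umis = 4, contig_id = "d1"),
    toy_contig("DDD-1", "TRB", "TGTGCAGCTTTT", umis = 2, contig_id = "d2"))
  cells <- group_cells(filter_productive(tbl))
  st <- setNames(cells$status, cells$barcode)
  expect_equal(st[["AAA-1"]], "paired")
  expect_equal(cells$n_alpha[cells$barcode == "AAA-1"], 2L)
  expect_equal(st[["BBB-1"]], "mixed")
  expect_equal(st[["CCC-1"]], "undetectable")
  expect_equal(st[["DDD-1"]], "paired")
})

test_that("clonotype partition matches brute-force string grouping", {
  # random instance up to 500 cells from the droplet simulator
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 60, seed = 41))
  sim <- simulate_condition(
    rep, droplet_params(target_recovery = 500, doublet_rate = 0,
                        cdr3_error_rate = 0),
    activation_model(), "stim", seed = 42)
  cells <- sim$contigs |> filter_productive() |> group_cells()
  clono <- call_clonotypes(cells)
  paired <- dplyr::filter(cells, status == "paired")

  # independent oracle: split barcodes by exact CDR3-beta string match
  oracle <- split(paired$barcode, paired$cdr3b_nt)
  expect_equal(length(oracle), nrow(clono))
  got <- setNames(clono$barcodes, clono$cdr3b_nt)
  for (k in names(oracle)) {
    expect_setequal(got[[k]], oracle[[k]])
  }
  expect_equal(sum(clono$n_cells), nrow(paired))
})

test_that("clonotype calling is invariant to contig row order", {
  spec <- fixture("CC3")
  contigs <- spec$conditions[["PP-2"]]$contigs
  cells1 <- contigs |> filter_productive() |> group_cells()
  set.seed(1)
  shuffled <- contigs[sample(nrow(contigs)), ]
  cells2 <- shuffled |> filter_productive() |> group_cells()
  expect_equal(call_clonotypes(cells1), call_clonotypes(cells2))
})

test_that("clonotype identity is nucleotide-level, not amino-acid-level", {
  nt1 <- "TGTGCAAGCAGCTTT"
  nt2 <- "TGTGCAAGCAGTTTT" # synonymous change in codon 4 (AGC -> AGT)
  expect_equal(tcrscreen:::translate_nt(nt1), tcrscreen:::translate_nt(nt2))
  tbl <- dplyr::bind_rows(toy_contig("AAA-1", "TRB", nt1),
                          toy_contig("BBB-1", "TRB", nt2))
  clono <- call_clonotypes(group_cells(filter_productive(tbl)))
  expect_equal(nrow(clono), 2)
})

test_that("cells sharing CDR3-beta but not alpha form one clonotype", {
  tbl <- dplyr::bind_rows(
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("AAA-1", "TRA", "TGTGCAGCCTTT"),
    toy_contig("BBB-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("BBB-1", "TRA", "TGTACAGCCTTT"))
  clono <- call_clonotypes(group_cells(filter_productive(tbl)))
  expect_equal(nrow(clono), 1)
  expect_equal(clono$n_cells, 2L)
  expect_equal(clono$n_alpha_variants, 2L)
})
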