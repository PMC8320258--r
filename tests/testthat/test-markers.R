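test_that("marker matrices read identically from MatrixMarket and CSV", {
  d <- withr::local_tempdir()
  prof <- dplyr::bind_rows(
    toy_profile("AAA-1", ifng = 12),
    toy_profile("BBB-1", il2 = 3, cd4 = 2),
    toy_profile("CCC-1", cd8a = 1, cd8b = 4))
  names(prof) <- c("barcode", tcrscreen:::MARKER_FEATURES)
  write_marker_matrix(prof, file.path(d, "mm"))
  long <- tidyr::pivot_longer(prof, -barcode, names_to = "feature",
                              values_to = "umi_count") |>
    dplyr::filter(umi_count > 0)
  readr::write_csv(long, file.path(d, "long.csv"))

  a <- read_marker_matrix(file.path(d, "mm"))
  b <- read_marker_matrix(file.path(d, "long.csv"))
  expect_equal(a, b)
  expect_equal(a$ifng[a$barcode == "AAA-1"], 12L)
  expect_equal(unlist(a[a$barcode == "AAA-1", -1], use.names = FALSE),
               c(12L, 0L, 0L, 0L, 0L))
})

test_that("marker reading validates features and merges duplicates", {
  d <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(barcode = "AAA-1", feature = "GZMB",
                                  umi_count = 1),
                   file.path(d, "bad.csv"))
  expect_error(read_marker_matrix(file.path(d, "bad.csv")),
               class = "tcrscreen_format_error")

  readr::write_csv(tibble::tibble(barcode = c("AAA-1", "AAA-1"),
                                  feature = c("IFNG", "IFNG"),
                                  umi_count = c(2, 3)),
                   file.path(d, "dup.csv"))
  expect_warning(res <- read_marker_matrix(file.path(d, "dup.csv")),
                 "duplicate")
  expect_equal(res$ifng, 5L)

  # empty long table gives an empty profile table
  readr::write_csv(tibble::tibble(barcode = character(),
                                  feature = character(),
                                  umi_count = integer()),
                   file.path(d, "empty.csv"))
  expect_equal(nrow(read_marker_matrix(file.path(d, "empty.csv"))), 0)
})

test_that("fixture marker files round-trip the generator totals", {
  d <- withr::local_tempdir()
  spec <- make_fixture("CC3", out_dir = d)
  prof <- spec$conditions[["PP-2"]]$profiles
  back <- read_marker_matrix(file.path(d, "markers_PP-2"))
  expect_equal(sum(back$ifng), sum(prof$IFNG))
  expect_equal(sum(back$il2), sum(prof$IL2))
  expect_equal(sum(back$cd4), sum(prof$CD4))
  expect_equal(sum(back$cd8a) + sum(back$cd8b),
               sum(prof$CD8A) + sum(prof$CD8B))
  expect_setequal(back$barcode, prof$barcode)
})

test_that("lineage calls follow the two-or-more-UMIs rule", {
  prof <- dplyr::bind_rows(
    toy_profile("a", cd4 = 2),                 # CD4 at the boundary
    toy_profile("b", cd4 = 1),                 # below threshold
    toy_profile("c", cd8a = 1, cd8b = 1),      # combined CD8 rule
    toy_profile("d", cd4 = 3, cd8a = 2),       # both lineages
    toy_profile("e"))
  out <- lineage_call(prof)
  expect_equal(out$lineage,
               c("CD4", "unassigned", "CD8", "double_positive",
                 "unassigned"))
})

test_that("activation calls are boundary-inclusive", {
  th <- activation_thresholds(ifng_min = 5, il2_min = 5)
  out <- activation_call(dplyr::bind_rows(
    toy_profile("a", ifng = 0),
    toy_profile("b", ifng = 5),
    toy_profile("c", ifng = 4),
    toy_profile("d", il2 = 5)), th)
  expect_equal(out$activated, c(FALSE, TRUE, FALSE, TRUE))
  expect_error(activation_thresholds(ifng_min = 0),
               class = "tcrscreen_config_error")
})

test_that("positivity calls are monotone in every marker count", {
  set.seed(99)
  base <- tibble::tibble(
    barcode = sprintf("bc%03d", 1:50),
    ifng = rpois(50, 3), il2 = rpois(50, 3), cd4 = rpois(50, 2),
    cd8a = rpois(50, 1), cd8b = rpois(50, 1))
  before <- call_markers(base)
  cd4_pos <- function(x) x$lineage %in% c("CD4", "double_positive")
  cd8_pos <- function(x) x$lineage %in% c("CD8", "double_positive")
  for (col in c("ifng", "il2", "cd4", "cd8a", "cd8b")) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] + 1L
    after <- call_markers(bumped)
    expect_true(all(after$ifng_pos >= before$ifng_pos), label = col)
    expect_true(all(after$il2_pos >= before$il2_pos), label = col)
    expect_true(all(cd4_pos(after) >= cd4_pos(before)), label = col)
    expect_true(all(cd8_pos(after) >= cd8_pos(before)), label = col)
  }
})
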