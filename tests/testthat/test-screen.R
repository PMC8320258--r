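test_that("join_condition returns exactly the activated barcodes", {
  cells <- group_cells(filter_productive(dplyr::bind_rows(
    toy_contig("AAA-1", "TRB", "TGTGCAGCATTT"),
    toy_contig("AAA-1", "TRA", "TGTGCAGCCTTT"),
    toy_contig("BBB-1", "TRB", "TGTCAAGCATTT"))))
  prof <- dplyr::bind_rows(
    toy_profile("AAA-1", ifng = 40),   # activated, paired
    toy_profile("BBB-1", ifng = 1),    # not activated
    toy_profile("XXX-1", ifng = 25))   # activated, marker-only
  act <- join_condition(cells, prof, condition = "PP-1")
  expect_setequal(act$barcode, c("AAA-1", "XXX-1"))
  expect_equal(act$clonotype_key[act$barcode == "AAA-1"], "TGTGCAGCATTT")
  expect_equal(act$vdj_status[act$barcode == "XXX-1"], "undetectable")
  lg <- attr(act, "log")
  expect_equal(lg$n_marker_only, 1)
  expect_equal(lg$n_activated_undetectable, 1)
})

test_that("M1 activated cells equal the planted responder set", {
  spec <- fixture("M1")
  res <- fixture_result("M1")
  act <- dplyr::filter(res$screen$activated, condition == "TMG-1")
  responders <- spec$truth$barcodes |>
    dplyr::filter(condition == "TMG-1", responding)
  expect_equal(nrow(act), 26)
  expect_setequal(act$barcode, responders$barcode)
})

test_that("autoreactive removal is clonotype-level and idempotent", {
  act <- tibble::tibble(
    condition = c("DMSO", "PP-1", "PP-1", "PP-1"),
    barcode = c("a", "b", "c", "d"),
    clonotype_key = c("K1", "K1", "K2", "K3"),
    vdj_status = "paired")
  rem <- remove_autoreactive(act, "DMSO")
  expect_equal(rem$autoreactive$clonotype_key, "K1")
  expect_setequal(rem$activated$clonotype_key, c("K2", "K3"))
  rem2 <- remove_autoreactive(rem$activated, "DMSO",
                              conditions = c("DMSO", "PP-1"))
  expect_equal(rem2$activated, rem$activated)

  # clean control removes nothing; absent control warns
  clean <- remove_autoreactive(act[act$condition != "DMSO", ], "DMSO",
                               conditions = c("DMSO", "PP-1"))
  expect_equal(nrow(clean$autoreactive), 0)
  expect_equal(nrow(clean$activated), 3)
  expect_warning(remove_autoreactive(act, "MOCK"), "not found")
})

test_that("M2 removes its DMSO-responding clonotype from all conditions", {
  res <- fixture_result("M2")
  expect_equal(nrow(res$screen$autoreactive), 1)
  auto_key <- res$screen$autoreactive$clonotype_key
  expect_false(auto_key %in% res$screen$candidates$clonotype_key)
  # paper-style outcome: PP-1 keeps 4 shared + 5 unique candidates
  cnt <- dplyr::count(res$screen$candidates, condition, klass)
  expect_equal(cnt$n[cnt$condition == "PP-1" & cnt$klass == "shared"], 4L)
  expect_equal(cnt$n[cnt$condition == "PP-1" & cnt$klass == "unique"], 5L)
  expect_equal(cnt$n[cnt$condition == "PP-6" & cnt$klass == "shared"], 5L)
  expect_equal(cnt$n[cnt$condition == "PP-6" & cnt$klass == "unique"], 7L)
  # PP-2 activation was entirely autoreactive
  expect_false("PP-2" %in% res$screen$candidates$condition)
})

test_that("candidate extraction counts support and classifies shared/unique", {
  act <- tibble::tibble(
    condition = "PP-1",
    barcode = c("a", "b", "c", "d", "e"),
    ifng = c(30L, 40L, 25L, 60L, 12L), il2 = 0L,
    clonotype_key = c("K1", "K1", "K1", "K1", "K2"),
    vdj_status = "paired",
    cdr3b_aa = "CASSF", v_gene_b = "TRBV9", j_gene_b = "TRBJ2-1",
    umis_b = 5L,
    alphas = list(tibble::tibble(v_gene = "TRAV17", j_gene = "TRAJ6",
                                 cdr3_nt = "TGTGCAGCCTTT",
                                 cdr3_aa = "CAAF", umis = 3L)))
  cand <- extract_candidates(act)
  expect_equal(nrow(cand), 2)
  k1 <- cand[cand$clonotype_key == "K1", ]
  expect_equal(k1$support, 4L)
  expect_equal(k1$klass, "shared")
  expect_equal(k1$ifng_total, 155L)
  expect_equal(cand$klass[cand$clonotype_key == "K2"], "unique")
  expect_equal(k1$cdr3a1_nt, "TGTGCAGCCTTT")
})

test_that("candidate counts conserve activated paired clonotypes", {
  for (fx in c("M2", "CC1")) {
    res <- fixture_result(fx)
    keys <- res$screen$activated |>
      dplyr::filter(vdj_status == "paired",
                    condition != res$negative_control,
                    !clonotype_key %in% res$screen$autoreactive$clonotype_key)
    per_cond <- keys |>
      dplyr::group_by(condition) |>
      dplyr::summarise(n = dplyr::n_distinct(clonotype_key),
                       .groups = "drop")
    cand_cond <- dplyr::count(res$screen$candidates, condition)
    joined <- dplyr::left_join(per_cond, cand_cond, by = "condition")
    expect_equal(joined$n.x, joined$n.y, label = fx)
  }
})

test_that("support never exceeds the clonotype's merged cell count", {
  res <- fixture_result("CC1")
  counts <- res$frequencies |> tibble::as_tibble()
  merged_count <- setNames(counts$n_cells, counts$cdr3b_nt)
  cand <- res$screen$candidates
  present <- cand$clonotype_key %in% names(merged_count)
  expect_true(all(cand$support[present] <=
                    merged_count[cand$clonotype_key[present]]))
  # absent keys are singleton clonotypes: support must be 1
  expect_true(all(cand$support[!present] == 1L))
})

test_that("ranking matches an independent sort oracle", {
  cand <- fixture_result("CC1")$screen$candidates |>
    dplyr::filter(condition == "PP-3")
  oracle <- cand[order(match(cand$klass, c("shared", "unique")),
                       -cand$support, -cand$ifng_total,
                       cand$clonotype_key), ]
  expect_equal(cand$clonotype_key, oracle$clonotype_key)
  expect_equal(cand$rank, seq_len(nrow(cand)))
  # class precedence and IFN-gamma tie-break on a toy set
  toy <- tibble::tibble(
    condition = "x",
    clonotype_key = c("B", "A", "C"),
    support = c(1L, 2L, 1L),
    ifng_total = c(40L, 10L, 12L),
    klass = c("unique", "shared", "unique"))
  ranked <- rank_candidates(toy)
  expect_equal(ranked$clonotype_key, c("A", "B", "C"))
})

test_that("IL-2-only activated cells are logged and cannot become candidates", {
  res <- fixture_result("CC1")
  logs <- res$screen$log
  expect_equal(logs[["PP-2"]]$n_il2_only, 1)
  il2_only <- res$screen$activated |>
    dplyr::filter(il2_pos, !ifng_pos, condition == "PP-2")
  expect_equal(nrow(il2_only), 1)
  expect_equal(il2_only$vdj_status, "undetectable")
  expect_equal(sum(res$screen$activated$condition == "PP-2"), 18)
})
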