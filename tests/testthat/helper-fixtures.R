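# Fixture and suite results are deterministic (fixed documented seeds), so
# they are generated once per test run and shared across test files.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, expr, envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

fixture <- function(name) {
  cached(paste0("fixture_", name), make_fixture(name))
}

fixture_result <- function(name) {
  cached(paste0("result_", name), {
    spec <- fixture(name)
    run_specimen(list(specimen = name, conditions = spec$conditions,
                      negative_control = spec$negative_control,
                      truth = spec$truth))
  })
}

full_suite <- function() {
  cached("suite", {
    results <- lapply(fixture_names(), fixture_result)
    names(results) <- fixture_names()
    validations <- lapply(fixture_names(), function(fx) {
      evaluate_candidates(results[[fx]]$screen$candidates,
                          fixture(fx)$truth, specimen = fx)
    })
    list(results = results, summary = summarize_suite(validations))
  })
}

# minimal hand-built contig tibble for unit tests
toy_contig <- function(barcode, chain, cdr3_nt, umis = 5L,
                       productive = TRUE, contig_id = NULL,
                       v_gene = "TRBV9", j_gene = "TRBJ2-1") {
  aa <- tcrscreen:::translate_nt(cdr3_nt)
  tibble::tibble(
    barcode = barcode, is_cell = TRUE,
    contig_id = contig_id %||% paste0(barcode, "_", chain, "_", cdr3_nt),
    chain = chain, v_gene = v_gene, j_gene = j_gene,
    cdr3 = ifelse(productive, aa, "None"), cdr3_nt = cdr3_nt,
    umis = as.integer(umis), productive = productive)
}

`%||%` <- rlang::`%||%`

# marker profile row helper
toy_profile <- function(barcode, ifng = 0L, il2 = 0L, cd4 = 0L,
                        cd8a = 0L, cd8b = 0L) {
  tibble::tibble(barcode = barcode, ifng = as.integer(ifng),
                 il2 = as.integer(il2), cd4 = as.integer(cd4),
                 cd8a = as.integer(cd8a), cd8b = as.integer(cd8b))
}
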