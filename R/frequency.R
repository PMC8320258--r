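#' Merge the per-condition runs of one specimen
#'
#' Combines the paired (clonotype-keyed) cells of every stimulation
#' condition of a specimen into one table, namespacing barcodes by
#' condition so droplet barcodes reused across channels cannot collide.
#'
#' @param cell_tables Named list of [group_cells()] outputs, one per
#'   condition.
#' @return Tibble of merged paired cells: `condition`, `barcode`,
#'   `merged_barcode`, `cdr3b_nt`.
#' @export
merge_conditions <- function(cell_tables) {
  merged <- purrr::imap(cell_tables, function(cells, label) {
    cells |>
      filter(.data$status == "paired") |>
      mutate(condition = label,
             merged_barcode = paste(label, .data$barcode, sep = ":")) |>
      select("condition", "barcode", "merged_barcode", "cdr3b_nt")
  }) |>
    bind_rows()
  if (anyDuplicated(merged$merged_barcode)) {
    abort_data("duplicate namespaced barcode after merging conditions.")
  }
  merged
}

#' Clonotype frequencies after singleton removal
#'
#' Counts merged cells per clonotype, removes clonotypes detected only once
#' (singletons are mostly sequencing-error or doublet artifacts), and
#' computes each retained clonotype's frequency as its share of the
#' retained cells.
#'
#' @param merged Output of [merge_conditions()] (or any tibble with a
#'   `cdr3b_nt` column, one row per cell).
#' @return A `tcr_frequency` tibble: `cdr3b_nt`, `n_cells`, `frequency`,
#'   with attributes `retained_total`, `dropped_singletons` and
#'   `merged_total`.
#' @export
compute_frequencies <- function(merged) {
  if (nrow(merged) == 0) abort_data("merged table is empty.")
  counts <- merged |> count(.data$cdr3b_nt, name = "n_cells")
  dropped <- sum(counts$n_cells == 1L)
  retained <- counts |> filter(.data$n_cells >= 2L)
  if (nrow(retained) == 0) {
    warn("all clonotypes are singletons; frequency table is empty.")
  }
  total <- sum(retained$n_cells)
  out <- retained |>
    mutate(frequency = .data$n_cells / total) |>
    arrange(desc(.data$n_cells), .data$cdr3b_nt)
  structure(out, retained_total = total, dropped_singletons = dropped,
            merged_total = nrow(merged),
            class = c("tcr_frequency", class(out)))
}

#' Annotate candidate TCRs with merged clonotype frequencies
#'
#' One row per distinct candidate clonotype (deduplicated across eliciting
#' conditions, keeping the shared class and maximal support), with its
#' merged cell count and frequency; clonotypes dropped as singletons get
#' `NA` frequency (detected once, frequency not calculated). The summed
#' frequency of all candidate clonotypes is stored in the
#' `"candidate_frequency_total"` attribute.
#'
#' @param freq A [compute_frequencies()] table.
#' @param candidates A candidate tibble from [extract_candidates()].
#' @return Annotated candidate-frequency tibble.
#' @export
annotate_candidates <- function(freq, candidates) {
  if (nrow(candidates) == 0) {
    out <- tibble(clonotype_key = character(), klass = character(),
                  support = integer(), n_cells = integer(),
                  frequency = numeric())
    attr(out, "candidate_frequency_total") <- 0
    return(out)
  }
  dedup <- candidates |>
    arrange(match(.data$klass, c("shared", "unique")),
            desc(.data$support)) |>
    distinct(.data$clonotype_key, .keep_all = TRUE)
  out <- dedup |>
    left_join(as_tibble(freq) |> rename(clonotype_key = "cdr3b_nt"),
              by = "clonotype_key") |>
    select("clonotype_key", "klass", "support", "condition", "cdr3b_aa",
           "n_cells", "frequency") |>
    arrange(desc(dplyr::coalesce(.data$frequency, -1)), .data$clonotype_key)
  attr(out, "candidate_frequency_total") <-
    sum(out$frequency, na.rm = TRUE)
  out
}
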