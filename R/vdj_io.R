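CONTIG_COLUMNS <- c("barcode", "is_cell", "contig_id", "chain", "v_gene",
                    "j_gene", "cdr3", "cdr3_nt", "umis", "productive")

as_logical_flag <- function(x) {
  if (is.logical(x)) return(x)
  toupper(as.character(x)) %in% c("TRUE", "T", "1", "YES")
}

#' Read a contig annotation table
#'
#' Reads the `filtered_contig_annotations.csv` dialect (columns `barcode`,
#' `is_cell`, `contig_id`, `chain`, `v_gene`, `j_gene`, `cdr3`, `cdr3_nt`,
#' `umis`, `productive`; extra columns are tolerated). Rows with
#' `is_cell = False` or a chain other than TRA/TRB are dropped with a
#' message; unproductive contigs are retained here and removed later by
#' [filter_productive()].
#'
#' @param path Path to a contig CSV.
#' @return A tibble of contig records.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(CONTIG_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort_format(paste0("contig table is missing mandatory column(s): ",
                        semicolon(missing_cols), "."))
  }
  raw <- raw |>
    select(dplyr::all_of(CONTIG_COLUMNS)) |>
    mutate(is_cell = as_logical_flag(.data$is_cell),
           productive = as_logical_flag(.data$productive),
           umis = as.integer(.data$umis))
  bad_umis <- which(is.na(raw$umis) | raw$umis < 0L)
  if (length(bad_umis)) {
    abort_format(paste0("malformed `umis` values at data row(s): ",
                        semicolon(head(bad_umis, 10)), "."))
  }
  n_not_cell <- sum(!raw$is_cell)
  n_other_chain <- sum(raw$is_cell & !raw$chain %in% c("TRA", "TRB"))
  if (n_not_cell + n_other_chain > 0) {
    inform(sprintf(
      "read_contigs: dropped %d non-cell and %d non-TRA/TRB contig row(s).",
      n_not_cell, n_other_chain))
  }
  raw |> filter(.data$is_cell, .data$chain %in% c("TRA", "TRB"))
}

#' Write a contig annotation table
#'
#' Writes the same CSV dialect [read_contigs()] reads, with `True`/`False`
#' logical encoding and the exact column order of the format.
#'
#' @param contigs A contig tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  out <- contigs |>
    select(dplyr::all_of(CONTIG_COLUMNS)) |>
    mutate(is_cell = if_else(as_logical_flag(.data$is_cell), "True", "False"),
           productive = if_else(as_logical_flag(.data$productive),
                                "True", "False"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep productive contigs, one per (barcode, chain, CDR3 nt)
#'
#' Retains `productive = TRUE` TRA/TRB contigs; among duplicates sharing
#' barcode, chain and CDR3 nucleotide sequence (e.g. allelic duplicates),
#' the contig with the highest UMI support is kept.
#'
#' @param contigs A contig tibble from [read_contigs()].
#' @return Filtered contig tibble.
#' @export
filter_productive <- function(contigs) {
  contigs |>
    filter(.data$productive) |>
    arrange(.data$barcode, .data$chain, .data$cdr3_nt, desc(.data$umis),
            .data$contig_id) |>
    distinct(.data$barcode, .data$chain, .data$cdr3_nt, .keep_all = TRUE)
}

#' Collapse contigs to per-cell paired-chain records
#'
#' One row per barcode. A cell is `paired` when it has exactly one distinct
#' productive CDR3-beta nucleotide sequence (one or two alpha chains may
#' accompany it), `mixed` when it has two or more distinct beta sequences
#' (doublet signature), and `undetectable` when no productive TRB contig was
#' recovered.
#'
#' @param contigs Productive-filtered contig tibble.
#' @return A tibble with columns `barcode`, `status`, beta-chain fields
#'   (`cdr3b_nt`, `cdr3b_aa`, `v_gene_b`, `j_gene_b`, `umis_b`), `n_alpha`,
#'   and a list-column `alphas` of TRA contigs.
#' @export
group_cells <- function(contigs) {
  trb <- contigs |> filter(.data$chain == "TRB")
  n_beta <- trb |>
    group_by(.data$barcode) |>
    summarise(n_beta = dplyr::n_distinct(.data$cdr3_nt), .groups = "drop")
  # representative beta: highest UMI support, ties by contig_id
  beta <- trb |>
    arrange(.data$barcode, desc(.data$umis), .data$contig_id) |>
    distinct(.data$barcode, .keep_all = TRUE) |>
    left_join(n_beta, by = "barcode") |>
    mutate(status = if_else(.data$n_beta >= 2L, "mixed", "paired"))
  alpha <- contigs |>
    filter(.data$chain == "TRA") |>
    select("barcode", "v_gene", "j_gene", "cdr3_nt", cdr3_aa = "cdr3",
           "umis") |>
    tidyr::nest(.by = "barcode", .key = "alphas")
  cells <- dplyr::full_join(beta, alpha, by = "barcode") |>
    mutate(status = dplyr::coalesce(.data$status, "undetectable"),
           n_alpha = vapply(.data$alphas,
                            function(a) if (is.null(a)) 0L else nrow(a),
                            integer(1)))
  cells |>
    mutate(cdr3b_nt = if_else(.data$status == "paired", .data$cdr3_nt,
                              NA_character_)) |>
    select("barcode", "status", "cdr3b_nt",
           cdr3b_aa = "cdr3", v_gene_b = "v_gene", j_gene_b = "j_gene",
           umis_b = "umis", "n_alpha", "alphas") |>
    arrange(.data$barcode)
}

#' Call clonotypes by CDR3-beta nucleotide identity
#'
#' Partitions paired cells into clonotypes keyed by the exact CDR3-beta
#' nucleotide sequence (nucleotide, not amino-acid, identity: a silent
#' change yields a distinct clonotype). Mixed and undetectable cells are
#' excluded from membership.
#'
#' @param cells Output of [group_cells()].
#' @return A tibble with one row per clonotype: `cdr3b_nt` (the key),
#'   representative beta annotation, `n_cells`, `n_alpha_variants`, and a
#'   list-column `barcodes`.
#' @export
call_clonotypes <- function(cells) {
  paired <- cells |> filter(.data$status == "paired")
  if (nrow(paired) == 0) {
    return(tibble(cdr3b_nt = character(), cdr3b_aa = character(),
                  v_gene_b = character(), j_gene_b = character(),
                  n_cells = integer(), n_alpha_variants = integer(),
                  barcodes = list()))
  }
  counts <- paired |> count(.data$cdr3b_nt, name = "n_cells")
  # representative beta: highest-UMI member, ties by barcode
  rep_beta <- paired |>
    arrange(.data$cdr3b_nt, desc(.data$umis_b), .data$barcode) |>
    distinct(.data$cdr3b_nt, .keep_all = TRUE) |>
    select("cdr3b_nt", "cdr3b_aa", "v_gene_b", "j_gene_b")
  alpha_var <- paired |>
    select("cdr3b_nt", "alphas") |>
    mutate(alphas = purrr::map(.data$alphas,
                               function(a) if (is.null(a))
                                 character() else a$cdr3_nt)) |>
    tidyr::unnest("alphas", keep_empty = FALSE) |>
    group_by(.data$cdr3b_nt) |>
    summarise(n_alpha_variants = dplyr::n_distinct(.data$alphas),
              .groups = "drop")
  ordered <- paired |> arrange(.data$cdr3b_nt, .data$barcode)
  bc_split <- vctrs::vec_split(ordered$barcode, ordered$cdr3b_nt)
  barcodes <- tibble(cdr3b_nt = bc_split$key, barcodes = bc_split$val)
  rep_beta |>
    left_join(counts, by = "cdr3b_nt") |>
    left_join(alpha_var, by = "cdr3b_nt") |>
    left_join(barcodes, by = "cdr3b_nt") |>
    mutate(n_alpha_variants = dplyr::coalesce(.data$n_alpha_variants, 0L)) |>
    select("cdr3b_nt", "cdr3b_aa", "v_gene_b", "j_gene_b", "n_cells",
           "n_alpha_variants", "barcodes") |>
    arrange(desc(.data$n_cells), .data$cdr3b_nt)
}

#' Write a clonotype table
#'
#' @param clonotypes Output of [call_clonotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(clonotypes, path) {
  out <- clonotypes |>
    mutate(barcodes = vapply(.data$barcodes, semicolon, character(1))) |>
    select("cdr3b_nt", "cdr3b_aa", "v_gene_b", "j_gene_b", "n_cells",
           "n_alpha_variants", "barcodes")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
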