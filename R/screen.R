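#' Join marker flags to clonotyped cells for one condition
#'
#' Returns the activated cells of one stimulation condition: exactly the
#' barcodes whose activation call is positive (IFN-gamma or IL-2), annotated
#' with their clonotype key and V(D)J status. Activated barcodes seen only
#' in the marker matrix are retained with `vdj_status = "undetectable"`
#' (they can never become candidates); contig-only barcodes have no marker
#' evidence and are dropped from the activated table. Both counts are
#' recorded in the `"log"` attribute.
#'
#' @param cells Per-cell records from [group_cells()].
#' @param profiles Marker profiles from [read_marker_matrix()].
#' @param thresholds An [activation_thresholds()].
#' @param condition Condition label stamped on the output.
#' @return Tibble of activated cells: `condition`, `barcode`, `ifng`, `il2`,
#'   `ifng_pos`, `il2_pos`, `lineage`, `clonotype_key`, `vdj_status`, plus
#'   the `alphas` list-column carried from `cells`.
#' @export
join_condition <- function(cells, profiles,
                           thresholds = activation_thresholds(),
                           condition = "stim") {
  flags <- call_markers(profiles, thresholds)
  n_marker_only <- sum(!flags$barcode %in% cells$barcode)
  n_contig_only <- sum(!cells$barcode %in% flags$barcode)
  activated <- flags |>
    filter(.data$activated) |>
    left_join(cells, by = "barcode") |>
    mutate(condition = condition,
           vdj_status = dplyr::coalesce(.data$status, "undetectable"),
           clonotype_key = if_else(.data$vdj_status == "paired",
                                   .data$cdr3b_nt, NA_character_)) |>
    select("condition", "barcode", "ifng", "il2", "ifng_pos", "il2_pos",
           "lineage", "clonotype_key", "vdj_status", "cdr3b_aa",
           "v_gene_b", "j_gene_b", "umis_b", "alphas")
  attr(activated, "log") <- list(
    condition = condition,
    n_profiles = nrow(profiles), n_cells = nrow(cells),
    n_activated = nrow(activated),
    n_marker_only = n_marker_only, n_contig_only = n_contig_only,
    n_activated_mixed = sum(activated$vdj_status == "mixed"),
    n_activated_undetectable = sum(activated$vdj_status == "undetectable"),
    n_il2_only = sum(activated$il2_pos & !activated$ifng_pos))
  activated
}

#' Remove autoreactive clonotypes using the negative control
#'
#' A clonotype with at least one activated cell in the negative-control
#' condition responds without antigen and is not antigen-specific; it is
#' removed from candidate consideration in every condition. Removal is
#' clonotype-level (all cells of the clonotype everywhere), not cell-level,
#' and is idempotent.
#'
#' @param activated Activated cells across all conditions (rows from
#'   [join_condition()], bound together).
#' @param negative_control Label of the negative-control condition. If no
#'   such condition was screened a warning is raised and nothing is
#'   removed.
#' @param conditions Labels of all screened conditions (defaults to those
#'   present among activated cells; a control with zero activated cells is
#'   a valid, clean control).
#' @return A list: `activated` (filtered tibble) and `autoreactive` (tibble
#'   of removed clonotype keys with the control-condition cell count).
#' @export
remove_autoreactive <- function(activated, negative_control,
                                conditions = unique(activated$condition)) {
  if (!negative_control %in% conditions) {
    warn(paste0("negative control '", negative_control,
                "' not found among conditions; no autoreactive removal."))
    return(list(activated = activated,
                autoreactive = tibble(clonotype_key = character(),
                                      n_control_cells = integer())))
  }
  auto <- activated |>
    filter(.data$condition == negative_control,
           !is.na(.data$clonotype_key)) |>
    count(.data$clonotype_key, name = "n_control_cells")
  list(
    activated = activated |>
      filter(is.na(.data$clonotype_key) |
               !.data$clonotype_key %in% auto$clonotype_key),
    autoreactive = auto
  )
}

top_alpha_chains <- function(alpha_list) {
  all_a <- bind_rows(purrr::compact(alpha_list))
  if (nrow(all_a) == 0) {
    return(tibble(cdr3a1_nt = NA_character_, cdr3a1_aa = NA_character_,
                  v_gene_a1 = NA_character_, j_gene_a1 = NA_character_,
                  cdr3a2_nt = NA_character_, cdr3a2_aa = NA_character_,
                  v_gene_a2 = NA_character_, j_gene_a2 = NA_character_))
  }
  ranked <- all_a |>
    group_by(.data$cdr3_nt) |>
    summarise(n_cells = n(), umis = sum(.data$umis),
              v_gene = first(.data$v_gene), j_gene = first(.data$j_gene),
              cdr3_aa = first(.data$cdr3_aa), .groups = "drop") |>
    arrange(desc(.data$n_cells), desc(.data$umis), .data$cdr3_nt) |>
    slice_head(n = 2)
  second <- if (nrow(ranked) > 1) ranked[2, ] else
    tibble(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
           v_gene = NA_character_, j_gene = NA_character_)
  tibble(cdr3a1_nt = ranked$cdr3_nt[1], cdr3a1_aa = ranked$cdr3_aa[1],
         v_gene_a1 = ranked$v_gene[1], j_gene_a1 = ranked$j_gene[1],
         cdr3a2_nt = second$cdr3_nt[1], cdr3a2_aa = second$cdr3_aa[1],
         v_gene_a2 = second$v_gene[1], j_gene_a2 = second$j_gene[1])
}

#' Extract candidate TCRs from activated cells
#'
#' One candidate per (condition, clonotype key) with at least one activated
#' paired cell, after autoreactive removal. Support is the number of
#' distinct activated paired cells of that clonotype in that condition;
#' candidates supported by two or more cells are class `shared`, by exactly
#' one cell `unique`. Up to the two most-supported alpha-chain variants
#' observed among the supporting cells are reported.
#'
#' @param activated Activated-cell tibble (autoreactive already removed).
#' @param negative_control Optional control label to exclude from candidate
#'   extraction.
#' @return Tibble of candidates with beta/alpha annotation, `support`,
#'   `ifng_total`, `il2_total` and `klass`.
#' @export
extract_candidates <- function(activated, negative_control = NULL) {
  pool <- activated |>
    filter(.data$vdj_status == "paired", !is.na(.data$clonotype_key))
  if (!is.null(negative_control)) {
    pool <- pool |> filter(.data$condition != negative_control)
  }
  if (nrow(pool) == 0) {
    return(tibble(condition = character(), clonotype_key = character(),
                  support = integer(), klass = character(),
                  ifng_total = integer(), il2_total = integer()))
  }
  pool |>
    group_by(.data$condition, .data$clonotype_key) |>
    summarise(
      support = dplyr::n_distinct(.data$barcode),
      ifng_total = sum(.data$ifng), il2_total = sum(.data$il2),
      cdr3b_aa = first(.data$cdr3b_aa),
      v_gene_b = first(.data$v_gene_b), j_gene_b = first(.data$j_gene_b),
      .alpha = list(top_alpha_chains(.data$alphas)),
      .groups = "drop") |>
    tidyr::unnest(".alpha") |>
    mutate(klass = if_else(.data$support >= 2L, "shared", "unique"))
}

#' Rank candidate TCRs
#'
#' Orders candidates within each condition: shared before unique, then
#' descending support, then descending summed IFN-gamma UMIs over the
#' supporting cells, then ascending clonotype key, and fills `rank` 1..n.
#' The paper-style priority (shared receptors and the strongest responders
#' first) determines which unique candidates are worth testing.
#'
#' @param candidates Tibble from [extract_candidates()].
#' @return The same tibble, ordered, with a `rank` column per condition.
#' @export
rank_candidates <- function(candidates) {
  candidates |>
    arrange(.data$condition, match(.data$klass, c("shared", "unique")),
            desc(.data$support), desc(.data$ifng_total),
            .data$clonotype_key) |>
    group_by(.data$condition) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Run the activation screen over one specimen
#'
#' Joins marker flags to clonotyped cells per condition, removes
#' autoreactive clonotypes via the negative control, extracts candidates
#' and ranks them.
#'
#' @param conditions Named list, one entry per condition, each a list with
#'   `cells` ([group_cells()] output) and `profiles`
#'   ([read_marker_matrix()] output).
#' @param negative_control Label of the negative-control condition.
#' @param thresholds An [activation_thresholds()].
#' @return A `tcr_screen` object: list with `activated`, `candidates`,
#'   `autoreactive`, and `log`.
#' @export
screen_specimen <- function(conditions, negative_control,
                            thresholds = activation_thresholds()) {
  joined <- purrr::imap(conditions, function(cond, label) {
    join_condition(cond$cells, cond$profiles, thresholds, label)
  })
  logs <- purrr::map(joined, attr, "log")
  activated <- bind_rows(joined)
  rem <- remove_autoreactive(activated, negative_control,
                             conditions = names(conditions))
  candidates <- rank_candidates(
    extract_candidates(rem$activated, negative_control))
  structure(list(activated = activated,
                 candidates = candidates,
                 autoreactive = rem$autoreactive,
                 negative_control = negative_control,
                 log = logs),
            class = "tcr_screen")
}

#' @export
print.tcr_screen <- function(x, ...) {
  cat("<tcr_screen>\n")
  cat("  conditions:", semicolon(names(x$log)), "\n")
  cat("  activated cells:", nrow(x$activated), "\n")
  cat("  autoreactive clonotypes removed:", nrow(x$autoreactive), "\n")
  cat(sprintf("  candidates: %d (%d shared, %d unique)\n",
              nrow(x$candidates), sum(x$candidates$klass == "shared"),
              sum(x$candidates$klass == "unique")))
  invisible(x)
}
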