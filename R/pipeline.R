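read_specimen_truth <- function(dir, cfg) {
  if (is.null(cfg$truth)) return(NULL)
  rt <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
  list(clonotypes = rt(cfg$truth$clonotypes),
       barcodes = rt(cfg$truth$barcodes),
       candidates = rt(cfg$truth$candidates))
}

#' Run the full screen on one specimen
#'
#' Executes the whole deterministic analysis for one specimen: read contig
#' tables and marker matrices per condition, filter productive contigs,
#' group cells and call clonotypes, apply activation/lineage thresholds,
#' remove autoreactive clonotypes via the negative control, extract and
#' rank candidates, then merge all conditions and compute clonotype
#' frequencies after singleton removal. Identical inputs give identical
#' outputs.
#'
#' @param config Path to a specimen `config.yaml` (as written by
#'   [make_fixture()]), the directory containing it, or an in-memory
#'   specimen list with `conditions` (each holding `contigs` and
#'   `profiles`) and `negative_control`.
#' @param thresholds An [activation_thresholds()].
#' @param out_dir Optional directory for TSV outputs (`activated_cells.tsv`,
#'   `candidates.tsv`, `autoreactive.tsv`, `frequencies.tsv`,
#'   `candidate_frequencies.tsv`, `summary.json`).
#' @return A `tcr_screen_result` list: `screen` (the [screen_specimen()]
#'   result), `frequencies`, `candidate_frequencies`, `cells` per
#'   condition, `truth` (when available) and `specimen`.
#' @export
run_specimen <- function(config, thresholds = activation_thresholds(),
                         out_dir = NULL) {
  truth <- NULL
  if (is.character(config)) {
    cfg_path <- if (dir.exists(config)) file.path(config, "config.yaml")
                else config
    if (!file.exists(cfg_path)) {
      abort_config(paste0("specimen config not found: ", cfg_path))
    }
    dir <- dirname(cfg_path)
    cfg <- yaml::read_yaml(cfg_path)
    conditions <- list()
    for (cond in cfg$conditions) {
      contigs <- tryCatch(
        read_contigs(file.path(dir, cond$contigs)),
        error = function(e) abort_data(paste0(
          "stage read_contigs failed for condition '", cond$label, "' (",
          cond$contigs, "): ", conditionMessage(e))))
      profiles <- tryCatch(
        read_marker_matrix(file.path(dir, cond$markers)),
        error = function(e) abort_data(paste0(
          "stage read_marker_matrix failed for condition '", cond$label,
          "' (", cond$markers, "): ", conditionMessage(e))))
      conditions[[cond$label]] <- list(contigs = contigs,
                                       profiles = profiles)
    }
    negative_control <- cfg$negative_control
    specimen <- cfg$specimen %||% basename(dir)
    truth <- read_specimen_truth(dir, cfg)
  } else {
    conditions <- lapply(config$conditions, function(x) {
      list(contigs = x$contigs, profiles = x$profiles)
    })
    negative_control <- config$negative_control
    specimen <- config$specimen %||% "specimen"
    truth <- config$truth
  }

  cells <- purrr::map(conditions, function(cond) {
    cond$contigs |> filter_productive() |> group_cells()
  })
  screen <- screen_specimen(
    purrr::map2(cells, conditions,
                function(cl, cond) list(cells = cl,
                                        profiles = cond$profiles)),
    negative_control = negative_control, thresholds = thresholds)
  merged <- merge_conditions(cells)
  freqs <- compute_frequencies(merged)
  cand_freqs <- annotate_candidates(freqs, screen$candidates)

  result <- structure(
    list(specimen = specimen, screen = screen, frequencies = freqs,
         candidate_frequencies = cand_freqs, cells = cells,
         negative_control = negative_control, truth = truth),
    class = "tcr_screen_result")
  if (!is.null(out_dir)) write_screen_result(result, out_dir)
  result
}

drop_list_cols <- function(df) {
  df[!vapply(df, is.list, logical(1))]
}

write_screen_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) readr::write_tsv(drop_list_cols(df),
                                        file.path(out_dir, f),
                                        progress = FALSE)
  w(result$screen$activated, "activated_cells.tsv")
  w(result$screen$candidates, "candidates.tsv")
  w(result$screen$autoreactive, "autoreactive.tsv")
  w(as_tibble(result$frequencies), "frequencies.tsv")
  w(result$candidate_frequencies, "candidate_frequencies.tsv")
  jsonlite::write_json(
    list(specimen = result$specimen,
         log = result$screen$log,
         retained_total = attr(result$frequencies, "retained_total"),
         dropped_singletons = attr(result$frequencies,
                                   "dropped_singletons"),
         candidate_frequency_total =
           attr(result$candidate_frequencies, "candidate_frequency_total")),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Score candidate calls against planted truth
#'
#' A candidate is counted reactive when its clonotype key is truth-flagged
#' reactive (and not autoreactive). Precision is computed per class over
#' the tested candidates only, mirroring the screening practice of testing
#' every shared receptor but only a ranked subset of unique ones: tested
#' flags are taken from `truth$candidates` when present, otherwise all
#' shared candidates and all unique candidates are considered tested.
#'
#' @param candidates Candidate tibble from a screen.
#' @param truth Truth list with `clonotypes` (columns `cdr3b_nt`,
#'   `reactive`, `autoreactive`) and optionally `candidates` (columns
#'   `condition`, `cdr3b_nt`, `tested`).
#' @param specimen Specimen label for the summary row.
#' @return A `tcr_validation` object: list with `summary` (one-row tibble:
#'   tested/reactive counts and precisions per class) and `candidates`
#'   (per-candidate annotation).
#' @export
evaluate_candidates <- function(candidates, truth, specimen = "specimen") {
  reactive_keys <- truth$clonotypes |>
    filter(.data$reactive, !.data$autoreactive) |>
    pull("cdr3b_nt")
  ann <- candidates |>
    mutate(reactive = .data$clonotype_key %in% reactive_keys)
  if (!is.null(truth$candidates) && "tested" %in% names(truth$candidates)) {
    ann <- ann |>
      left_join(truth$candidates |>
                  select("condition", clonotype_key = "cdr3b_nt", "tested"),
                by = c("condition", "clonotype_key")) |>
      mutate(tested = dplyr::coalesce(.data$tested, FALSE))
  } else {
    ann <- ann |> mutate(tested = TRUE)
  }
  class_stats <- function(k) {
    t <- ann |> filter(.data$klass == k, .data$tested)
    n_tested <- nrow(t)
    n_reactive <- sum(t$reactive)
    tibble(n_tested = n_tested, n_reactive = n_reactive,
           precision = if (n_tested == 0) NA_real_
                       else 100 * n_reactive / n_tested)
  }
  sh <- class_stats("shared")
  un <- class_stats("unique")
  summary <- tibble(
    specimen = specimen,
    n_shared_tested = sh$n_tested, n_shared_reactive = sh$n_reactive,
    shared_precision = sh$precision,
    n_unique_tested = un$n_tested, n_unique_reactive = un$n_reactive,
    unique_precision = un$precision,
    total_reactive = sh$n_reactive + un$n_reactive)
  structure(list(summary = summary, candidates = ann),
            class = "tcr_validation")
}

#' Pool validation summaries across specimens
#'
#' Pooled counts are sums over specimens; pooled precisions are recomputed
#' from the pooled counts (never averaged).
#'
#' @param summaries A list of [evaluate_candidates()] results, or a tibble
#'   of their `summary` rows.
#' @return A `tcr_validation_suite` object with `per_specimen` and `pooled`
#'   tibbles.
#' @export
summarize_suite <- function(summaries) {
  per <- if (is.data.frame(summaries)) {
    summaries
  } else {
    bind_rows(purrr::map(summaries, "summary"))
  }
  if (nrow(per) == 0) abort_config("no specimen summaries supplied.")
  pooled <- per |>
    summarise(specimen = "pooled",
              across(c("n_shared_tested", "n_shared_reactive",
                       "n_unique_tested", "n_unique_reactive",
                       "total_reactive"), sum)) |>
    mutate(shared_precision = if_else(.data$n_shared_tested > 0,
                                      100 * .data$n_shared_reactive /
                                        .data$n_shared_tested, NA_real_),
           unique_precision = if_else(.data$n_unique_tested > 0,
                                      100 * .data$n_unique_reactive /
                                        .data$n_unique_tested, NA_real_))
  structure(list(per_specimen = per, pooled = pooled),
            class = "tcr_validation_suite")
}

#' @export
print.tcr_validation_suite <- function(x, ...) {
  cat("<tcr_validation_suite>\n")
  fmt <- function(r) {
    sprintf("  %-8s shared %d/%d (%s%%)  unique %d/%d (%s%%)  reactive %d\n",
            r$specimen, r$n_shared_reactive, r$n_shared_tested,
            ifelse(is.na(r$shared_precision), "NA",
                   round(r$shared_precision)),
            r$n_unique_reactive, r$n_unique_tested,
            ifelse(is.na(r$unique_precision), "NA",
                   round(r$unique_precision)),
            r$total_reactive)
  }
  for (i in seq_len(nrow(x$per_specimen))) cat(fmt(x$per_specimen[i, ]))
  cat(fmt(x$pooled))
  invisible(x)
}

#' Simulate, screen and validate the six reference specimens
#'
#' Generates every fixture with its documented seed, runs the full screen
#' on each, evaluates the candidate calls against the planted truth, and
#' pools the reliability statistics.
#'
#' @param fixtures Fixture names (default all six).
#' @param out_dir Optional directory; when given, fixture inputs and screen
#'   outputs are written under per-specimen subdirectories and a pooled
#'   `summary.json` at the top level.
#' @param thresholds An [activation_thresholds()].
#' @return A `tcr_suite` object: list with `results` (per-specimen
#'   `tcr_screen_result`s), `validation` (per-specimen
#'   [evaluate_candidates()] objects) and `summary`
#'   (a [summarize_suite()] object).
#' @export
run_fixture_suite <- function(fixtures = fixture_names(), out_dir = NULL,
                              thresholds = activation_thresholds()) {
  results <- list()
  validations <- list()
  for (fx in fixtures) {
    fx_dir <- if (is.null(out_dir)) NULL else file.path(out_dir, fx, "input")
    spec <- make_fixture(fx, out_dir = fx_dir)
    res <- run_specimen(
      list(specimen = fx, conditions = spec$conditions,
           negative_control = spec$negative_control, truth = spec$truth),
      thresholds = thresholds,
      out_dir = if (is.null(out_dir)) NULL
                else file.path(out_dir, fx, "screen"))
    results[[fx]] <- res
    validations[[fx]] <- evaluate_candidates(res$screen$candidates,
                                             spec$truth, specimen = fx)
  }
  summary <- summarize_suite(validations)
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(per_specimen = summary$per_specimen, pooled = summary$pooled),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
      dataframe = "rows")
  }
  structure(list(results = results, validation = validations,
                 summary = summary),
            class = "tcr_suite")
}

#' @export
print.tcr_suite <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
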