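VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "tumor_depth",
                     "normal_depth", "tumor_variant_reads", "vaf")

#' Read a somatic variant table
#'
#' Tab-separated table with columns `chrom`, `pos`, `ref`, `alt`,
#' `tumor_depth`, `normal_depth`, `tumor_variant_reads`, `vaf` and optional
#' annotation columns (e.g. `gene`, `effect`).
#'
#' @param path TSV path.
#' @return Variant tibble.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  v <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chrom = "c", ref = "c", alt = "c",
                         .default = readr::col_guess()))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(v))
  if (length(missing_cols)) {
    abort_format(paste0("variant table is missing column(s): ",
                        semicolon(missing_cols), "."))
  }
  v
}

#' Hard-filter somatic variant calls
#'
#' Applies the post-calling criteria for retaining a somatic mutation:
#' tumor and normal read depths of 10 or greater, variant allele frequency
#' of 10% or greater, and 4 or more tumor variant reads. All four
#' thresholds are boundary-inclusive. VAF given in percent (any value
#' above 1) is normalized to a fraction with a message.
#'
#' @param variants Variant tibble (see [read_variants()]).
#' @param min_depth Minimum tumor and normal depth.
#' @param min_vaf Minimum variant allele frequency (fraction).
#' @param min_variant_reads Minimum tumor variant reads.
#' @param nonsyn_only Keep only non-synonymous records; requires an
#'   `effect` column and treats values containing "synonymous" (and not
#'   "non") as synonymous.
#' @return The input with logical `pass` and character `fail_reasons`
#'   columns (`NA` for passing records, violated criteria joined by ";"
#'   otherwise).
#' @export
filter_somatic <- function(variants, min_depth = 10L, min_vaf = 0.10,
                           min_variant_reads = 4L, nonsyn_only = FALSE) {
  num_cols <- c("tumor_depth", "normal_depth", "tumor_variant_reads")
  if (any(unlist(variants[num_cols]) < 0, na.rm = TRUE)) {
    abort_data("negative read counts in variant table.")
  }
  if (any(variants$tumor_variant_reads > variants$tumor_depth,
          na.rm = TRUE)) {
    abort_data("tumor_variant_reads exceeds tumor_depth.")
  }
  vaf <- variants$vaf
  if (any(vaf > 1, na.rm = TRUE)) {
    inform("filter_somatic: `vaf` appears to be in percent; dividing by 100.")
    vaf <- vaf / 100
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) {
    abort_data("`vaf` outside [0, 1] after normalization.")
  }
  variants$vaf <- vaf
  out <- variants |>
    mutate(
      .r1 = if_else(.data$tumor_depth >= min_depth, NA_character_,
                    sprintf("tumor_depth<%d", min_depth)),
      .r2 = if_else(.data$normal_depth >= min_depth, NA_character_,
                    sprintf("normal_depth<%d", min_depth)),
      .r3 = if_else(.data$vaf >= min_vaf, NA_character_,
                    sprintf("vaf<%g", min_vaf)),
      .r4 = if_else(.data$tumor_variant_reads >= min_variant_reads,
                    NA_character_,
                    sprintf("variant_reads<%d", min_variant_reads)))
  if (nonsyn_only) {
    if (!"effect" %in% names(out)) {
      abort_config("`nonsyn_only = TRUE` requires an `effect` column.")
    }
    out <- out |>
      mutate(.r5 = if_else(
        # "synonymous" not preceded by "non"/"non-"
        grepl("(?<![a-z-])synonymous", .data$effect,
              ignore.case = TRUE, perl = TRUE),
        "synonymous", NA_character_))
  } else {
    out <- out |> mutate(.r5 = NA_character_)
  }
  reasons <- out |>
    select(dplyr::starts_with(".r")) |>
    apply(1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0) NA_character_ else semicolon(r)
    })
  out |>
    select(-dplyr::starts_with(".r")) |>
    mutate(fail_reasons = reasons, pass = is.na(reasons))
}
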