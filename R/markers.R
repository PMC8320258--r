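MARKER_FEATURES <- c("IFNG", "IL2", "CD4", "CD8A", "CD8B")

#' Activation and lineage UMI thresholds
#'
#' Positivity cutoffs for the targeted marker panel. Lineage positivity
#' follows the two-or-more-UMIs rule (CD4 >= 2; CD8A + CD8B >= 2 combined).
#' The IFN-gamma/IL-2 "high" cutoffs are configurable; the default of 5 UMIs
#' sits an order of magnitude below typical responding-cell counts and well
#' above ambient background.
#'
#' @param ifng_min,il2_min Minimum UMIs to call a cell IFN-gamma- or
#'   IL-2-high (boundary inclusive).
#' @param lineage_min Minimum UMIs for CD4/CD8 positivity.
#' @return An `activation_thresholds` list.
#' @export
activation_thresholds <- function(ifng_min = 5L, il2_min = 5L,
                                  lineage_min = 2L) {
  if (any(c(ifng_min, il2_min, lineage_min) < 1)) {
    abort_config("all thresholds must be >= 1.")
  }
  structure(list(ifng_min = as.integer(ifng_min),
                 il2_min = as.integer(il2_min),
                 lineage_min = as.integer(lineage_min)),
            class = "activation_thresholds")
}

#' Read a per-barcode marker UMI matrix
#'
#' Accepts either a directory holding a MatrixMarket triplet
#' (`matrix.mtx` + `barcodes.tsv` + `features.tsv`) or a long-form CSV with
#' columns `barcode`, `feature`, `umi_count`. Features must be exactly
#' IFNG, IL2, CD4, CD8A, CD8B (any order); absent entries are zero and
#' duplicate (barcode, feature) entries are summed with a warning.
#'
#' @param path Matrix directory or CSV file.
#' @return A tibble with columns `barcode`, `ifng`, `il2`, `cd4`, `cd8a`,
#'   `cd8b`.
#' @export
read_marker_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx_path <- file.path(path, "matrix.mtx")
    bc_path <- file.path(path, "barcodes.tsv")
    ft_path <- file.path(path, "features.tsv")
    for (p in c(mtx_path, bc_path, ft_path)) {
      if (!file.exists(p)) abort_format(paste0("missing matrix file: ", p))
    }
    m <- Matrix::readMM(mtx_path)
    barcodes <- readr::read_tsv(bc_path, col_names = "barcode",
                                show_col_types = FALSE)$barcode
    features <- readr::read_tsv(ft_path, col_names = "feature",
                                show_col_types = FALSE)$feature
    if (!setequal(features, MARKER_FEATURES) ||
        length(features) != length(MARKER_FEATURES)) {
      abort_format(paste0("features must be exactly ",
                          semicolon(MARKER_FEATURES), "; got ",
                          semicolon(features), "."))
    }
    if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
      abort_format("matrix dimensions do not match features x barcodes.")
    }
    dense <- as.matrix(m)
    rownames(dense) <- features
    long <- tibble(barcode = rep(barcodes, each = length(features)),
                   feature = rep(features, times = length(barcodes)),
                   umi_count = as.vector(dense))
  } else if (file.exists(path)) {
    long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    need <- c("barcode", "feature", "umi_count")
    missing_cols <- setdiff(need, names(long))
    if (length(missing_cols)) {
      abort_format(paste0("marker CSV is missing column(s): ",
                          semicolon(missing_cols), "."))
    }
    unknown <- setdiff(unique(long$feature), MARKER_FEATURES)
    if (length(unknown)) {
      abort_format(paste0("unknown marker feature(s): ",
                          semicolon(unknown), "."))
    }
    if (anyDuplicated(long[c("barcode", "feature")])) {
      warn("duplicate (barcode, feature) entries summed.")
    }
  } else {
    abort_format(paste0("no such file or directory: ", path))
  }
  if (nrow(long) == 0) {
    out <- tibble(barcode = character(), ifng = integer(), il2 = integer(),
                  cd4 = integer(), cd8a = integer(), cd8b = integer())
    return(out)
  }
  long |>
    mutate(umi_count = as.integer(.data$umi_count)) |>
    group_by(.data$barcode, .data$feature) |>
    summarise(umi_count = sum(.data$umi_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "umi_count",
                       values_fill = 0L) |>
    (\(d) {
      for (f in setdiff(MARKER_FEATURES, names(d))) d[[f]] <- 0L
      d
    })() |>
    select("barcode", ifng = "IFNG", il2 = "IL2", cd4 = "CD4",
           cd8a = "CD8A", cd8b = "CD8B") |>
    mutate(across(-"barcode", as.integer)) |>
    arrange(.data$barcode)
}

#' Write a marker matrix as a MatrixMarket triplet directory
#'
#' @param profiles Wide marker tibble (as from [read_marker_matrix()] or the
#'   simulator, with upper- or lower-case marker columns).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_marker_matrix <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- names(profiles)
  names(profiles) <- if_else(toupper(nm) %in% MARKER_FEATURES,
                             toupper(nm), nm)
  m <- t(as.matrix(profiles[, MARKER_FEATURES]))
  sp <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(x = profiles$barcode),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(tibble(x = MARKER_FEATURES),
                   file.path(dir, "features.tsv"), col_names = FALSE,
                   progress = FALSE)
  invisible(dir)
}

# Accept marker columns in either the feature-name case (IFNG, ...) or the
# reader's lowercase form.
normalize_profiles <- function(profiles) {
  nm <- names(profiles)
  hit <- nm %in% MARKER_FEATURES
  names(profiles)[hit] <- tolower(nm[hit])
  missing_cols <- setdiff(tolower(MARKER_FEATURES), names(profiles))
  if (length(missing_cols)) {
    abort_format(paste0("marker profiles missing column(s): ",
                        semicolon(missing_cols), "."))
  }
  profiles
}

#' Call CD4/CD8 lineage from marker UMIs
#'
#' CD4-positive when `cd4 >= lineage_min`; CD8-positive when
#' `cd8a + cd8b >= lineage_min` (combined, the permissive reading of the
#' two-or-more-UMIs rule); both gives `double_positive`, neither
#' `unassigned`. Pure per-cell rule with no cross-cell dependence.
#'
#' @param profiles Marker tibble with `cd4`, `cd8a`, `cd8b` columns.
#' @param thresholds An [activation_thresholds()].
#' @return `profiles` with a `lineage` column added.
#' @export
lineage_call <- function(profiles, thresholds = activation_thresholds()) {
  lm <- thresholds$lineage_min
  profiles |>
    mutate(
      .cd4_pos = .data$cd4 >= lm,
      .cd8_pos = (.data$cd8a + .data$cd8b) >= lm,
      lineage = dplyr::case_when(
        .data$.cd4_pos & .data$.cd8_pos ~ "double_positive",
        .data$.cd4_pos ~ "CD4",
        .data$.cd8_pos ~ "CD8",
        TRUE ~ "unassigned")) |>
    select(-".cd4_pos", -".cd8_pos")
}

#' Call activation from marker UMIs
#'
#' Flags cells as IFN-gamma-high and/or IL-2-high at the configured UMI
#' cutoffs (boundary inclusive); `activated` is their union.
#'
#' @inheritParams lineage_call
#' @return `profiles` with `ifng_pos`, `il2_pos` and `activated` columns.
#' @export
activation_call <- function(profiles, thresholds = activation_thresholds()) {
  profiles |>
    mutate(ifng_pos = .data$ifng >= thresholds$ifng_min,
           il2_pos = .data$il2 >= thresholds$il2_min,
           activated = .data$ifng_pos | .data$il2_pos)
}

#' Apply all marker positivity rules
#'
#' Convenience wrapper running [activation_call()] and [lineage_call()].
#'
#' @inheritParams lineage_call
#' @return Annotated profile tibble.
#' @export
call_markers <- function(profiles, thresholds = activation_thresholds()) {
  profiles |>
    normalize_profiles() |>
    activation_call(thresholds) |>
    lineage_call(thresholds)
}
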