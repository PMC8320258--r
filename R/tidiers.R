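#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a screen result into its candidate table
#' @param x A `tcr_screen` or `tcr_screen_result`.
#' @param ... Unused.
#' @return Candidate tibble (one row per (condition, clonotype)).
#' @export
tidy.tcr_screen <- function(x, ...) x$candidates

#' @rdname tidy.tcr_screen
#' @export
tidy.tcr_screen_result <- function(x, ...) x$screen$candidates

#' One-row summary of a screen
#' @param x A `tcr_screen` or `tcr_screen_result`.
#' @param ... Unused.
#' @return One-row tibble of screen-level counts.
#' @export
glance.tcr_screen <- function(x, ...) {
  tibble(n_conditions = length(x$log),
         n_activated = nrow(x$activated),
         n_candidates = nrow(x$candidates),
         n_shared = sum(x$candidates$klass == "shared"),
         n_unique = sum(x$candidates$klass == "unique"),
         n_autoreactive = nrow(x$autoreactive))
}

#' @rdname glance.tcr_screen
#' @export
glance.tcr_screen_result <- function(x, ...) {
  glance(x$screen) |>
    mutate(specimen = x$specimen,
           retained_total = attr(x$frequencies, "retained_total"),
           dropped_singletons = attr(x$frequencies, "dropped_singletons"),
           candidate_frequency_total =
             attr(x$candidate_frequencies, "candidate_frequency_total"),
           .before = 1)
}

#' Tidy a validation result
#' @param x A `tcr_validation` or `tcr_validation_suite`.
#' @param ... Unused.
#' @return Per-candidate annotations (`tcr_validation`) or per-specimen
#'   summary rows (`tcr_validation_suite`).
#' @export
tidy.tcr_validation <- function(x, ...) x$candidates

#' @rdname tidy.tcr_validation
#' @export
tidy.tcr_validation_suite <- function(x, ...) x$per_specimen

#' @rdname tidy.tcr_validation
#' @export
glance.tcr_validation <- function(x, ...) x$summary

#' @rdname tidy.tcr_validation
#' @export
glance.tcr_validation_suite <- function(x, ...) x$pooled

#' @rdname tidy.tcr_validation
#' @export
tidy.tcr_suite <- function(x, ...) tidy(x$summary)

#' @rdname tidy.tcr_validation
#' @export
glance.tcr_suite <- function(x, ...) glance(x$summary)
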