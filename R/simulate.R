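#' Repertoire simulation settings
#'
#' Parameters for drawing a synthetic T-cell repertoire: how many clonotypes,
#' the clonotype-frequency law, and the fraction of clonotypes carrying two
#' productive TCR-alpha chains (up to about one third of mature T cells
#' express dual alpha chains, so that is the default).
#'
#' @param n_clonotypes Number of clonotypes to draw (>= 1).
#' @param frequency_law `"power_law"` (frequency of the i-th clonotype
#'   proportional to `i^-shape`) or `"log_normal"` (sorted log-normal weights
#'   with log-sd `shape`).
#' @param shape Positive shape parameter of the frequency law.
#' @param dual_alpha_fraction Probability that a clonotype carries two
#'   productive alpha chains.
#' @param cdr3b_length_range Integer pair of CDR3-beta nucleotide lengths
#'   (multiples of 3).
#' @param seed Optional integer seed.
#' @return A `repertoire_spec` list.
#' @export
repertoire_spec <- function(n_clonotypes = 2000L,
                            frequency_law = c("power_law", "log_normal"),
                            shape = 1.5,
                            dual_alpha_fraction = 1 / 3,
                            cdr3b_length_range = c(30L, 48L),
                            seed = NULL) {
  frequency_law <- match.arg(frequency_law)
  if (!is.numeric(n_clonotypes) || n_clonotypes < 1) {
    abort_config("`n_clonotypes` must be a positive integer.")
  }
  if (!is.numeric(shape) || !is.finite(shape) || shape <= 0) {
    abort_config("`shape` must be a positive finite number.")
  }
  if (dual_alpha_fraction < 0 || dual_alpha_fraction > 1) {
    abort_config("`dual_alpha_fraction` must lie in [0, 1].")
  }
  structure(list(n_clonotypes = as.integer(n_clonotypes),
                 frequency_law = frequency_law, shape = shape,
                 dual_alpha_fraction = dual_alpha_fraction,
                 cdr3b_length_range = as.integer(cdr3b_length_range),
                 seed = seed),
            class = "repertoire_spec")
}

#' Droplet-capture settings
#'
#' Loading and noise parameters of a simulated droplet run. Defaults mirror a
#' standard V(D)J channel: 10,000 cells loaded with a targeted recovery of
#' 6,000 single cells.
#'
#' @param n_cells_loaded Cells loaded on the channel.
#' @param target_recovery Barcodes recovered (must not exceed
#'   `n_cells_loaded`).
#' @param doublet_rate Probability that a recovered barcode captured two
#'   cells (contigs and marker counts are summed).
#' @param cdr3_error_rate Per-nucleotide substitution probability applied to
#'   each emitted contig; this is what creates singleton artifact clonotypes.
#' @param ambient_marker_rate Mean spurious UMIs per marker per barcode
#'   (Poisson).
#' @param seed Optional integer seed.
#' @return A `droplet_params` list.
#' @export
droplet_params <- function(n_cells_loaded = 10000L,
                           target_recovery = 6000L,
                           doublet_rate = 0.04,
                           cdr3_error_rate = 5e-4,
                           ambient_marker_rate = 0.05,
                           seed = NULL) {
  if (doublet_rate < 0 || doublet_rate >= 1) {
    abort_config("`doublet_rate` must lie in [0, 1).")
  }
  if (target_recovery > n_cells_loaded) {
    abort_config("`target_recovery` cannot exceed `n_cells_loaded`.")
  }
  structure(list(n_cells_loaded = as.integer(n_cells_loaded),
                 target_recovery = as.integer(target_recovery),
                 doublet_rate = doublet_rate,
                 cdr3_error_rate = cdr3_error_rate,
                 ambient_marker_rate = ambient_marker_rate, seed = seed),
            class = "droplet_params")
}

#' Activation-response model
#'
#' Which clonotypes respond to a stimulation and how strongly. Reactive
#' clonotypes respond only on their cognate stimulation; autoreactive
#' clonotypes respond in every condition including the negative control.
#' Only about a third of the cells of a reactive clonotype typically respond
#' (the rest are exhausted), hence the default `responder_fraction`.
#'
#' @param reactive_clonotype_ids Clonotype ids that respond to this
#'   condition's antigen.
#' @param responder_fraction Per-cell response probability within a reactive
#'   clonotype.
#' @param ifng_high_mean,ifng_dispersion Negative-binomial mean/size of
#'   IFN-gamma UMIs in responding cells.
#' @param ifng_floor Lower truncation of the responder IFN-gamma draw,
#'   keeping responders separated from ambient background.
#' @param ifng_background_mean Ambient mean (must be below `ifng_high_mean`).
#' @param il2_coexpression_prob Probability that a responding cell also
#'   expresses IL-2.
#' @param autoreactive_clonotype_ids Clonotypes responding in every
#'   condition.
#' @return An `activation_model` list.
#' @export
activation_model <- function(reactive_clonotype_ids = character(),
                             responder_fraction = 1 / 3,
                             ifng_high_mean = 50, ifng_dispersion = 2,
                             ifng_floor = 10,
                             ifng_background_mean = 0.05,
                             il2_coexpression_prob = 0.3,
                             autoreactive_clonotype_ids = character()) {
  if (ifng_high_mean <= ifng_background_mean) {
    abort_config("`ifng_high_mean` must exceed `ifng_background_mean`.")
  }
  if (responder_fraction < 0 || responder_fraction > 1) {
    abort_config("`responder_fraction` must lie in [0, 1].")
  }
  structure(list(reactive_clonotype_ids = as.character(reactive_clonotype_ids),
                 responder_fraction = responder_fraction,
                 ifng_high_mean = ifng_high_mean,
                 ifng_dispersion = ifng_dispersion, ifng_floor = ifng_floor,
                 ifng_background_mean = ifng_background_mean,
                 il2_coexpression_prob = il2_coexpression_prob,
                 autoreactive_clonotype_ids =
                   as.character(autoreactive_clonotype_ids)),
            class = "activation_model")
}

#' Simulate a T-cell repertoire
#'
#' Draws clonotypes with unique in-frame CDR3-beta nucleotide sequences,
#' paired alpha chain(s), V/J gene labels, a CD4/CD8 lineage, and clonotype
#' frequencies summing to one.
#'
#' @param spec A [repertoire_spec()].
#' @return A tibble with one row per clonotype: `clonotype_id`, `cdr3b_nt`,
#'   `cdr3b_aa`, beta/alpha V-J labels, `cdr3a1_nt`/`cdr3a2_nt` (second alpha
#'   `NA` unless `dual_alpha`), `lineage`, `dual_alpha`, `freq`.
#' @export
#' @examples
#' rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 50, seed = 1))
#' sum(rep$freq)
simulate_repertoire <- function(spec = repertoire_spec()) {
  stopifnot(inherits(spec, "repertoire_spec"))
  with_seed(spec$seed, {
    n <- spec$n_clonotypes
    w <- switch(spec$frequency_law,
      power_law = seq_len(n)^(-spec$shape),
      log_normal = sort(rlnorm(n, meanlog = 0, sdlog = spec$shape),
                        decreasing = TRUE)
    )
    freq <- w / sum(w)
    cdr3b <- random_cdr3_nt(n, spec$cdr3b_length_range)
    dual <- runif(n) < spec$dual_alpha_fraction
    cdr3a <- random_cdr3_nt(n + sum(dual), spec$cdr3b_length_range,
                            avoid = cdr3b)
    a1 <- cdr3a[seq_len(n)]
    a2 <- rep(NA_character_, n)
    a2[dual] <- cdr3a[n + seq_len(sum(dual))]
    tibble(
      clonotype_id = sprintf("CT%05d", seq_len(n)),
      cdr3b_nt = cdr3b,
      cdr3b_aa = translate_nt(cdr3b),
      v_gene_b = sample(TRBV_POOL, n, replace = TRUE),
      j_gene_b = sample(TRBJ_POOL, n, replace = TRUE),
      cdr3a1_nt = a1,
      cdr3a1_aa = translate_nt(a1),
      v_gene_a1 = sample(TRAV_POOL, n, replace = TRUE),
      j_gene_a1 = sample(TRAJ_POOL, n, replace = TRUE),
      cdr3a2_nt = a2,
      cdr3a2_aa = translate_nt(a2),
      v_gene_a2 = if_else(dual, sample(TRAV_POOL, n, replace = TRUE),
                          NA_character_),
      j_gene_a2 = if_else(dual, sample(TRAJ_POOL, n, replace = TRUE),
                          NA_character_),
      lineage = sample(c("CD4", "CD8"), n, replace = TRUE,
                       prob = c(0.4, 0.6)),
      dual_alpha = dual,
      freq = freq
    )
  })
}

# ---- cell-level rendering --------------------------------------------------
# A cell plan has one row per barcode with columns:
#   barcode, cid, cid2 (NA unless doublet), responding, respond_marker
#   ("IFNG"/"IL2"), ifng_lo, ifng_hi, emit_trb, emit_tra, artifact
# (artifact cells emit a singly-substituted CDR3-beta).

default_plan_cols <- function(plan) {
  # columns where NA is meaningful and must be preserved
  keep_na <- list(cid2 = NA_character_, ifng_lo = NA_real_,
                  cdr3b_override = NA_character_)
  fill <- list(responding = FALSE, respond_marker = "IFNG", ifng_hi = Inf,
               emit_trb = TRUE, emit_tra = TRUE, artifact = FALSE)
  for (nm in names(keep_na)) {
    if (!nm %in% names(plan)) plan[[nm]] <- keep_na[[nm]]
  }
  for (nm in names(fill)) {
    plan[[nm]] <- if (nm %in% names(plan)) {
      dplyr::coalesce(plan[[nm]], fill[[nm]])
    } else {
      fill[[nm]]
    }
  }
  plan
}

render_contigs <- function(plan, repertoire, cdr3_error_rate = 0) {
  rep_idx <- setNames(seq_len(nrow(repertoire)), repertoire$clonotype_id)
  cells <- bind_rows(
    plan |> select("barcode", cid = "cid", "emit_trb", "emit_tra",
                   "cdr3b_override"),
    plan |> filter(!is.na(.data$cid2)) |>
      select("barcode", cid = "cid2") |>
      mutate(emit_trb = TRUE, emit_tra = TRUE,
             cdr3b_override = NA_character_)
  )
  cells <- cells |> filter(!is.na(.data$cid))
  ri <- rep_idx[cells$cid]
  if (anyNA(ri)) abort_config("cell plan references unknown clonotype id.")

  trb <- cells |> filter(.data$emit_trb)
  rb <- rep_idx[trb$cid]
  trb <- trb |>
    mutate(chain = "TRB",
           v_gene = repertoire$v_gene_b[rb],
           j_gene = repertoire$j_gene_b[rb],
           cdr3_nt = dplyr::coalesce(.data$cdr3b_override,
                                     repertoire$cdr3b_nt[rb]))

  tra_rows <- cells |> filter(.data$emit_tra)
  ra <- rep_idx[tra_rows$cid]
  tra1 <- tra_rows |>
    mutate(chain = "TRA", v_gene = repertoire$v_gene_a1[ra],
           j_gene = repertoire$j_gene_a1[ra],
           cdr3_nt = repertoire$cdr3a1_nt[ra])
  dual <- which(repertoire$dual_alpha[ra])
  tra2 <- tra_rows[dual, ] |>
    mutate(chain = "TRA", v_gene = repertoire$v_gene_a2[ra[dual]],
           j_gene = repertoire$j_gene_a2[ra[dual]],
           cdr3_nt = repertoire$cdr3a2_nt[ra[dual]])

  contigs <- bind_rows(trb, tra1, tra2) |>
    select("barcode", "chain", "v_gene", "j_gene", "cdr3_nt") |>
    mutate(umis = if_else(.data$chain == "TRB",
                          2L + rpois(n(), 6), 1L + rpois(n(), 4)),
           productive = TRUE)
  contigs$cdr3_nt <- apply_cdr3_errors(contigs$cdr3_nt, cdr3_error_rate)

  # sprinkle a few unproductive TRA contigs (out-of-frame junctions)
  n_unprod <- rbinom(1, nrow(plan), 0.03)
  if (n_unprod > 0) {
    src <- sample(plan$barcode, n_unprod)
    bad <- random_cdr3_nt(n_unprod, c(30L, 45L))
    contigs <- bind_rows(contigs, tibble(
      barcode = src, chain = "TRA",
      v_gene = sample(TRAV_POOL, n_unprod, replace = TRUE),
      j_gene = sample(TRAJ_POOL, n_unprod, replace = TRUE),
      cdr3_nt = substr(bad, 1, nchar(bad) - 1L),
      umis = 1L + rpois(n_unprod, 1), productive = FALSE))
  }

  contigs |>
    arrange(.data$barcode, .data$chain, desc(.data$umis)) |>
    group_by(.data$barcode) |>
    mutate(contig_id = paste0(.data$barcode, "_contig_", row_number())) |>
    ungroup() |>
    mutate(is_cell = TRUE,
           cdr3_aa = if_else(.data$productive, translate_nt(.data$cdr3_nt),
                             "None")) |>
    select("barcode", "is_cell", "contig_id", "chain", "v_gene", "j_gene",
           cdr3 = "cdr3_aa", "cdr3_nt", "umis", "productive")
}

render_markers <- function(plan, repertoire, activation, ambient_rate) {
  n <- nrow(plan)
  prof <- tibble(
    barcode = plan$barcode,
    IFNG = rpois(n, ambient_rate), IL2 = rpois(n, ambient_rate),
    CD4 = rpois(n, ambient_rate), CD8A = rpois(n, ambient_rate),
    CD8B = rpois(n, ambient_rate)
  )
  lin_of <- setNames(repertoire$lineage, repertoire$clonotype_id)
  add_lineage <- function(prof, cids) {
    ok <- !is.na(cids)
    cd4 <- ok & lin_of[cids] == "CD4"
    cd8 <- ok & lin_of[cids] == "CD8"
    prof$CD4[cd4] <- prof$CD4[cd4] + rpois(sum(cd4), 4)
    prof$CD8A[cd8] <- prof$CD8A[cd8] + rpois(sum(cd8), 2)
    prof$CD8B[cd8] <- prof$CD8B[cd8] + rpois(sum(cd8), 2)
    prof
  }
  prof <- add_lineage(prof, plan$cid)
  prof <- add_lineage(prof, plan$cid2)

  resp <- which(plan$responding)
  if (length(resp)) {
    lo <- ifelse(is.na(plan$ifng_lo[resp]), activation$ifng_floor,
                 plan$ifng_lo[resp])
    hi <- plan$ifng_hi[resp]
    draw <- function(lo, hi) {
      vapply(seq_along(lo), function(i) {
        rnbinom_trunc(1, mu = activation$ifng_high_mean,
                      size = activation$ifng_dispersion,
                      lo = lo[i], hi = hi[i])
      }, numeric(1))
    }
    ifng_cells <- resp[plan$respond_marker[resp] == "IFNG"]
    il2_only <- resp[plan$respond_marker[resp] == "IL2"]
    if (length(ifng_cells)) {
      m <- match(ifng_cells, resp)
      prof$IFNG[ifng_cells] <- prof$IFNG[ifng_cells] + draw(lo[m], hi[m])
      co <- ifng_cells[runif(length(ifng_cells)) <
                         activation$il2_coexpression_prob]
      if (length(co)) {
        prof$IL2[co] <- prof$IL2[co] +
          rnbinom_trunc(length(co), mu = 20, size = 2, lo = 5)
      }
    }
    if (length(il2_only)) {
      m <- match(il2_only, resp)
      prof$IL2[il2_only] <- prof$IL2[il2_only] + draw(lo[m], hi[m])
    }
  }
  prof
}

render_truth <- function(plan, condition) {
  tibble(
    condition = condition,
    barcode = plan$barcode,
    clonotype_ids = ifelse(is.na(plan$cid2), plan$cid,
                           paste(plan$cid, plan$cid2, sep = ";")),
    responding = plan$responding,
    respond_marker = if_else(plan$responding, plan$respond_marker,
                             NA_character_),
    is_doublet = !is.na(plan$cid2),
    artifact = plan$artifact,
    observed_cdr3b = plan$cdr3b_override,
    has_trb = plan$emit_trb | !is.na(plan$cid2)
  )
}

#' Simulate one stimulation condition of a droplet run
#'
#' Draws `target_recovery` barcodes from a repertoire, plants doublets and
#' per-contig CDR3 sequencing errors, and renders marker UMI profiles:
#' Poisson ambient background everywhere, plus truncated negative-binomial
#' activation counts for responding cells of reactive (or autoreactive)
#' clonotypes.
#'
#' @param repertoire A tibble from [simulate_repertoire()].
#' @param droplet A [droplet_params()].
#' @param activation An [activation_model()]; ids must exist in `repertoire`.
#' @param condition_label Name of the stimulation condition.
#' @param seed Optional integer seed (falls back to `droplet$seed`).
#' @return A list with `contigs` (contig annotation tibble), `profiles`
#'   (per-barcode marker UMI tibble) and `truth` (per-barcode ground truth).
#' @export
simulate_condition <- function(repertoire, droplet = droplet_params(),
                               activation = activation_model(),
                               condition_label = "stim", seed = NULL) {
  ids <- c(activation$reactive_clonotype_ids,
           activation$autoreactive_clonotype_ids)
  unknown <- setdiff(ids, repertoire$clonotype_id)
  if (length(unknown)) {
    abort_config(paste0("activation model references unknown clonotype id(s): ",
                        semicolon(head(unknown, 5)), "."))
  }
  with_seed(seed %||% droplet$seed, {
    n <- droplet$target_recovery
    cid <- sample(repertoire$clonotype_id, n, replace = TRUE,
                  prob = repertoire$freq)
    is_dbl <- runif(n) < droplet$doublet_rate
    cid2 <- rep(NA_character_, n)
    cid2[is_dbl] <- sample(repertoire$clonotype_id, sum(is_dbl),
                           replace = TRUE, prob = repertoire$freq)
    can_respond <- function(x) !is.na(x) & x %in% ids
    respond_draw <- runif(n) < activation$responder_fraction
    responding <- (can_respond(cid) | can_respond(cid2)) & respond_draw
    plan <- default_plan_cols(tibble(
      barcode = random_barcodes(n), cid = cid, cid2 = cid2,
      responding = responding))
    list(
      contigs = render_contigs(plan, repertoire, droplet$cdr3_error_rate),
      profiles = render_markers(plan, repertoire, activation,
                                droplet$ambient_marker_rate),
      truth = render_truth(plan, condition_label)
    )
  })
}
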