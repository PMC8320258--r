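# Internal helpers shared across the simulator and the analysis pipeline.

abort_config <- function(msg, ...) {
  abort(msg, class = c("tcrscreen_config_error", "tcrscreen_error"), ...)
}
abort_format <- function(msg, ...) {
  abort(msg, class = c("tcrscreen_format_error", "tcrscreen_error"), ...)
}
abort_data <- function(msg, ...) {
  abort(msg, class = c("tcrscreen_data_error", "tcrscreen_error"), ...)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  g <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}
SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

# Small fixed human-style gene-name pools; labels are for realism only and
# play no role in clonotype identity.
TRBV_POOL <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-5", "TRBV7-9", "TRBV9",
               "TRBV12-3", "TRBV19", "TRBV20-1", "TRBV27", "TRBV28", "TRBV30")
TRBJ_POOL <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-5", "TRBJ2-1", "TRBJ2-3",
               "TRBJ2-5", "TRBJ2-7")
TRAV_POOL <- c("TRAV1-2", "TRAV8-2", "TRAV12-1", "TRAV13-1", "TRAV17",
               "TRAV19", "TRAV21", "TRAV26-1", "TRAV27", "TRAV29/DV5",
               "TRAV35", "TRAV38-1")
TRAJ_POOL <- c("TRAJ6", "TRAJ10", "TRAJ18", "TRAJ23", "TRAJ30", "TRAJ33",
               "TRAJ42", "TRAJ49")

translate_nt <- function(nt) {
  vapply(nt, function(s) {
    if (is.na(s) || nchar(s) < 3L) return(NA_character_)
    paste(seqinr::translate(seqinr::s2c(s)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# In-frame CDR3 nucleotide strings: canonical Cys...Phe frame, no stop codons,
# unique within the returned vector (and against `avoid`).
random_cdr3_nt <- function(n, length_range = c(30L, 48L), avoid = character()) {
  lo <- as.integer(length_range[1]); hi <- as.integer(length_range[2])
  if (lo %% 3L != 0L || hi %% 3L != 0L || lo < 9L || hi < lo) {
    abort_config("`cdr3_length_range` must be an increasing pair of multiples of 3 (>= 9).")
  }
  len_choices <- seq(lo, hi, by = 3L)
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  seen <- new.env(parent = emptyenv())
  for (a in avoid) assign(a, TRUE, envir = seen)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      k <- lens[i] / 3L
      body <- sample(SENSE_CODONS, k - 2L, replace = TRUE)
      s <- paste0("TGT", paste(body, collapse = ""), "TTT")
      if (!exists(s, envir = seen, inherits = FALSE)) {
        assign(s, TRUE, envir = seen)
        out[i] <- s
        break
      }
    }
  }
  out
}

# Substitute `n_sub` random positions, never creating a stop codon and never
# returning a string present in `avoid` (used for planting error singletons).
mutate_cdr3 <- function(nt, n_sub = 1L, avoid = character()) {
  repeat {
    chars <- strsplit(nt, "", fixed = TRUE)[[1]]
    for (p in sample(seq_along(chars), n_sub)) {
      chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
    }
    s <- paste(chars, collapse = "")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (!any(codons %in% STOP_CODONS) && !s %in% avoid && s != nt) return(s)
  }
}

# Per-nucleotide substitution process used by the droplet simulator; returns
# the input vector with errors applied (stops avoided so contigs remain
# productive annotations).
apply_cdr3_errors <- function(nt, rate) {
  if (rate <= 0) return(nt)
  n_sub <- rbinom(length(nt), nchar(nt), rate)
  idx <- which(n_sub > 0L)
  for (i in idx) nt[i] <- mutate_cdr3(nt[i], n_sub = n_sub[i])
  nt
}

# Left/right-truncated negative binomial via inverse-CDF sampling.
rnbinom_trunc <- function(n, mu, size, lo = 0, hi = Inf) {
  p_lo <- if (lo > 0) pnbinom(lo - 1, size = size, mu = mu) else 0
  p_hi <- if (is.finite(hi)) pnbinom(hi, size = size, mu = mu) else 1
  qnbinom(runif(n, p_lo, p_hi), size = size, mu = mu)
}

# 10x-style droplet barcodes: 16 nt + "-1", unique within a call.
random_barcodes <- function(n) {
  make_one <- function(m) {
    vapply(seq_len(m), function(i) {
      paste0(paste(sample(BASES, 16L, replace = TRUE), collapse = ""), "-1")
    }, character(1))
  }
  bc <- make_one(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- make_one(length(dup))
  }
  bc
}

semicolon <- function(x) paste(x, collapse = ";")
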