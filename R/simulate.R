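#' Default multi-family alignment simulation configuration
#'
#' Emulates a family of tandem AAA-module proteins: an N-terminal variable
#' region that differs between families (their main distinguishing feature)
#' and conserved Walker A / Walker B-like motif blocks shared by all
#' families, on a common background consensus. Substitutions are drawn
#' uniformly over the 19 non-consensus residues; gaps are independent
#' per-site Bernoulli events.
#'
#' @param n_families Number of families (>= 2).
#' @param seqs_per_family Sequences per family (>= 2).
#' @param total_length Alignment length.
#' @param variable_region `c(start, end)` of the family-divergent region.
#' @param conserved_blocks List of `list(start, end, motif)` blocks sharing
#'   one consensus across families; `motif = NULL` draws a random consensus.
#' @param p_c Per-site, per-sequence substitution probability (replicate
#'   noise around the family consensus, applied over the whole length).
#' @param p_v Per-site, per-family divergence probability inside the
#'   variable region: each family's consensus independently replaces the
#'   ancestral background residue with probability `p_v`. At the default
#'   0.4 two family consensuses differ at about 63% of variable-region
#'   sites in expectation.
#' @param gap_probability Per-site gap probability.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A config list of class `fs_family_sim_config`.
#' @export
family_sim_config <- function(n_families = 3L, seqs_per_family = 20L,
                              total_length = 300L,
                              variable_region = c(1L, 90L),
                              conserved_blocks = list(
                                list(start = 121L, end = 135L,
                                     motif = "GSSGSGKGPPGTGKT"),
                                list(start = 201L, end = 215L,
                                     motif = "VLLFIDEIDAIGGKR")
                              ),
                              p_c = 0.05, p_v = 0.4,
                              gap_probability = 0.0, seed = 1L) {
  stopifnot(n_families >= 2L, seqs_per_family >= 2L, total_length >= 1L)
  if (!(p_c >= 0 && p_c <= p_v && p_v <= 1)) {
    stop("config error: need 0 <= p_c <= p_v <= 1", call. = FALSE)
  }
  regions <- rbind(variable_region,
                   t(vapply(conserved_blocks,
                            function(b) c(b$start, b$end), numeric(2L))))
  if (any(regions < 1L) || any(regions > total_length)) {
    stop("config error: region outside 1..", total_length, call. = FALSE)
  }
  ord <- order(regions[, 1L])
  if (any(regions[ord, 2L][-nrow(regions)] >= regions[ord, 1L][-1L])) {
    stop("config error: overlapping regions", call. = FALSE)
  }
  for (b in conserved_blocks) {
    if (!is.null(b$motif) && nchar(b$motif) != b$end - b$start + 1L) {
      stop("config error: motif length does not match block ", b$start, "..",
           b$end, call. = FALSE)
    }
  }
  structure(
    list(n_families = as.integer(n_families),
         seqs_per_family = as.integer(seqs_per_family),
         total_length = as.integer(total_length),
         variable_region = as.integer(variable_region),
         conserved_blocks = conserved_blocks,
         p_c = p_c, p_v = p_v, gap_probability = gap_probability,
         seed = as.integer(seed)),
    class = "fs_family_sim_config"
  )
}

AA20_FS <- setdiff(AA_ALPHABET_FS, c("X", "-"))

#' Simulate a labelled multi-family alignment
#'
#' A single ancestral background consensus (with conserved motif blocks)
#' is drawn first. Each family then derives its own consensus: inside the
#' variable region every site independently diverges from the background
#' with probability `p_v`, replacing the ancestral residue with a
#' uniformly drawn different one, so the variable region carries the
#' family signatures while the rest of the protein — including the Walker
#' motif blocks — is shared. Individual sequences add independent
#' per-site replicate substitutions (probability `p_c`) and gaps around
#' their family consensus.
#'
#' @param cfg An [family_sim_config()].
#' @return An [fs_alignment] with family labels; attributes
#'   `variable_region` (integer range), `conserved_blocks` and
#'   `consensus` carry the ground truth.
#' @export
simulate_family_msa <- function(cfg = family_sim_config()) {
  stopifnot(inherits(cfg, "fs_family_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$total_length
  background <- sample(AA20_FS, L, replace = TRUE)
  for (b in cfg$conserved_blocks) {
    motif <- if (is.null(b$motif)) {
      paste(sample(AA20_FS, b$end - b$start + 1L, replace = TRUE),
            collapse = "")
    } else b$motif
    background[b$start:b$end] <- strsplit(toupper(motif), "")[[1L]]
  }
  vr <- cfg$variable_region[1L]:cfg$variable_region[2L]
  fam_consensus <- lapply(seq_len(cfg$n_families), function(f) {
    cons <- background
    div <- vr[stats::runif(length(vr)) < cfg$p_v]
    if (length(div) > 0L) {
      cons[div] <- vapply(div, function(s) {
        sample(setdiff(AA20_FS, background[s]), 1L)
      }, character(1L))
    }
    cons
  })
  p_site <- rep(cfg$p_c, L)
  ids <- character(0)
  seqs <- character(0)
  labels <- character(0)
  for (f in seq_len(cfg$n_families)) {
    fam <- paste0("F", f)
    for (s in seq_len(cfg$seqs_per_family)) {
      chars <- fam_consensus[[f]]
      mut <- stats::runif(L) < p_site
      if (any(mut)) {
        # uniform over the 19 non-consensus residues
        chars[mut] <- vapply(which(mut), function(i) {
          sample(setdiff(AA20_FS, chars[i]), 1L)
        }, character(1L))
      }
      if (cfg$gap_probability > 0) {
        chars[stats::runif(L) < cfg$gap_probability] <- "-"
      }
      ids <- c(ids, sprintf("%s_seq%02d", fam, s))
      seqs <- c(seqs, paste(chars, collapse = ""))
      labels <- c(labels, fam)
    }
  }
  aln <- fs_alignment(ids, seqs, labels = stats::setNames(labels, ids))
  attr(aln, "variable_region") <- cfg$variable_region
  attr(aln, "conserved_blocks") <- cfg$conserved_blocks
  attr(aln, "consensus") <- lapply(fam_consensus, paste, collapse = "")
  aln
}

#' Simulate a noisy Hill binding curve
#'
#' Hill-equation signal plus i.i.d. Gaussian noise, on a titration series
#' mirroring a thermophoresis design (default: 10-point 1.5x dilution
#' series spanning 0.09-3.5 µM).
#'
#' @param U,B,Kd,h Hill parameters (see [hill_predict()]).
#' @param concentrations Titrant concentrations (µM); sorted ascending.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An [fs_binding_curve][binding_curve].
#' @export
simulate_binding_curve <- function(U = 0.2, B = 1.0, Kd = 0.36, h = 2,
                                   concentrations = dilution_series(),
                                   noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) {
    stop("parameter error: noise_sd must be >= 0", call. = FALSE)
  }
  S <- sort(as.numeric(concentrations))
  y <- hill_predict(S, U, B, Kd, h)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(S), sd = noise_sd)
  }
  binding_curve(S, y)
}

#' Geometric dilution series
#'
#' @param top Highest concentration (µM).
#' @param factor Dilution factor between consecutive points.
#' @param n Number of points.
#' @return Ascending concentration vector; the default reproduces a
#'   10-point 1.5x series from 0.09 to 3.5 µM.
#' @export
dilution_series <- function(top = 3.5, factor = 1.5, n = 10L) {
  sort(top / factor^(seq_len(n) - 1L))
}

#' Simulate a multi-Gaussian chromatogram
#'
#' Sum of Gaussian peaks on a flat baseline with optional Gaussian noise.
#' Peak windows are auto-derived as center +/- 4 sigma (wide enough that
#' endpoint-baseline subtraction clips well under 1% of a peak's area);
#' overlapping auto-windows are clipped at the midpoints between peak
#' centers, with a message.
#'
#' @param peaks List of `list(center, sigma, amplitude)` (ml, ml, AU);
#'   also accepts named species, e.g.
#'   `list(hexamer = list(center = 13.5, sigma = 0.3, amplitude = 50))`.
#' @param baseline Flat baseline level.
#' @param grid Elution volume grid (ml).
#' @param noise_sd Gaussian noise sd added to the trace.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An [fs_chromatogram][chromatogram] with auto-derived
#'   `peak_windows` named after the peaks.
#' @export
simulate_chromatogram <- function(peaks, baseline = 0,
                                  grid = seq(8, 20, by = 0.01),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(length(peaks) >= 1L)
  centers <- vapply(peaks, function(p) p$center, numeric(1L))
  sigmas <- vapply(peaks, function(p) p$sigma, numeric(1L))
  amps <- vapply(peaks, function(p) p$amplitude, numeric(1L))
  if (any(centers < min(grid)) || any(centers > max(grid))) {
    stop("parameter error: peak center outside the volume grid",
         call. = FALSE)
  }
  if (any(sigmas <= 0) || any(amps < 0)) {
    stop("parameter error: sigma must be > 0 and amplitude >= 0",
         call. = FALSE)
  }
  signal <- rep(baseline, length(grid))
  for (i in seq_along(peaks)) {
    signal <- signal + amps[i] * exp(-(grid - centers[i])^2 /
                                       (2 * sigmas[i]^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(grid), sd = noise_sd)
  }
  lo <- pmax(centers - 4 * sigmas, min(grid))
  hi <- pmin(centers + 4 * sigmas, max(grid))
  ord <- order(centers)
  clipped <- FALSE
  for (i in seq_along(ord)[-1L]) {
    a <- ord[i - 1L]; b <- ord[i]
    if (hi[a] > lo[b]) {
      mid <- (centers[a] + centers[b]) / 2
      hi[a] <- mid
      lo[b] <- mid + min(diff(grid))  # keep windows disjoint
      clipped <- TRUE
    }
  }
  if (clipped) message("overlapping auto-windows clipped at peak midpoints")
  nm <- names(peaks)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- paste0("peak", seq_along(peaks))
  }
  windows <- stats::setNames(
    lapply(seq_along(peaks), function(i) c(lo[i], hi[i])), nm)
  chromatogram(grid, signal, windows)
}

#' Default LFQ simulation configuration
#'
#' @param n_proteins Number of proteins.
#' @param n_replicates Replicates per group (default 5, a pentaplicate
#'   design).
#' @param fraction_spiked Fraction of proteins with a true abundance change.
#' @param true_log2_fc Absolute log2 fold change of spiked proteins (sign
#'   assigned randomly per protein).
#' @param sigma Replicate noise sd on the log2 scale. The default 0.64
#'   gives a two-sample t-test power of about 0.9 for `|log2 fc| = 1.5`
#'   at n = 5 per group and alpha = 0.05.
#' @param base_mean,base_sd Mean and sd of true per-protein log2 abundance.
#' @param seed Integer seed.
#' @return Config list of class `fs_lfq_sim_config`.
#' @export
lfq_sim_config <- function(n_proteins = 2000L, n_replicates = 5L,
                           fraction_spiked = 0.1, true_log2_fc = 1.5,
                           sigma = 0.64, base_mean = 25, base_sd = 2,
                           seed = 1L) {
  if (fraction_spiked < 0 || fraction_spiked > 1) {
    stop("config error: fraction_spiked must be in [0, 1]", call. = FALSE)
  }
  if (n_replicates < 2L) {
    stop("config error: n_replicates must be >= 2", call. = FALSE)
  }
  if (sigma < 0) stop("config error: sigma must be >= 0", call. = FALSE)
  structure(
    list(n_proteins = as.integer(n_proteins),
         n_replicates = as.integer(n_replicates),
         fraction_spiked = fraction_spiked, true_log2_fc = true_log2_fc,
         sigma = sigma, base_mean = base_mean, base_sd = base_sd,
         seed = as.integer(seed)),
    class = "fs_lfq_sim_config"
  )
}

#' Simulate a replicate LFQ intensity table with spiked fold changes
#'
#' Intensities are log-normal: per-protein true log2 abundance is drawn
#' from a normal distribution, replicate log2 intensities add Gaussian
#' noise, and spiked proteins are shifted by the true log2 fold change in
#' the knockout group (random sign per protein).
#'
#' @param cfg An [lfq_sim_config()].
#' @return An [fs_lfq_table][lfq_table] with groups `wt` and `knockout`;
#'   attribute `truth` is a data.frame with `protein`, `spiked` and
#'   `true_log2_fc` (signed; positive = up in knockout).
#' @export
simulate_lfq_table <- function(cfg = lfq_sim_config()) {
  stopifnot(inherits(cfg, "fs_lfq_sim_config"))
  set.seed(cfg$seed)
  np <- cfg$n_proteins
  nr <- cfg$n_replicates
  proteins <- sprintf("P%04d", seq_len(np))
  base <- stats::rnorm(np, cfg$base_mean, cfg$base_sd)
  n_spiked <- round(cfg$fraction_spiked * np)
  spiked <- rep(FALSE, np)
  spiked[sample.int(np, n_spiked)] <- TRUE
  effect <- rep(0, np)
  effect[spiked] <- cfg$true_log2_fc *
    sample(c(-1, 1), n_spiked, replace = TRUE)
  wt <- base + matrix(stats::rnorm(np * nr, sd = cfg$sigma), np, nr)
  ko <- base + effect +
    matrix(stats::rnorm(np * nr, sd = cfg$sigma), np, nr)
  m <- 2^cbind(wt, ko)
  rownames(m) <- proteins
  colnames(m) <- c(sprintf("wt_%d", seq_len(nr)),
                   sprintf("ko_%d", seq_len(nr)))
  group <- stats::setNames(rep(c("wt", "knockout"), each = nr), colnames(m))
  tab <- lfq_table(m, group)
  attr(tab, "truth") <- data.frame(
    protein = proteins, spiked = spiked, true_log2_fc = effect,
    stringsAsFactors = FALSE
  )
  tab
}
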