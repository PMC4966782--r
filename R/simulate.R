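#' Step signal over the sample axis
#'
#' A differential-expression-like signal: +1 on the first half of the
#' samples and -1 on the second half (mean 0, mean square 1).
#'
#' @param n even number of samples.
#' @return Numeric vector of length n.
#' @export
make_step_signal <- function(n) {
  if (n %% 2L != 0L) stop("the step signal needs an even number of samples")
  c(rep(1, n / 2), rep(-1, n / 2))
}

#' Random signal over the sample axis
#'
#' Standard normal draws, centered and scaled to unit sample variance;
#' stands in for an unmeasured or unknown sample attribute.
#'
#' @param n number of samples (>= 2).
#' @param seed optional seed; if \code{NULL} the current RNG stream is used.
#' @return Numeric vector of length n with mean 0 and sample variance 1.
#' @export
make_random_signal <- function(n, seed = NULL) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- stats::rnorm(n)
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Signal-to-noise ratio in decibels
#'
#' \code{10 * log10(var(vec(Sigma)) / var(vec(Noise)))} on the vectorized
#' signal-only and noise-only matrices.
#'
#' @param Sigma signal-only matrix.
#' @param Noise noise-only matrix with positive variance.
#' @return SNR in dB.
#' @export
snr_db <- function(Sigma, Noise) {
  vn <- stats::var(as.vector(raw_values(Noise)))
  if (vn == 0) stop("noise matrix has zero variance")
  10 * log10(stats::var(as.vector(raw_values(Sigma))) / vn)
}

#' Configuration for the multi-modal simulator
#'
#' Defines the study conditions of the simulation benchmark: two stacked
#' blocks measured on 50 shared samples, block row counts drawn from
#' \{1000, 2000, ..., 10000\}, a step signal and a random signal each
#' planted on a small disjoint set of rows per block, and i.i.d. Gaussian
#' noise, with the signal globally rescaled to hit a target SNR.
#'
#' @param K number of blocks, default 2.
#' @param p_choices candidate row counts per block, default
#'   \code{seq(1000, 10000, by = 1000)}; a single value fixes the size.
#' @param n number of samples (even), default 50.
#' @param support_fraction fraction of rows carrying each signal per block,
#'   default 0.02.
#' @param min_support minimum number of supported rows per signal per
#'   block, default 20.
#' @param snr_db target SNR in dB, default 0.
#' @param amplitude_range range of the uniform amplitude magnitude for
#'   supported rows (a random sign is applied), default \code{c(0.5, 1.5)}.
#' @param noise \code{"gaussian"} (default) or \code{"t"} (df 5, scaled to
#'   unit variance) for heavier-tailed robustness checks.
#' @param orthogonal_signals if \code{TRUE}, the random signal is
#'   orthogonalized against the step signal (and rescaled), making the two
#'   planted eigen-signals exactly orthogonal.
#' @param seed RNG seed.
#' @return An object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(K = 2L, p_choices = seq(1000L, 10000L, 1000L),
                              n = 50L, support_fraction = 0.02,
                              min_support = 20L, snr_db = 0,
                              amplitude_range = c(0.5, 1.5),
                              noise = c("gaussian", "t"),
                              orthogonal_signals = FALSE, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(K >= 1L, n >= 4L, n %% 2L == 0L,
            support_fraction > 0, support_fraction < 1,
            min_support >= 1L, length(amplitude_range) == 2L,
            amplitude_range[1L] > 0,
            amplitude_range[2L] >= amplitude_range[1L])
  structure(list(K = as.integer(K), p_choices = as.integer(p_choices),
                 n = as.integer(n), support_fraction = support_fraction,
                 min_support = as.integer(min_support), snr_db = snr_db,
                 amplitude_range = amplitude_range, noise = noise,
                 orthogonal_signals = orthogonal_signals,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-modal data set with planted sparse signals
#'
#' Generates \code{K} variables-by-samples blocks, each the sum of a
#' signal-only matrix (a step signal and a random signal, planted on
#' disjoint sparse row sets with uniform random-sign amplitudes) and an
#' i.i.d. noise matrix. The signal is globally rescaled so that the
#' stacked-matrix SNR hits the configured target exactly; ground-truth
#' supports and signals are returned alongside the data.
#'
#' @param config a [simulation_config()].
#' @return An object of class \code{"simulated_mmds"}: list with
#'   \code{blocks} (row-centered [data_matrix] list, signal + noise),
#'   \code{signal_only} and \code{noise_only} (stacked matrices),
#'   \code{support} (stacked logical vectors \code{step} and \code{rand},
#'   aligned with \code{stack_mmds(blocks)}), \code{signals} (\code{step},
#'   \code{rand}, length n), \code{realized_snr_db}, and \code{config}.
#' @export
simulate_mmds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n
  ss1 <- make_step_signal(n)
  ss2 <- make_random_signal(n)
  if (config$orthogonal_signals) {
    ss2 <- ss2 - sum(ss2 * ss1) / sum(ss1 * ss1) * ss1
    if (stats::sd(ss2) == 0) stop("degenerate random signal")
    ss2 <- (ss2 - mean(ss2)) / stats::sd(ss2)
  }
  amp <- function(m) stats::runif(m, config$amplitude_range[1L],
                                  config$amplitude_range[2L]) *
    sample(c(-1, 1), m, replace = TRUE)
  draw_noise <- function(p) {
    if (config$noise == "gaussian") matrix(stats::rnorm(p * n), p, n)
    else matrix(stats::rt(p * n, df = 5) / sqrt(5 / 3), p, n)
  }
  Sig <- vector("list", config$K)
  Noi <- vector("list", config$K)
  sup1 <- vector("list", config$K)
  sup2 <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    p_k <- if (length(config$p_choices) == 1L) config$p_choices else
      sample(config$p_choices, 1L)
    m <- max(config$min_support, round(config$support_fraction * p_k))
    if (2L * m > p_k)
      stop("cannot place two disjoint supports of ", m, " rows in ", p_k,
           " rows (block ", k, ")")
    rows1 <- sample.int(p_k, m)
    rows2 <- sample(setdiff(seq_len(p_k), rows1), m)
    S <- matrix(0, p_k, n)
    S[rows1, ] <- amp(m) %o% ss1
    S[rows2, ] <- amp(m) %o% ss2
    Sig[[k]] <- S
    Noi[[k]] <- draw_noise(p_k)
    sup1[[k]] <- seq_len(p_k) %in% rows1
    sup2[[k]] <- seq_len(p_k) %in% rows2
  }
  Sig_all <- do.call(rbind, Sig)
  Noi_all <- do.call(rbind, Noi)
  target_ratio <- 10^(config$snr_db / 10)
  scale_c <- sqrt(target_ratio * stats::var(as.vector(Noi_all)) /
                    stats::var(as.vector(Sig_all)))
  Sig <- lapply(Sig, function(S) S * scale_c)
  Sig_all <- Sig_all * scale_c
  blocks <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    p_k <- nrow(Sig[[k]])
    m <- data_matrix(Sig[[k]] + Noi[[k]],
                     sprintf("b%d_v%04d", k, seq_len(p_k)),
                     sprintf("s%02d", seq_len(n)),
                     paste0("type", k))
    blocks[[k]] <- row_center(m)
  }
  structure(list(blocks = blocks, signal_only = Sig_all,
                 noise_only = Noi_all,
                 support = list(step = unlist(sup1), rand = unlist(sup2)),
                 signals = list(step = ss1, rand = ss2),
                 realized_snr_db = snr_db(Sig_all, Noi_all),
                 config = config),
            class = "simulated_mmds")
}

#' @export
print.simulated_mmds <- function(x, ...) {
  p_k <- vapply(x$blocks, function(b) nrow(b$values), 0L)
  cat(sprintf(
    "simulated MMDS: %d block(s) of %s rows x %d samples, SNR %.2f dB\n",
    length(x$blocks), paste(p_k, collapse = "/"), x$config$n,
    x$realized_snr_db))
  cat(sprintf("  planted support: %d step rows, %d random-signal rows\n",
              sum(x$support$step), sum(x$support$rand)))
  invisible(x)
}
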