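#' ROC curve from a penalty sweep
#'
#' Sweeps the sparse rank-1 fit over a penalty grid; at each penalty the
#' detected set is the nonzero rows of the eigen-array, scored against a
#' ground-truth support vector. The curve is augmented with (0,0) and (1,1)
#' and integrated by the trapezoid rule after deduplicating identical
#' points.
#'
#' @param x super-matrix input (see [jammit()]).
#' @param grid a [lambda_grid()] (built from \code{x} if missing).
#' @param truth logical (or 0/1) vector of length p marking the true
#'   support; must contain at least one positive and one negative.
#' @param tol,max_iter forwarded to [jammit()].
#' @param L grid size when \code{grid} is missing.
#' @return An object of class \code{"roc_result"}: list with \code{sweep}
#'   (data frame \code{lambda}, \code{s}, \code{tpr}, \code{fpr}) and
#'   \code{auroc}.
#' @export
roc_from_sweep <- function(x, grid = NULL, truth, tol = 1e-6,
                           max_iter = 500L, L = 25L) {
  sm <- as_super_matrix(x)
  truth <- as.logical(truth)
  if (length(truth) != nrow(sm$values))
    stop("truth length ", length(truth), " does not match super-matrix rows ",
         nrow(sm$values))
  if (all(truth) || !any(truth))
    stop("truth must contain at least one positive and one negative row")
  if (is.null(grid)) grid <- lambda_grid(sm, L = L)
  lambdas <- grid$lambdas
  init <- svd_rank1(sm$values)
  np <- sum(truth)
  nn <- sum(!truth)
  tpr <- fpr <- numeric(length(lambdas))
  s <- integer(length(lambdas))
  for (l in seq_along(lambdas)) {
    fit <- jammit(sm, lambdas[l], tol = tol, max_iter = max_iter,
                  init = init)
    det <- fit$u != 0
    s[l] <- fit$s
    tpr[l] <- sum(det & truth) / np
    fpr[l] <- sum(det & !truth) / nn
  }
  structure(list(sweep = data.frame(lambda = lambdas, s = s, tpr = tpr,
                                    fpr = fpr),
                 auroc = trapezoid_auroc(fpr, tpr)),
            class = "roc_result")
}

# trapezoid AUROC over (fpr, tpr) points augmented with the two corners,
# sorted by fpr then tpr, duplicates removed
trapezoid_auroc <- function(fpr, tpr) {
  pts <- unique(data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1L) +
                         utils::tail(pts$tpr, -1L)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("penalty-sweep ROC: %d operating points, AUROC = %.4f\n",
              nrow(x$sweep), x$auroc))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(x$sweep$fpr, x$sweep$tpr)
  plot(c(0, x$sweep$fpr[o], 1), c(0, x$sweep$tpr[o], 1), type = "b",
       pch = 16, xlab = "false positive rate", ylab = "true positive rate",
       main = sprintf("Penalty-sweep ROC (AUROC = %.3f)", x$auroc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' AUROC of a per-row score vector
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of continuous scores
#' against a binary truth; ties receive average ranks.
#'
#' @param scores numeric per-row scores (higher = more likely positive).
#' @param truth logical (or 0/1) truth of the same length.
#' @return AUROC in [0, 1].
#' @export
auroc_from_scores <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (all(truth) || !any(truth))
    stop("truth must contain both classes")
  r <- rank(scores)
  np <- sum(truth)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * sum(!truth))
}

#' Matched per-signal AUROC of the penalty sweep on a simulated MMDS
#'
#' Runs the sweep on the stacked simulation, assigns extraction order to the
#' planted signals by correlating the unpenalized eigen-signal with each
#' planted signal, deflates the first component, and sweeps the residual for
#' the second signal.
#'
#' @param sim a [simulate_mmds()] result.
#' @param L grid size per sweep, default 25.
#' @param tol,max_iter forwarded to [jammit()].
#' @return Named numeric vector \code{c(step = ..., rand = ...)} of AUROCs,
#'   with attribute \code{"first"} naming the signal matched to the first
#'   extraction.
#' @export
evaluate_sim_auroc <- function(sim, L = 25L, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(sim, "simulated_mmds"))
  sm <- stack_mmds(sim$blocks, scale = TRUE)
  base <- jammit(sm, 0, tol = tol, max_iter = max_iter)
  first <- if (abs(stats::cor(base$v, sim$signals$step)) >=
               abs(stats::cor(base$v, sim$signals$rand))) "step" else "rand"
  second <- setdiff(c("step", "rand"), first)
  res <- residualize(sm, base)
  a1 <- roc_from_sweep(sm, truth = sim$support[[first]], L = L,
                       tol = tol, max_iter = max_iter)$auroc
  a2 <- roc_from_sweep(res, truth = sim$support[[second]], L = L,
                       tol = tol, max_iter = max_iter)$auroc
  out <- c(a1, a2)[order(c(first, second) != "step")]
  names(out) <- c("step", "rand")
  attr(out, "first") <- first
  out
}

#' Built-in baseline detectors
#'
#' A detector receives the stacked super-matrix (and the simulation object)
#' and returns either a per-row numeric score vector of length p or a list
#' of detected row sets (logical or integer vectors), one per operating
#' point.
#'
#' \code{detector_svd_threshold} ranks rows by the magnitude of the plain
#' (unpenalized) leading left singular vector. \code{detector_random}
#' assigns i.i.d. uniform scores, the chance baseline.
#'
#' @param sm a \code{super_matrix}.
#' @param ... unused.
#' @return Numeric score vector of length \code{nrow(sm$values)}.
#' @export
detector_svd_threshold <- function(sm, ...) {
  abs(svd_rank1(sm$values)$u0)
}

#' @rdname detector_svd_threshold
#' @export
detector_random <- function(sm, ...) {
  stats::runif(nrow(sm$values))
}

detector_auroc <- function(detector, name, sm, sim, truth) {
  out <- detector(sm, sim = sim)
  if (is.numeric(out)) {
    if (length(out) != nrow(sm$values))
      stop("detector '", name, "' returned ", length(out),
           " scores for ", nrow(sm$values), " rows")
    auroc_from_scores(out, truth)
  } else if (is.list(out)) {
    pts <- vapply(out, function(set) {
      det <- if (is.logical(set)) set else seq_len(nrow(sm$values)) %in% set
      if (length(det) != nrow(sm$values))
        stop("detector '", name, "' returned a detected set of wrong length")
      c(sum(det & !truth) / sum(!truth), sum(det & truth) / sum(truth))
    }, numeric(2L))
    trapezoid_auroc(pts[1L, ], pts[2L, ])
  } else stop("detector '", name, "' must return scores or detected sets")
}

#' Compare detection performance over repeated simulations
#'
#' For each simulated MMDS, scores the penalty-sweep detector and every
#' supplied alternative on both planted signals, records AUROC differences
#' (sweep minus alternative), and reports an exact binomial sign test per
#' detector and signal.
#'
#' @param config a [simulation_config()]; per-simulation seeds are derived
#'   from \code{seed}.
#' @param detectors named list of detector functions (see
#'   [detector_svd_threshold()]).
#' @param n_sims number of simulations, at least 5.
#' @param seed base RNG seed.
#' @param L sweep grid size, default 25.
#' @return An object of class \code{"detector_comparison"}: list with
#'   \code{table} (one row per simulation x signal x detector, with both
#'   AUROCs and their difference) and \code{tests} (median difference and
#'   exact binomial sign-test p-value per detector x signal).
#' @export
compare_over_sims <- function(config, detectors, n_sims = 20L, seed = 1L,
                              L = 25L) {
  stopifnot(inherits(config, "simulation_config"), n_sims >= 5L,
            length(detectors) >= 1L)
  if (is.null(names(detectors)) || any(names(detectors) == ""))
    stop("'detectors' must be a named list")
  rows <- list()
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- as.integer(seed) + 104729L * i
    sim <- simulate_mmds(cfg)
    sm <- stack_mmds(sim$blocks, scale = TRUE)
    set.seed(cfg$seed + 1L)  # stream for stochastic detectors
    sweep_auc <- evaluate_sim_auroc(sim, L = L)
    for (nm in names(detectors)) {
      for (sig in c("step", "rand")) {
        alt <- detector_auroc(detectors[[nm]], nm, sm, sim,
                              sim$support[[sig]])
        rows[[length(rows) + 1L]] <- data.frame(
          sim = i, signal = sig, detector = nm,
          auroc_sweep = unname(sweep_auc[sig]), auroc_detector = alt,
          delta = unname(sweep_auc[sig]) - alt,
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tests <- do.call(rbind, lapply(split(tab, tab[c("detector", "signal")]),
                                 function(d) {
    nz <- d$delta[d$delta != 0]
    p <- if (length(nz) == 0L) 1 else
      stats::binom.test(sum(nz > 0), length(nz), 0.5)$p.value
    data.frame(detector = d$detector[1L], signal = d$signal[1L],
               median_delta = stats::median(d$delta),
               n_positive = sum(d$delta > 0), n_nonzero = length(nz),
               sign_test_p = p, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  structure(list(table = tab, tests = tests), class = "detector_comparison")
}

#' Per-simulation AUROC differences between two detector results
#'
#' @param a,b numeric vectors (or matrices) of AUROCs from the same
#'   simulations and signals.
#' @return Elementwise \code{a - b}; positive values favor \code{a}.
#' @export
delta_auroc <- function(a, b) {
  if (length(a) != length(b))
    stop("AUROC vectors differ in length (", length(a), " vs ", length(b), ")")
  a - b
}

#' @export
print.detector_comparison <- function(x, ...) {
  cat("detector comparison (penalty sweep vs alternatives):\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
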