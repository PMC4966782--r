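#' Build an l1 penalty grid for a super-matrix
#'
#' The grid runs from 0 (no shrinkage: the plain SVD signature) to
#' \code{lambda_sup}, the smallest penalty that empties the signature on the
#' first eigen-array update: \code{lambda_sup = 2 * max_i |d_i . v0|} with
#' \code{v0} the unit leading right singular vector.
#'
#' @param x super-matrix input (see [jammit()]).
#' @param L number of grid points, at least 3. Default 50.
#' @param type \code{"linear"} (default) or \code{"geometric"}; the
#'   geometric grid keeps 0 as its first point and spaces the rest
#'   log-uniformly above a small floor (\code{lambda_sup / 1e3}).
#' @return An object of class \code{"lambda_grid"}: list with
#'   \code{lambdas} (strictly increasing, first 0, last \code{lambda_sup}),
#'   \code{L} and \code{lambda_sup}.
#' @export
lambda_grid <- function(x, L = 50L, type = c("linear", "geometric")) {
  type <- match.arg(type)
  stopifnot(L >= 3L)
  sm <- as_super_matrix(x)
  init <- svd_rank1(sm$values)
  v0 <- init$v0 / init$sigma
  lambda_sup <- 2 * max(abs(drop(sm$values %*% v0)))
  if (lambda_sup <= 0) stop("degenerate matrix: lambda_sup is 0")
  lambdas <- if (type == "linear") {
    seq(0, lambda_sup, length.out = L)
  } else {
    c(0, exp(seq(log(lambda_sup / 1e3), log(lambda_sup), length.out = L - 1L)))
  }
  structure(list(lambdas = lambdas, L = L, lambda_sup = lambda_sup),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("lambda grid: %d points in [0, %.6g]\n", x$L, x$lambda_sup))
  invisible(x)
}

# signature sizes (joint and per block) for every grid lambda on one matrix,
# sharing a single SVD initialization across the grid
sweep_sizes <- function(sm, lambdas, tol, max_iter) {
  init <- svd_rank1(sm$values)
  blk <- block_of_rows(sm)
  K <- nrow(sm$block_map)
  s_joint <- integer(length(lambdas))
  s_block <- matrix(0L, length(lambdas), K)
  for (l in seq_along(lambdas)) {
    fit <- jammit(sm, lambdas[l], tol = tol, max_iter = max_iter,
                  init = init)
    s_joint[l] <- fit$s
    if (fit$s > 0)
      s_block[l, ] <- tabulate(blk[fit$u != 0], nbins = K)
  }
  list(joint = s_joint, block = s_block)
}

# independently shuffle the entries within each row (destroys the shared
# column signal, preserves each row's marginal distribution)
permute_rows <- function(vals) {
  n <- ncol(vals)
  t(apply(vals, 1L, function(r) r[sample.int(n)]))
}

#' Permutation-based FDR profile over a penalty grid
#'
#' For each grid penalty the observed signature size \code{s_obs(lambda)} is
#' compared with signature sizes obtained on null matrices in which every
#' row of the super-matrix is independently shuffled. The estimated FDR at
#' \code{lambda} is the mean over permutations of
#' \code{min(1, s_null / s_obs)}, with the convention FDR = 1 wherever
#' \code{s_obs = 0}. Per-block profiles use block-restricted counts in the
#' same way.
#'
#' @param x super-matrix input (see [jammit()]).
#' @param grid a [lambda_grid()] (built from \code{x} if missing).
#' @param B number of permutations, default 100.
#' @param seed RNG seed for the permutations (mandatory for
#'   reproducibility).
#' @param estimator \code{"mean"} (default) or \code{"median"} over the
#'   permutation ratios.
#' @param tol,max_iter forwarded to [jammit()].
#' @param L grid size when \code{grid} is missing.
#' @return An object of class \code{"fdr_profile"}: list with \code{grid},
#'   \code{s_obs}, \code{s_obs_block} (L x K), \code{fdr_joint},
#'   \code{fdr_per_block} (L x K matrix), \code{B}, \code{seed}.
#' @export
estimate_fdr <- function(x, grid = NULL, B = 100L, seed = 1L,
                         estimator = c("mean", "median"),
                         tol = 1e-6, max_iter = 500L, L = 50L) {
  estimator <- match.arg(estimator)
  if (B < 1L) stop("need at least one permutation (B >= 1)")
  sm <- as_super_matrix(x)
  if (is.null(grid)) grid <- lambda_grid(sm, L = L)
  stopifnot(inherits(grid, "lambda_grid"))
  lambdas <- grid$lambdas
  K <- nrow(sm$block_map)
  obs <- sweep_sizes(sm, lambdas, tol, max_iter)
  ratio_joint <- matrix(NA_real_, length(lambdas), B)
  ratio_block <- array(NA_real_, c(length(lambdas), K, B))
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    null_sm <- sm
    null_sm$values <- permute_rows(sm$values)
    nul <- sweep_sizes(null_sm, lambdas, tol, max_iter)
    ratio_joint[, b] <- ifelse(obs$joint == 0, 1,
                               pmin(1, nul$joint / obs$joint))
    ratio_block[, , b] <- ifelse(obs$block == 0, 1,
                                 pmin(1, nul$block / obs$block))
  }
  agg <- if (estimator == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  fdr_joint <- agg(ratio_joint)
  fdr_per_block <- apply(ratio_block, c(1L, 2L),
                         if (estimator == "mean") mean else stats::median)
  colnames(fdr_per_block) <- sm$block_map$dtype_tag
  structure(list(grid = grid, s_obs = obs$joint, s_obs_block = obs$block,
                 fdr_joint = fdr_joint, fdr_per_block = fdr_per_block,
                 B = B, seed = as.integer(seed), estimator = estimator),
            class = "fdr_profile")
}

#' @export
print.fdr_profile <- function(x, ...) {
  cat(sprintf("FDR profile: %d lambdas, B = %d permutations\n",
              x$grid$L, x$B))
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ...", nrow(df) - 10L, "more rows\n")
  invisible(x)
}

#' @export
as.data.frame.fdr_profile <- function(x, ...) {
  df <- data.frame(lambda = x$grid$lambdas, s_obs = x$s_obs,
                   fdr_joint = x$fdr_joint)
  for (k in seq_len(ncol(x$fdr_per_block)))
    df[[paste0("fdr_", colnames(x$fdr_per_block)[k])]] <- x$fdr_per_block[, k]
  df
}

#' @export
plot.fdr_profile <- function(x, ...) {
  plot(x$grid$lambdas, x$fdr_joint, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "lambda", ylab = "estimated FDR", main = "FDR profile", ...)
  K <- ncol(x$fdr_per_block)
  for (k in seq_len(K))
    lines(x$grid$lambdas, x$fdr_per_block[, k], lty = k + 1L, col = k + 1L)
  legend("topright", bty = "n", lty = c(1, seq_len(K) + 1L),
         col = c(1, seq_len(K) + 1L), pch = c(16, rep(NA, K)),
         legend = c("joint", colnames(x$fdr_per_block)))
  invisible(x)
}

#' Select the penalty from an FDR profile
#'
#' Returns the smallest grid penalty whose joint FDR is at or below
#' \code{threshold} (the first crossing of the profile's decay). Choosing
#' the first qualifying penalty keeps the signature as dense as the FDR
#' budget allows, so the full underlying support enters the model at an
#' already-acceptable FDR and the subsequent deflation removes the
#' detected component cleanly; larger qualifying penalties retain only the
#' strongest rows of the same signal. Profiles that never reach the
#' threshold yield \code{NULL}.
#'
#' @param profile an \code{"fdr_profile"}.
#' @param threshold FDR threshold in (0, 1), default 0.05.
#' @return A list with \code{lambda}, \code{index}, \code{fdr}, or
#'   \code{NULL} when no grid point qualifies.
#' @export
select_lambda <- function(profile, threshold = 0.05) {
  stopifnot(inherits(profile, "fdr_profile"), threshold > 0, threshold < 1)
  f <- profile$fdr_joint
  cand <- which(f <= threshold)
  if (!length(cand)) return(NULL)
  best <- cand[1L]
  list(lambda = profile$grid$lambdas[best], index = best, fdr = f[best])
}

#' Iterative multi-signal fitting with deflation
#'
#' Repeatedly: build a penalty grid and permutation-FDR profile on the
#' current (residual) super-matrix, select the penalty at the qualifying FDR
#' minimum, fit the sparse rank-1 model there, record it, and deflate the
#' fitted component. Stops when no penalty qualifies, the fit comes back
#' empty, or the iteration count reaches the bound \code{min_k rank(D_k)}.
#'
#' @param mmds list of [data_matrix] blocks (or a \code{super_matrix}).
#' @param L grid size per iteration, default 50.
#' @param B permutations per iteration, default 100.
#' @param threshold FDR threshold, default 0.05.
#' @param seed RNG seed; each iteration's permutations use a seed derived
#'   from it.
#' @param tol,max_iter forwarded to [jammit()].
#' @param max_signals optional cap on the number of extracted components
#'   (defaults to the rank bound).
#' @return An object of class \code{"jammit_run"}: list with
#'   \code{iterations} (each holding \code{fit}, \code{signature},
#'   \code{fdr_profile}, \code{lambda_star}, \code{residual_fraction}),
#'   \code{stop_reason}, and \code{rank_bound}.
#' @export
jammit_iterate <- function(mmds, L = 50L, B = 100L, threshold = 0.05,
                           seed = 1L, tol = 1e-6, max_iter = 500L,
                           max_signals = NULL) {
  sm0 <- as_super_matrix(mmds)
  rank_bound <- min(vapply(seq_len(nrow(sm0$block_map)), function(k) {
    qr(block_slice(sm0, k)$values)$rank
  }, 0L))
  n_max <- if (is.null(max_signals)) rank_bound else
    min(max_signals, rank_bound)
  norm0 <- sqrt(sum(sm0$values^2))
  res <- sm0
  iterations <- list()
  stop_reason <- "iteration bound"
  for (r in seq_len(n_max)) {
    grid <- lambda_grid(res, L = L)
    profile <- estimate_fdr(res, grid = grid, B = B,
                            seed = as.integer(seed) + 7919L * r,
                            tol = tol, max_iter = max_iter)
    sel <- select_lambda(profile, threshold = threshold)
    if (is.null(sel)) {
      stop_reason <- "no significant lambda"
      break
    }
    fit <- jammit(res, sel$lambda, tol = tol, max_iter = max_iter)
    if (fit$s == 0L) {
      stop_reason <- "empty fit"
      break
    }
    res <- residualize(res, fit)
    iterations[[r]] <- list(iteration = r, fit = fit,
                            signature = fit$signature,
                            fdr_profile = profile,
                            lambda_star = sel$lambda, fdr_star = sel$fdr,
                            residual_fraction = sqrt(sum(res$values^2)) / norm0)
  }
  structure(list(iterations = iterations, stop_reason = stop_reason,
                 rank_bound = rank_bound, initial_norm = norm0),
            class = "jammit_run")
}

#' @export
print.jammit_run <- function(x, ...) {
  cat(sprintf("jammit run: %d signal(s) extracted (stop: %s)\n",
              length(x$iterations), x$stop_reason))
  for (it in x$iterations)
    cat(sprintf(
      "  #%d: lambda* = %.6g (FDR %.4g), s = %d, residual %.3f of input norm\n",
      it$iteration, it$lambda_star, it$fdr_star, it$fit$s,
      it$residual_fraction))
  invisible(x)
}

#' @export
summary.jammit_run <- function(object, ...) {
  df <- do.call(rbind, lapply(object$iterations, function(it) {
    data.frame(iteration = it$iteration, lambda_star = it$lambda_star,
               fdr = it$fdr_star, s = it$fit$s,
               residual_fraction = it$residual_fraction)
  }))
  list(table = df, stop_reason = object$stop_reason,
       rank_bound = object$rank_bound)
}

#' Leave-one-out signature robustness
#'
#' Drops each sample in turn, restacks and rescales the reduced blocks,
#' refits at the fixed penalty chosen on the full data, and measures how
#' much of the full-data signature each minus-one signature recapitulates.
#'
#' @param mmds list of [data_matrix] blocks (or a \code{super_matrix}).
#' @param lambda fixed l1 penalty (typically the full-data selection).
#' @param tol,max_iter forwarded to [jammit()].
#' @return An object of class \code{"jammit_loocv"}: list with
#'   \code{full_signature} (variable keys of the full-data fit),
#'   \code{signatures} (per left-out sample), \code{recapitulation}
#'   (fraction of the full signature recovered, per sample),
#'   \code{intersection} (keys common to every minus-one signature) and
#'   \code{mean_recapitulation}.
#' @export
jammit_loocv <- function(mmds, lambda, tol = 1e-6, max_iter = 500L) {
  sm <- as_super_matrix(mmds)
  n <- ncol(sm$values)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  sig_keys <- function(fit) {
    e <- fit$signature$entries
    paste(e$dtype_tag, e$variable_id, sep = ":")
  }
  full <- jammit(sm, lambda, tol = tol, max_iter = max_iter)
  if (full$s == 0L)
    stop("full-data signature is empty at lambda = ", lambda,
         "; choose a smaller penalty")
  keys0 <- sig_keys(full)
  sigs <- vector("list", n)
  recap <- numeric(n)
  K <- nrow(sm$block_map)
  for (j in seq_len(n)) {
    blocks_j <- lapply(seq_len(K), function(k) {
      b <- block_slice(sm, k)
      data_matrix(b$values[, -j, drop = FALSE], b$variable_ids,
                  b$sample_ids[-j], b$dtype_tag)
    })
    fit_j <- jammit(stack_mmds(blocks_j, scale = TRUE), lambda,
                    tol = tol, max_iter = max_iter)
    sigs[[j]] <- sig_keys(fit_j)
    recap[j] <- length(intersect(sigs[[j]], keys0)) / length(keys0)
  }
  structure(list(full_signature = keys0, signatures = sigs,
                 recapitulation = recap,
                 intersection = Reduce(intersect, sigs),
                 mean_recapitulation = mean(recap), lambda = lambda),
            class = "jammit_loocv")
}

#' @export
print.jammit_loocv <- function(x, ...) {
  cat(sprintf(
    "leave-one-out at lambda = %.6g: full signature %d variables\n",
    x$lambda, length(x$full_signature)))
  cat(sprintf("  mean recapitulation: %.3f; intersection: %d variables\n",
              x$mean_recapitulation, length(x$intersection)))
  invisible(x)
}
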