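#' Extract an eigen-survival model from a signature realization
#'
#' The eigen-survival model (ESM) of a signature is the dominant left
#' singular vector of the signature's row-centered s x n realization
#' matrix: a unit vector of per-variable loadings whose inner product with a
#' sample's profile is that sample's prognostic score. Using the dominant
#' singular direction damps random noise relative to averaging the raw
#' variables.
#'
#' @param signature_matrix numeric s x n matrix (s >= 2 signature variables
#'   by n >= 4 samples), rows centered.
#' @param variable_ids row identifiers; default rownames.
#' @return An object of class \code{"esm"}: list with \code{variable_ids},
#'   \code{loadings} (unit l2 norm, largest-magnitude entry positive) and
#'   \code{train_scores} (\code{= t(loadings) \%*\% signature_matrix}).
#' @export
extract_esm <- function(signature_matrix, variable_ids = rownames(signature_matrix)) {
  x <- raw_values(signature_matrix)
  if (nrow(x) < 2L) stop("an ESM needs at least 2 signature variables")
  if (ncol(x) < 4L) stop("an ESM needs at least 4 samples")
  if (all(x == 0)) stop("zero signature matrix")
  if (is.null(variable_ids)) variable_ids <- paste0("v", seq_len(nrow(x)))
  if (length(variable_ids) != nrow(x) || anyDuplicated(variable_ids))
    stop("'variable_ids' must uniquely label the ", nrow(x), " rows")
  w <- svd_rank1(x)$u0
  scores <- drop(crossprod(x, w))
  names(scores) <- colnames(x)
  structure(list(variable_ids = as.character(variable_ids), loadings = w,
                 train_scores = scores),
            class = "esm")
}

#' @export
print.esm <- function(x, ...) {
  cat(sprintf("eigen-survival model: %d loadings, %d training scores\n",
              length(x$loadings), length(x$train_scores)))
  invisible(x)
}

#' @export
coef.esm <- function(object, ...) {
  stats::setNames(object$loadings, object$variable_ids)
}

#' Project a new cohort onto an eigen-survival model
#'
#' Computes prognostic scores for unseen samples measured on the same
#' signature variables. Rows are matched by ID (order-corrected); a missing
#' variable is an error.
#'
#' @param esm an \code{"esm"}.
#' @param new_matrix s x m matrix for the new cohort.
#' @param new_variable_ids row identifiers of \code{new_matrix}; default
#'   rownames.
#' @return Numeric vector of m prognostic scores.
#' @export
project_scores <- function(esm, new_matrix,
                           new_variable_ids = rownames(new_matrix)) {
  stopifnot(inherits(esm, "esm"))
  x <- raw_values(new_matrix)
  if (is.null(new_variable_ids))
    stop("new matrix must carry variable IDs (rownames or new_variable_ids)")
  new_variable_ids <- as.character(new_variable_ids)
  if (length(new_variable_ids) != nrow(x))
    stop("'new_variable_ids' length does not match the new matrix")
  idx <- match(esm$variable_ids, new_variable_ids)
  if (anyNA(idx))
    stop("new matrix lacks signature variable(s): ",
         paste(utils::head(esm$variable_ids[is.na(idx)], 10L), collapse = ", "))
  drop(crossprod(x[idx, , drop = FALSE], esm$loadings))
}

#' @export
predict.esm <- function(object, newdata = NULL,
                        new_variable_ids = rownames(newdata), ...) {
  if (is.null(newdata)) return(object$train_scores)
  project_scores(object, newdata, new_variable_ids)
}

#' Quartile stratification of prognostic scores
#'
#' Labels the \code{floor(m/4)} largest scores \code{"top"}, the
#' \code{floor(m/4)} smallest \code{"bottom"}, and the remainder
#' \code{"middle"}. Boundary ties are broken by stable sample order.
#' Invariant under adding a constant or multiplying by a positive constant.
#'
#' @param scores numeric vector of at least 8 scores.
#' @return Factor of labels with levels \code{bottom}, \code{middle},
#'   \code{top}.
#' @examples
#' table(quartile_groups(rnorm(291)))  # 72 top, 72 bottom
#' @export
quartile_groups <- function(scores) {
  m <- length(scores)
  if (m < 8L) stop("quartile stratification needs at least 8 samples")
  q <- m %/% 4L
  ord <- order(scores)  # stable: boundary ties resolved by sample order
  lab <- rep("middle", m)
  lab[ord[seq_len(q)]] <- "bottom"
  lab[ord[(m - q + 1L):m]] <- "top"
  factor(lab, levels = c("bottom", "middle", "top"))
}

check_survival_args <- function(times, censored) {
  stopifnot(length(times) == length(censored))
  if (any(!is.finite(times)) || any(times <= 0))
    stop("survival times must be finite and positive")
  if (!all(censored %in% c(0, 1)))
    stop("'censored' must be coded 0 = event observed, 1 = censored")
  1 - censored  # event indicator
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square statistic for a two-group comparison, with
#' the p-value from the chi-square distribution on 1 degree of freedom.
#' Censoring is coded 1 = censored, 0 = event observed.
#'
#' @param times positive survival times.
#' @param censored 0/1 censoring indicators (1 = censored).
#' @param groups two-level grouping (samples in other levels, e.g. the
#'   middle quartiles, are dropped).
#' @return List with \code{statistic}, \code{p_value}, \code{n} per group.
#' @export
logrank_test <- function(times, censored, groups) {
  event <- check_survival_args(times, censored)
  groups <- as.factor(groups)
  keep <- !is.na(groups)
  g <- droplevels(groups[keep])
  if (nlevels(g) != 2L)
    stop("log-rank comparison needs exactly two non-empty groups, got ",
         nlevels(g))
  if (sum(event[keep]) < 1L) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(times[keep], event[keep]) ~ g)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       n = as.vector(table(g)))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; Wald tests per
#' coefficient. Censoring is coded 1 = censored.
#'
#' @param times positive survival times.
#' @param censored 0/1 censoring indicators (1 = censored).
#' @param covariates data frame (or matrix) of finite covariates with
#'   nonzero variance.
#' @return Data frame with one row per coefficient: \code{coef}, \code{se},
#'   \code{z}, \code{p_value}, plus the fitted \code{"coxph"} model as
#'   attribute \code{"model"}.
#' @export
cox_ph <- function(times, censored, covariates) {
  event <- check_survival_args(times, censored)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(times))
    stop("covariate rows must match the number of samples")
  for (nm in colnames(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      if (any(!is.finite(v))) stop("covariate '", nm, "' has non-finite values")
      if (stats::var(v) == 0) stop("covariate '", nm, "' is constant")
    } else if (length(unique(v)) < 2L) stop("covariate '", nm, "' is constant")
  }
  if (length(unique(times[event == 1])) < 2L)
    stop("need at least two distinct event times")
  fit <- survival::coxph(survival::Surv(times, event) ~ .,
                         data = covariates, ties = "efron")
  s <- summary(fit)$coefficients
  out <- data.frame(coef = unname(s[, "coef"]), se = unname(s[, "se(coef)"]),
                    z = unname(s[, "z"]), p_value = unname(s[, "Pr(>|z|)"]),
                    row.names = rownames(s))
  attr(out, "model") <- fit
  out
}

#' Kaplan-Meier summary
#'
#' Product-limit survival curve with the median survival time (smallest
#' time at which the curve reaches 0.5 or below; NA if it never does) and
#' the survival rate at a fixed horizon (default 5 time units).
#'
#' @param times positive survival times.
#' @param censored 0/1 censoring indicators (1 = censored).
#' @param horizon time at which to report the survival rate, default 5.
#' @return List with \code{time} and \code{surv} (the step function over
#'   event times), \code{median}, \code{horizon}, \code{rate_at_horizon}.
#' @export
km_summary <- function(times, censored, horizon = 5) {
  event <- check_survival_args(times, censored)
  fit <- survival::survfit(survival::Surv(times, event) ~ 1)
  surv_at <- summary(fit, times = horizon, extend = TRUE)$surv
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
    NA_real_
  list(time = fit$time, surv = fit$surv, median = med, horizon = horizon,
       rate_at_horizon = surv_at)
}

#' Eigen-survival prognosis of a signature realization
#'
#' End-to-end prognostic evaluation: extract the ESM, stratify the cohort
#' into top/bottom score quartiles, compare them by the log-rank test, and
#' fit a Cox model of survival on the continuous score (plus optional
#' covariates). The signature is called predictive only when both the
#' log-rank and Cox p-values are at or below \code{alpha}.
#'
#' @param signature_matrix s x n realization of the signature
#'   (row-centered), or an already-extracted \code{"esm"}.
#' @param times,censored survival data for the n samples (1 = censored).
#' @param covariates optional data frame of extra Cox covariates (e.g.
#'   age).
#' @param alpha significance level for both tests, default 0.05.
#' @param horizon horizon for the reported survival rate, default 5.
#' @return An object of class \code{"esm_prognosis"}: list with the
#'   \code{esm}, \code{scores}, \code{groups}, \code{logrank}, \code{cox}
#'   (coefficient table), \code{km} (per-group KM summaries),
#'   \code{predictive} flag and \code{alpha}.
#' @export
esm_prognosis <- function(signature_matrix, times, censored,
                          covariates = NULL, alpha = 0.05, horizon = 5) {
  esm <- if (inherits(signature_matrix, "esm")) signature_matrix else
    extract_esm(signature_matrix)
  scores <- esm$train_scores
  if (length(scores) != length(times))
    stop("survival data must cover the ", length(scores), " scored samples")
  groups <- quartile_groups(scores)
  extreme <- groups %in% c("top", "bottom")
  lr <- logrank_test(times[extreme], censored[extreme],
                     droplevels(groups[extreme]))
  covs <- data.frame(score = as.vector(scores))
  if (!is.null(covariates)) covs <- cbind(covs, as.data.frame(covariates))
  cox <- cox_ph(times, censored, covs)
  km <- lapply(c(bottom = "bottom", top = "top"), function(gr) {
    sel <- groups == gr
    km_summary(times[sel], censored[sel], horizon = horizon)
  })
  structure(list(esm = esm, scores = scores, groups = groups, logrank = lr,
                 cox = cox, km = km,
                 predictive = lr$p_value <= alpha &&
                   cox["score", "p_value"] <= alpha,
                 alpha = alpha),
            class = "esm_prognosis")
}

#' @export
print.esm_prognosis <- function(x, ...) {
  cat(sprintf(
    "eigen-survival prognosis: top/bottom quartiles of %d samples (%d each)\n",
    length(x$scores), sum(x$groups == "top")))
  cat(sprintf("  log-rank: chi-square = %.4g, p = %.4g\n",
              x$logrank$statistic, x$logrank$p_value))
  cat(sprintf("  Cox (score): coef = %.4g, p = %.4g\n",
              x$cox["score", "coef"], x$cox["score", "p_value"]))
  cat(sprintf("  predictive at alpha = %g: %s\n", x$alpha,
              if (x$predictive) "yes" else "no"))
  invisible(x)
}
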