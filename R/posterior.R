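#' Effective sample size by Geyer's initial positive sequence
#'
#' Estimates the effective number of independent samples of a scalar chain
#' as `G / tau`, where the integrated autocorrelation time
#' `tau = -1 + 2 sum_k Gamma_k` sums consecutive lag-pair sums
#' `Gamma_k = rho_{2k} + rho_{2k+1}` truncated at the first non-positive
#' pair (the initial positive sequence).
#'
#' @param samples Numeric vector (one scalar parameter's chain).
#' @return Effective sample size (capped at the chain length).
#' @export
ess_initial_positive <- function(samples) {
  x <- as.numeric(samples)
  G <- length(x)
  if (G < 10) stop("need at least 10 samples for an ESS estimate")
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) {
    stop("effective sample size undefined for a zero-variance chain")
  }
  rho <- stats::acf(x, lag.max = min(G - 1, 10000), plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
  n_pairs <- floor(length(rho) / 2)
  tau <- -1
  for (k in seq_len(n_pairs)) {
    gk <- rho[2 * k - 1] + rho[2 * k]
    if (gk <= 0) break
    tau <- tau + 2 * gk
  }
  tau <- max(tau, 1 / G)
  min(G / tau, G)
}

# Posterior mean, type-7 2.5/97.5 percentiles and Geyer ESS for one scalar.
summarize_scalar <- function(x, name) {
  qs <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  ess <- tryCatch(ess_initial_positive(x), error = function(e) NA_real_)
  data.frame(parameter = name, pm = mean(x), ppi_low = qs[1],
             ppi_high = qs[2], ess = ess, stringsAsFactors = FALSE)
}

#' Posterior summary table of a fitted chain
#'
#' Per stored scalar parameter: posterior mean, 95% posterior probability
#' interval (2.5 and 97.5 empirical percentiles, type-7 interpolation), and
#' Geyer initial-positive-sequence effective sample size.
#'
#' @param chain A `sire_chain`, or a numeric matrix of samples (columns =
#'   parameters).
#' @param params Optional character vector restricting the parameters.
#' @return Data frame with columns `parameter`, `pm`, `ppi_low`,
#'   `ppi_high`, `ess`.
#' @export
summarize_chain <- function(chain, params = NULL) {
  s <- if (inherits(chain, "sire_chain")) chain$samples else as.matrix(chain)
  if (is.null(dim(s)) || nrow(s) == 0) stop("empty chain")
  if (is.null(colnames(s))) colnames(s) <- paste0("param", seq_len(ncol(s)))
  if (!is.null(params)) {
    miss <- setdiff(params, colnames(s))
    if (length(miss)) stop("unknown parameter(s): ",
                           paste(miss, collapse = ", "))
    s <- s[, params, drop = FALSE]
  }
  s <- s[, apply(s, 2, function(x) all(is.finite(x))), drop = FALSE]
  do.call(rbind, lapply(colnames(s), function(p) {
    summarize_scalar(s[, p], p)
  }))
}

#' Flag outlying records from posterior-mean mixing scales
#'
#' Under the Student's-t fit, a record whose posterior-mean mixing scale is
#' well below 1 is poorly explained by a normal residual; values below
#' about 0.2 correspond to records three or more residual standard
#' deviations from their fitted mean on at least one trait. Both the 0.3
#' and the 0.2 thresholds of the usual diagnostic plot are reported.
#'
#' @param lambda_means n-vector of posterior-mean mixing scales (e.g.
#'   `chain$lambda_mean`), or a `sire_chain`.
#' @param thresholds Decreasing vector of flagging thresholds.
#' @param residuals Optional n x m matrix of fitted residuals to attach.
#' @return Data frame of flagged records: `record`, `lambda_pm`,
#'   `threshold` (the smallest threshold under which the record flags),
#'   plus residual columns when supplied.
#' @export
flag_outliers <- function(lambda_means, thresholds = c(0.3, 0.2),
                          residuals = NULL) {
  if (inherits(lambda_means, "sire_chain")) {
    lambda_means <- lambda_means$lambda_mean
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  flagged <- which(lambda_means < max(thresholds))
  tightest <- vapply(lambda_means[flagged], function(l) {
    min(thresholds[thresholds > l])
  }, numeric(1))
  out <- data.frame(record = flagged, lambda_pm = lambda_means[flagged],
                    threshold = tightest)
  if (!is.null(residuals)) {
    res <- rbind(residuals)[flagged, , drop = FALSE]
    colnames(res) <- paste0("residual_",
                            colnames(res) %||% seq_len(ncol(res)))
    out <- cbind(out, res)
  }
  out[order(out$lambda_pm), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction-quality metrics for sire evaluations
#'
#' Per trait: Pearson correlation between true and predicted sire effects,
#' the prediction error variance `PEV = Var(a - a_hat)`, and, when a second
#' model's predictions are supplied, the Kendall tau-b rank correlation
#' between the two models' predictions and their top-k overlap (fraction of
#' shared sires among each model's best k, ranking in decreasing order of
#' the prediction).
#'
#' @param true_effects n x m matrix (or vector) of simulated true effects.
#' @param predicted n x m matrix of posterior-mean predictions.
#' @param alt_predicted Optional n x m matrix from a second model.
#' @param k Top-list size for the overlap (default `min(100, n)`).
#' @return List of class `evaluation_report` with per-trait `accuracy`,
#'   `pev`, and (when applicable) `kendall_tau`, `topk_overlap`, `k`.
#' @export
evaluate_predictions <- function(true_effects, predicted,
                                 alt_predicted = NULL, k = NULL) {
  a <- as.matrix(true_effects)
  ah <- as.matrix(predicted)
  if (!all(dim(a) == dim(ah))) stop("true/predicted dimensions differ")
  m <- ncol(a)
  k <- k %||% min(100L, nrow(a))
  acc <- vapply(seq_len(m), function(t) stats::cor(a[, t], ah[, t]),
                numeric(1))
  pev <- vapply(seq_len(m), function(t) stats::var(a[, t] - ah[, t]),
                numeric(1))
  out <- list(accuracy = acc, pev = pev)
  if (!is.null(alt_predicted)) {
    ah2 <- as.matrix(alt_predicted)
    if (!all(dim(ah2) == dim(ah))) stop("alt_predicted dimensions differ")
    out$kendall_tau <- vapply(seq_len(m), function(t) {
      stats::cor(ah[, t], ah2[, t], method = "kendall")
    }, numeric(1))
    out$topk_overlap <- vapply(seq_len(m), function(t) {
      top1 <- order(ah[, t], decreasing = TRUE)[seq_len(k)]
      top2 <- order(ah2[, t], decreasing = TRUE)[seq_len(k)]
      length(intersect(top1, top2)) / k
    }, numeric(1))
    out$k <- k
  }
  structure(out, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("accuracy r(a_hat, a):", signif(x$accuracy, 3), "\n")
  cat("prediction error variance:", signif(x$pev, 3), "\n")
  if (!is.null(x$kendall_tau)) {
    cat("Kendall tau vs alternative model:", signif(x$kendall_tau, 3), "\n")
    cat("top-", x$k, " overlap: ", paste(signif(x$topk_overlap, 3),
                                         collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
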