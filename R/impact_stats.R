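#' Summary statistics and histogram bins for index scores
#'
#' @param scores numeric vector of integer index scores (non-empty).
#' @return List with `mean`, `sd` (sample SD, n-1 denominator), `n`, and
#'   `histogram`: a data.frame of integer-valued bins covering the observed
#'   range with their counts.
#' @export
summarize_scores <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  bins <- seq(floor(min(scores)), ceiling(max(scores)))
  counts <- tabulate(match(round(scores), bins), nbins = length(bins))
  list(mean = mean(scores),
       sd = stats::sd(scores),
       n = length(scores),
       histogram = data.frame(score = bins, count = counts))
}

#' Paired Student's t test between aligned score vectors
#'
#' Classic paired t on the per-stay differences, two-sided, df = n - 1.
#' Zero-variance differences (e.g. identical codings) return the defined
#' result t = 0, p = 1 rather than NaN.
#'
#' @param scores_a,scores_b equal-length numeric vectors aligned by stay.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors differ in length", call. = FALSE)
  }
  n <- length(scores_a)
  if (n < 2L) stop("paired t test needs at least 2 pairs", call. = FALSE)
  d <- scores_a - scores_b
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t = 0, df = n - 1L, p = 1, mean_diff = mean(d)))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       mean_diff = mean(d))
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param scores_a,scores_b equal-length numeric vectors (n >= 4), neither
#'   constant.
#' @param confidence confidence level of the interval (default 0.95).
#' @return List with `r`, `ci_low`, `ci_high`, `confidence`, `n`.
#' @export
pearson_with_ci <- function(scores_a, scores_b, confidence = 0.95) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors differ in length", call. = FALSE)
  }
  n <- length(scores_a)
  if (n < 4L) stop("Pearson CI needs at least 4 pairs", call. = FALSE)
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    stop("correlation undefined: constant input vector", call. = FALSE)
  }
  r <- stats::cor(scores_a, scores_b)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm((1 + confidence) / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - half), ci_high = tanh(z + half),
       confidence = confidence, n = n)
}

#' Backward stepwise logistic regression on comorbidity indicators
#'
#' Fits mortality on the category indicator matrix by maximum-likelihood
#' logistic regression, then repeatedly removes the covariate with the
#' largest Wald p-value at or above the elimination threshold and refits,
#' until every retained covariate is below the threshold. The intercept is
#' always retained. Quasi-separated covariates (coefficient magnitude
#' drifting beyond `separation_limit`) are removed with a warning.
#'
#' @param flags logical/numeric matrix of per-stay category indicators
#'   (columns named by category).
#' @param outcome logical/0-1 vector of per-stay deaths (both classes must
#'   be present; `length(outcome) must exceed `ncol(flags)`).
#' @param threshold Wald p-value at/above which a covariate is eliminated
#'   (default 0.05).
#' @param separation_limit coefficient magnitude treated as quasi-separation
#'   (default 15).
#' @return List of class `reweight_result`: `coefficients` (log-odds, NA for
#'   eliminated), `se`, `p_values`, `retained` (character), `intercept`,
#'   `n_observations`, `steps` (elimination log).
#' @export
backward_stepwise_logistic <- function(flags, outcome, threshold = 0.05,
                                       separation_limit = 15) {
  x <- as.matrix(flags) * 1
  y <- as.integer(as.logical(outcome))
  if (length(y) != nrow(x)) stop("outcome length mismatch", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic model is undefined",
         call. = FALSE)
  }
  if (is.null(colnames(x)) && ncol(x) > 0L) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (nrow(x) <= ncol(x)) {
    stop("need more observations than covariates", call. = FALSE)
  }
  all_vars <- colnames(x)
  active <- all_vars
  # drop constant indicators up front: their coefficient is not identifiable
  const <- active[apply(x[, active, drop = FALSE], 2L, function(v) length(unique(v)) == 1L)]
  if (length(const)) {
    warning("dropping constant indicator(s): ", paste(const, collapse = ", "),
            call. = FALSE)
    active <- setdiff(active, const)
  }
  steps <- character()
  fit <- NULL
  repeat {
    if (length(active) == 0L) {
      fit <- stats::glm(y ~ 1, family = stats::binomial())
      break
    }
    dat <- data.frame(y = y, x[, active, drop = FALSE], check.names = FALSE)
    fit <- stats::glm(y ~ ., data = dat, family = stats::binomial())
    cf <- summary(fit)$coefficients
    rows <- setdiff(rownames(cf), "(Intercept)")
    nm <- gsub("^`|`$", "", rows)
    beta <- cf[rows, "Estimate"]
    sep <- abs(beta) > separation_limit | is.na(beta)
    if (!fit$converged && !any(sep)) {
      stop("logistic fit failed to converge at step ",
           length(steps) + 1L, " with covariates: ",
           paste(nm, collapse = ", "), call. = FALSE)
    }
    if (any(sep)) {
      drop_var <- nm[which(sep)[[1L]]]
      warning("removing quasi-separated covariate ", drop_var,
              " (|coefficient| > ", separation_limit, ")", call. = FALSE)
      steps <- c(steps, paste0("separation:", drop_var))
      active <- setdiff(active, drop_var)
      next
    }
    p <- cf[rows, "Pr(>|z|)"]
    if (length(p) && max(p) >= threshold) {
      drop_var <- nm[which.max(p)]
      steps <- c(steps, paste0("p=", signif(max(p), 4), ":", drop_var))
      active <- setdiff(active, drop_var)
      next
    }
    break
  }
  cf <- summary(fit)$coefficients
  rows <- setdiff(rownames(cf), "(Intercept)")
  nm <- gsub("^`|`$", "", rows)
  coefs <- stats::setNames(rep(NA_real_, length(all_vars)), all_vars)
  ses <- pvals <- coefs
  coefs[nm] <- cf[rows, "Estimate"]
  ses[nm] <- cf[rows, "Std. Error"]
  pvals[nm] <- cf[rows, "Pr(>|z|)"]
  structure(list(coefficients = coefs, se = ses, p_values = pvals,
                 retained = nm,
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 n_observations = length(y), threshold = threshold,
                 steps = steps),
            class = "reweight_result")
}

#' @export
print.reweight_result <- function(x, ...) {
  cat("<reweight_result> ", length(x$retained), "/",
      length(x$coefficients), " categories retained (Wald p < ",
      x$threshold, "), n = ", x$n_observations, "\n", sep = "")
  invisible(x)
}

#' Derive integer category weights from regression coefficients
#'
#' Each retained category's weight is its regression coefficient divided by
#' the retained coefficient with the smallest absolute value, rounded to
#' the nearest whole number (half away from zero, preserving sign
#' symmetry). Eliminated categories receive weight 0. By construction the
#' minimum absolute weight among retained categories is 1 and each weight
#' keeps the sign of its coefficient.
#'
#' @param coefficients named numeric vector of log-odds coefficients (NA
#'   allowed for eliminated categories).
#' @param retained character vector of retained category names (non-empty).
#' @return Named integer vector of weights over all categories.
#' @export
derive_integer_weights <- function(coefficients, retained) {
  if (length(retained) == 0L) {
    stop("no retained categories: cannot derive weights", call. = FALSE)
  }
  beta <- coefficients[retained]
  if (anyNA(beta)) stop("retained category without a coefficient", call. = FALSE)
  m <- min(abs(beta))
  if (m == 0) {
    stop("degenerate model: a retained coefficient is exactly 0", call. = FALSE)
  }
  ratio <- beta / m
  w_ret <- sign(ratio) * floor(abs(ratio) + 0.5)  # half away from zero
  w <- stats::setNames(rep(0L, length(coefficients)), names(coefficients))
  w[retained] <- as.integer(w_ret)
  w
}

#' Convenience: stepwise reweighting plus integer weight derivation
#'
#' @inheritParams backward_stepwise_logistic
#' @return The `reweight_result` with an added `weights` element (integer
#'   weights per category; all-zero when no category is retained).
#' @export
reweight_categories <- function(flags, outcome, threshold = 0.05,
                                separation_limit = 15) {
  res <- backward_stepwise_logistic(flags, outcome, threshold,
                                    separation_limit)
  res$weights <- if (length(res$retained)) {
    derive_integer_weights(res$coefficients, res$retained)
  } else {
    stats::setNames(rep(0L, length(res$coefficients)), names(res$coefficients))
  }
  res
}

#' Spearman rank correlation between weight vectors
#'
#' Rank correlation with average ranks for ties; the two-sided p-value uses
#' the t-distribution approximation (appropriate for the 17/31-category
#' weight vectors compared here).
#'
#' @param weights_a,weights_b equal-length numeric vectors aligned by
#'   category (n >= 3).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rank <- function(weights_a, weights_b) {
  if (length(weights_a) != length(weights_b)) {
    stop("weight vectors differ in length", call. = FALSE)
  }
  n <- length(weights_a)
  if (n < 3L) stop("Spearman needs at least 3 categories", call. = FALSE)
  ra <- rank(weights_a); rb <- rank(weights_b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("correlation undefined: constant weight vector", call. = FALSE)
  }
  rho <- stats::cor(ra, rb)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare score distributions between two codings of the same stays
#'
#' Bundles the distribution comparison of the study: per-population mean
#' and SD, paired t test, and Pearson correlation with Fisher interval.
#'
#' @param scores_a,scores_b aligned score vectors (same stays, two codings).
#' @param index label carried into the result.
#' @param confidence Pearson CI level.
#' @return List of class `distribution_comparison`.
#' @export
compare_distributions <- function(scores_a, scores_b, index = "CCI",
                                  confidence = 0.95) {
  sa <- summarize_scores(scores_a)
  sb <- summarize_scores(scores_b)
  tt <- paired_t(scores_a, scores_b)
  pr <- if (stats::sd(scores_a) > 0 && stats::sd(scores_b) > 0) {
    pearson_with_ci(scores_a, scores_b, confidence)
  } else {
    list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         confidence = confidence, n = length(scores_a))
  }
  structure(list(index = index,
                 mean_a = sa$mean, sd_a = sa$sd,
                 mean_b = sb$mean, sd_b = sb$sd,
                 t_statistic = tt$t, degrees_of_freedom = tt$df,
                 p_value = tt$p,
                 pearson_r = pr$r, pearson_ci_low = pr$ci_low,
                 pearson_ci_high = pr$ci_high, confidence = confidence,
                 n = length(scores_a),
                 histogram_a = sa$histogram, histogram_b = sb$histogram),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat("<distribution_comparison> ", x$index, " over ", x$n, " stays\n",
      sep = "")
  cat(sprintf("  A: mean %.3f (SD %.3f);  B: mean %.3f (SD %.3f)\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  cat(sprintf("  paired t = %.3f (df %d, p = %.3g); Pearson r = %.4f (%g%% CI %.4f-%.4f)\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$pearson_r,
              100 * x$confidence, x$pearson_ci_low, x$pearson_ci_high))
  invisible(x)
}
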