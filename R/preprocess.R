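# ---- normalization, imputation, differential expression, power -------------

new_normalized_matrix <- function(values, method, imputed_mask = NULL) {
  if (is.null(imputed_mask)) {
    imputed_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  }
  structure(values, scale = "log2_normalized", method = method,
            imputed_mask = imputed_mask,
            class = c("normalized_matrix", "intensity_matrix", class(values)))
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every sample onto the common distribution of per-rank means, as is
#' standard for near-complete DIA protein matrices. Tied values receive the
#' mean of the reference values at their tied ranks; missing values are left
#' missing (impute afterwards with [impute_sequential()]). A log2 transform
#' with a pseudo-count follows normalization.
#'
#' @param matrix Raw-scale [intensity_matrix()] with >= 2 samples.
#' @param log2_transform Apply `log2(x + offset)` after normalization.
#' @param offset Pseudo-count for the log step (default 1).
#' @return A `normalized_matrix` (scale `log2_normalized`, method
#'   `"quantile"`).
#' @export
quantile_normalize <- function(matrix, log2_transform = TRUE, offset = 1) {
  stopifnot_raw(matrix)
  if (ncol(matrix) < 2) stop("quantile normalization needs >= 2 samples")
  v <- unclass(matrix)
  qn <- limma::normalizeQuantiles(v, ties = TRUE)
  if (log2_transform) qn <- log2(qn + offset)
  dimnames(qn) <- dimnames(v)
  new_normalized_matrix(qn, method = "quantile")
}

#' Scaling-factor normalize an intensity matrix
#'
#' Each sample is multiplied by `median(sample totals) / (its total)` so that
#' all sample totals agree, then log2-transformed with a pseudo-count.
#' Within-sample ratios are unchanged. This is the usual total-intensity
#' scaling applied to TMT reporter data.
#'
#' @inheritParams quantile_normalize
#' @return A `normalized_matrix` (method `"scaling_factor"`).
#' @export
scaling_factor_normalize <- function(matrix, log2_transform = TRUE,
                                     offset = 1) {
  stopifnot_raw(matrix)
  v <- unclass(matrix)
  totals <- colSums(v, na.rm = TRUE)
  if (any(totals <= 0)) stop("sample with zero total intensity")
  factors <- median(totals) / totals
  out <- sweep(v, 2, factors, `*`)
  if (log2_transform) out <- log2(out + offset)
  res <- new_normalized_matrix(out, method = "scaling_factor")
  attr(res, "scaling_factors") <- factors
  res
}

#' Sequential conditional-mean imputation
#'
#' Rows (protein groups) are processed in increasing order of missing count.
#' Each row's missing cells are filled with the conditional mean of a
#' multivariate normal over samples whose mean vector and covariance matrix
#' are estimated from the currently complete rows; after a row is imputed it
#' joins the complete set, so later rows see updated estimates. Observed
#' values are never altered. Suitable for the low missingness (about 1-2%
#' per sample) typical of DIA protein matrices.
#'
#' @param matrix A `normalized_matrix` (or any numeric matrix on log scale).
#' @param ridge Diagonal regularization added to the observed-block
#'   covariance before inversion, relative to its mean diagonal.
#' @return The matrix with no missing values and an updated `imputed_mask`
#'   attribute marking every filled cell.
#' @export
impute_sequential <- function(matrix, ridge = 1e-8) {
  v <- unclass(matrix)
  mask <- is.na(v)
  if (!any(mask)) {
    return(new_normalized_matrix(v, method = attr(matrix, "method") %||% "none",
                                 imputed_mask = mask))
  }
  complete <- which(!apply(mask, 1, any))
  if (length(complete) == 0) stop("no complete rows to estimate from")
  if (length(complete) < 3) stop("need >= 3 complete rows")
  incomplete <- setdiff(seq_len(nrow(v)), complete)
  incomplete <- incomplete[order(rowSums(mask[incomplete, , drop = FALSE]))]
  pool <- v[complete, , drop = FALSE]
  for (r in incomplete) {
    mu <- colMeans(pool)
    sigma <- stats::cov(pool)
    obs <- which(!mask[r, ])
    mis <- which(mask[r, ])
    if (length(obs) == 0) {
      v[r, mis] <- mu[mis]
    } else {
      s_oo <- sigma[obs, obs, drop = FALSE]
      diag(s_oo) <- diag(s_oo) + ridge * mean(diag(s_oo))
      s_mo <- sigma[mis, obs, drop = FALSE]
      v[r, mis] <- mu[mis] +
        as.vector(s_mo %*% solve(s_oo, v[r, obs] - mu[obs]))
    }
    pool <- rbind(pool, v[r, , drop = FALSE])
  }
  new_normalized_matrix(v, method = attr(matrix, "method") %||% "none",
                        imputed_mask = mask)
}

#' Blocked differential expression between two conditions
#'
#' Per protein group, fits an ordinary linear model of log2 intensity on
#' condition, with the TMT plex entering as an additive fixed block term
#' when more than one plex is present (with a single plex the term is
#' dropped). Two-sided p-values come from the condition coefficient's t
#' statistic; Benjamini-Hochberg adjustment is applied across all tested
#' proteins of the experiment.
#'
#' @param matrix A `normalized_matrix`.
#' @param metadata A [sample_metadata()] covering the matrix's samples.
#' @param contrast Length-2 character vector `c(conditionA, conditionB)`;
#'   the reported fold change is A minus B in log2 units.
#' @param q_threshold Significance cut-off on the adjusted p-value for the
#'   `pct_significant` summary (default 0.05).
#' @return A `de_result` `data.frame` with columns `protein`, `log2fc`,
#'   `p_value`, `q_value`, `tested`; attribute `pct_significant`.
#' @export
differential_expression <- function(matrix, metadata, contrast,
                                    q_threshold = 0.05) {
  if (length(contrast) != 2) stop("contrast must name two conditions")
  if (!all(contrast %in% metadata$condition))
    stop("condition absent from metadata: ",
         paste(setdiff(contrast, metadata$condition), collapse = ", "))
  meta <- metadata[metadata$condition %in% contrast, , drop = FALSE]
  meta <- meta[meta$sample_id %in% colnames(matrix), , drop = FALSE]
  v <- unclass(matrix)[, meta$sample_id, drop = FALSE]
  cond <- factor(meta$condition, levels = c(contrast[2], contrast[1]))
  if (any(table(cond) < 2)) stop("need >= 2 samples per condition")
  plex <- meta$plex
  use_plex <- length(unique(plex[!is.na(plex)])) > 1
  n <- nrow(v)
  log2fc <- p <- rep(NA_real_, n)
  tested <- rep(FALSE, n)
  for (i in seq_len(n)) {
    y <- v[i, ]
    ok <- !is.na(y)
    if (min(table(cond[ok])) < 2) next
    df <- data.frame(y = y[ok], cond = droplevels(cond[ok]))
    if (use_plex) df$plex <- factor(plex[ok])
    fit <- if (use_plex && nlevels(df$plex) > 1)
      lm(y ~ cond + plex, data = df) else lm(y ~ cond, data = df)
    sm <- summary(fit)$coefficients
    row <- grep("^cond", rownames(sm))
    if (!length(row) || nrow(sm) < 2) next
    log2fc[i] <- sm[row[1], "Estimate"]
    p[i] <- sm[row[1], "Pr(>|t|)"]
    tested[i] <- TRUE
  }
  q <- rep(NA_real_, n)
  q[tested] <- p.adjust(p[tested], method = "BH")
  out <- data.frame(protein = rownames(v), log2fc = log2fc,
                    p_value = p, q_value = q, tested = tested,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "pct_significant") <-
    100 * sum(q < q_threshold, na.rm = TRUE) / sum(tested)
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Per-test alpha after Bonferroni-style family correction
#'
#' @param alpha_family Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha_family / n_tests`.
#' @export
corrected_alpha <- function(alpha_family, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha_family / n_tests
}

# exact power of a two-sided two-sample t-test via the noncentral t
two_sample_t_power <- function(n_per_group, d, alpha) {
  df <- 2 * n_per_group - 2
  ncp <- abs(d) * sqrt(n_per_group / 2)
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp)
}

#' Minimal per-group sample size for a two-sample t-test
#'
#' Smallest `n` per group reaching `power_target` for a two-tailed
#' two-sample t-test at `alpha_per_test`, evaluated with the exact
#' noncentral-t power function. The floor is 2 per group.
#'
#' @param effect_size_d Standardized difference (Cohen's d), non-zero.
#' @param alpha_per_test Per-test significance level in (0, 1).
#' @param power_target Target power in (0, 1).
#' @return Integer sample size per group.
#' @export
sample_size_two_sample_t <- function(effect_size_d, alpha_per_test,
                                     power_target) {
  if (effect_size_d == 0) stop("effect size must be non-zero")
  if (alpha_per_test <= 0 || alpha_per_test >= 1) stop("alpha out of (0,1)")
  if (power_target <= 0 || power_target >= 1) stop("power out of (0,1)")
  lo <- 2L
  if (two_sample_t_power(lo, effect_size_d, alpha_per_test) >= power_target)
    return(lo)
  hi <- 4L
  while (two_sample_t_power(hi, effect_size_d, alpha_per_test) < power_target) {
    lo <- hi
    hi <- hi * 2L
    if (hi > 1e6) stop("target power unreachable within n <= 1e6")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (two_sample_t_power(mid, effect_size_d, alpha_per_test) >= power_target)
      hi <- mid else lo <- mid
  }
  hi
}
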