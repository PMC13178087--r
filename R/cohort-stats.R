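#' Median and interquartile range of a parameter
#'
#' Summaries follow the Me \[Q1; Q3\] convention. Quartiles are Tukey hinges
#' (the inclusive-median rule of [stats::fivenum()]): the hinges are medians
#' of the lower and upper halves with the overall median included in both
#' when n is odd. This rule is fixed and documented because common software
#' defaults differ.
#'
#' @param x Numeric vector, non-empty.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`.
#' @examples
#' quartile_summary(c(1, 2, 3, 4, 5)) # median 3 [2; 4]
#' @export
quartile_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) abort("cannot summarise an empty vector")
  fn <- fivenum(x)
  tibble(n = length(x), median = fn[3], q1 = fn[2], q3 = fn[4])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

rank_u <- function(g0, g1) {
  n0 <- length(g0); n1 <- length(g1)
  r <- rank(c(g0, g1))
  u1 <- sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  list(u1 = u1, u0 = n0 * n1 - u1, n0 = n0, n1 = n1, ranks = r)
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The reported `u_statistic` is the
#' smaller of the two orientations (so `u_statistic + u_other = n0 * n1`).
#' Modes:
#' * `"exact"` — exact two-sided p from the null distribution of U when the
#'   data have no ties; with ties, a seeded Monte-Carlo permutation p
#'   (`n_perm` label reshuffles).
#' * `"asymptotic"` — normal approximation with tie correction and
#'   continuity correction.
#' * `"auto"` (default) — exact when `n0 + n1 <= exact_limit` and there are
#'   no ties, asymptotic otherwise.
#'
#' @param g0,g1 Numeric samples for the two groups.
#' @param mode `"auto"`, `"exact"` or `"asymptotic"`.
#' @param exact_limit Largest `n0 + n1` for which `"auto"` picks the exact
#'   test.
#' @param n_perm Permutation draws for the tied exact mode.
#' @param perm_seed Seed for the permutation draws (local to the call).
#' @return A one-row tibble: `u_statistic`, `u_g0`, `u_g1`, `p_value`,
#'   `n0`, `n1`, `method`.
#' @export
mann_whitney <- function(g0, g1, mode = c("auto", "exact", "asymptotic"),
                         exact_limit = 25L, n_perm = 1e5, perm_seed = 1L) {
  mode <- match.arg(mode)
  g0 <- g0[!is.na(g0)]; g1 <- g1[!is.na(g1)]
  if (length(g0) == 0L || length(g1) == 0L) abort("both groups must be non-empty")
  u <- rank_u(g0, g1)
  n0 <- u$n0; n1 <- u$n1; N <- n0 + n1
  ties <- anyDuplicated(c(g0, g1)) > 0L
  out <- function(p, method) tibble(
    u_statistic = min(u$u0, u$u1), u_g0 = u$u0, u_g1 = u$u1,
    p_value = min(1, p), n0 = n0, n1 = n1, method = method
  )
  if (length(unique(c(g0, g1))) == 1L) {
    warn("all values identical in both groups; p = 1")
    return(out(1, "degenerate"))
  }
  if (mode == "auto") {
    mode <- if (!ties && N <= exact_limit) "exact" else "asymptotic"
  }
  if (mode == "exact" && !ties) {
    p_lo <- pwilcox(u$u1, n1, n0)
    p_hi <- 1 - pwilcox(u$u1 - 1, n1, n0)
    return(out(2 * min(p_lo, p_hi), "exact"))
  }
  if (mode == "exact") {
    mu <- n0 * n1 / 2
    obs <- abs(u$u1 - mu)
    pooled <- c(g0, g1)
    exceed <- with_local_seed(perm_seed, {
      sum(vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(N, n1)
        u1p <- sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
        abs(u1p - mu) >= obs - 1e-9
      }, logical(1)))
    })
    return(out((1 + exceed) / (n_perm + 1), "permutation"))
  }
  # asymptotic with tie correction
  tie_tab <- table(c(g0, g1))
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n0 * n1 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    warn("zero rank variance; p = 1")
    return(out(1, "degenerate"))
  }
  mu <- n0 * n1 / 2
  z <- (u$u1 - mu - sign(u$u1 - mu) * 0.5) / sqrt(sigma2)
  out(2 * pnorm(-abs(z)), "asymptotic")
}

#' Rank-based ROC AUC against a binary outcome
#'
#' AUC from the Mann-Whitney rank formulation with midranks for ties:
#' `AUC_raw = U1 / (n0 * n1)`, the probability that a random positive case
#' has a higher predictor value than a random negative one (ties count 1/2).
#' The reported AUC is oriented to be at least 0.5; `direction` records
#' whether the positive class has the higher or the lower predictor values,
#' so a protective index (lower in cases) is reported explicitly rather than
#' silently flipped.
#'
#' @param predictor Numeric predictor values.
#' @param outcome Binary outcome (0/1, logical, or a two-level factor);
#'   1 / TRUE / second level is the positive class.
#' @return A one-row tibble of class `roc_result`: `auc`, `auc_raw`,
#'   `direction` (`"higher_in_positive"` or `"lower_in_positive"`), `n0`,
#'   `n1`; ROC curve points are attached as attribute `"points"` (see
#'   [roc_points()]).
#' @export
roc_auc <- function(predictor, outcome) {
  outcome <- as_binary_outcome(outcome)
  keep <- !is.na(predictor) & !is.na(outcome)
  predictor <- predictor[keep]; outcome <- outcome[keep]
  if (length(unique(outcome)) < 2L) {
    abort("outcome must contain both classes")
  }
  u <- rank_u(predictor[outcome == 0], predictor[outcome == 1])
  auc_raw <- u$u1 / (u$n0 * u$n1)
  direction <- if (auc_raw >= 0.5) "higher_in_positive" else "lower_in_positive"
  auc <- max(auc_raw, 1 - auc_raw)
  s <- if (direction == "higher_in_positive") predictor else -predictor
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE))
  pts <- tibble(
    threshold = cuts,
    tpr = vapply(cuts, function(t) mean(s[outcome == 1] >= t), numeric(1)),
    fpr = vapply(cuts, function(t) mean(s[outcome == 0] >= t), numeric(1))
  )
  structure(
    tibble(auc = auc, auc_raw = auc_raw, direction = direction,
           n0 = u$n0, n1 = u$n1),
    points = pts,
    class = c("roc_result", class(tibble()))
  )
}

as_binary_outcome <- function(outcome) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (!all(outcome %in% c(0, 1, NA))) {
    abort("outcome must be binary (0/1, logical, or a two-level factor)")
  }
  outcome
}

#' ROC curve points of a [roc_auc()] result
#' @param x A `roc_result`.
#' @return Tibble with `threshold`, `tpr`, `fpr` (threshold on the oriented
#'   predictor).
#' @export
roc_points <- function(x) attr(x, "points")

#' Compare the morphometric parameters between two outcome groups
#'
#' For each parameter (TAIM, OIMR, total index) computes the per-group
#' median \[Q1; Q3\], the two-sided Mann-Whitney test and the rank-based ROC
#' AUC of the parameter against the group label. Group 0 is the reference
#' (e.g. no atrial fibrillation), group 1 the positive class.
#'
#' @param results Per-patient results tibble with `group_label` and the
#'   parameter columns (see [compute_morphometry()]).
#' @param parameters Character vector of parameter columns to compare.
#' @param ... Passed to [mann_whitney()] (e.g. `mode`, `exact_limit`).
#' @return A tibble of class `cohort_comparison`, one row per parameter,
#'   with per-group summaries, `u_statistic`, `p_value`, `auc` and
#'   `auc_direction`; ROC results are attached per parameter (attribute
#'   `"roc"`), and the input data as attribute `"data"` for plotting.
#' @export
compare_cohort <- function(results,
                           parameters = c("taim_pct", "oimr_pct", "total_index"),
                           ...) {
  if (!"group_label" %in% names(results)) abort("results need a group_label column")
  grp <- as_binary_outcome(results$group_label)
  missing <- setdiff(parameters, names(results))
  if (length(missing)) {
    abort(paste0("results are missing parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (g in 0:1) {
    if (sum(grp == g, na.rm = TRUE) < 2L) {
      abort(paste0("group ", g, " has fewer than 2 patients"))
    }
  }
  rocs <- list()
  rows <- purrr::map(parameters, function(p) {
    v0 <- results[[p]][grp == 0]
    v1 <- results[[p]][grp == 1]
    s0 <- quartile_summary(v0); s1 <- quartile_summary(v1)
    mw <- mann_whitney(v0, v1, ...)
    rc <- roc_auc(results[[p]], grp)
    rocs[[p]] <<- rc
    tibble(
      parameter = p,
      n_g0 = s0$n, median_g0 = s0$median, q1_g0 = s0$q1, q3_g0 = s0$q3,
      n_g1 = s1$n, median_g1 = s1$median, q1_g1 = s1$q1, q3_g1 = s1$q3,
      u_statistic = mw$u_statistic, p_value = mw$p_value,
      auc = rc$auc, auc_direction = rc$direction
    )
  })
  structure(
    dplyr::bind_rows(rows),
    roc = rocs, data = results,
    class = c("cohort_comparison", class(tibble()))
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("Two-group comparison (Mann-Whitney, rank ROC)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-12s %5.1f [%.1f; %.1f] vs %5.1f [%.1f; %.1f]   U=%g, p=%.3f, AUC=%.3f (%s)\n",
      x$parameter[i],
      x$median_g0[i], x$q1_g0[i], x$q3_g0[i],
      x$median_g1[i], x$q1_g1[i], x$q3_g1[i],
      x$u_statistic[i], x$p_value[i], x$auc[i], x$auc_direction[i]
    ))
  }
  invisible(x)
}

#' @rdname compare_cohort
#' @param x A `cohort_comparison`.
#' @exportS3Method generics::tidy
tidy.cohort_comparison <- function(x, ...) {
  as_tibble(unclass(x)[names(x)[vapply(x, is.atomic, logical(1))]])
}

#' @rdname compare_cohort
#' @exportS3Method generics::glance
glance.cohort_comparison <- function(x, ...) {
  tibble(
    n_patients = x$n_g0[1] + x$n_g1[1],
    n_g0 = x$n_g0[1], n_g1 = x$n_g1[1],
    n_parameters = nrow(x),
    n_significant = sum(x$p_value <= 0.05)
  )
}

#' Box-and-point plot of a cohort comparison
#'
#' @param object A `cohort_comparison`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_comparison <- function(object, ...) {
  d <- attr(object, "data")
  long <- tidyr::pivot_longer(
    d[, c("group_label", object$parameter)],
    -"group_label", names_to = "parameter", values_to = "value"
  )
  long$group <- factor(as_binary_outcome(long$group_label))
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "group", y = NULL)
}

#' ROC curve plot for one compared parameter
#'
#' @param x A `cohort_comparison`.
#' @param parameter Which parameter's ROC to plot.
#' @return A ggplot of the ROC step curve with the AUC in the subtitle.
#' @export
plot_roc <- function(x, parameter = "total_index") {
  rc <- attr(x, "roc")[[parameter]]
  if (is.null(rc)) abort(paste0("no ROC stored for parameter '", parameter, "'"))
  pts <- roc_points(rc)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0("ROC: ", parameter),
      subtitle = sprintf("AUC = %.3f (%s)", rc$auc, rc$direction),
      x = "false positive rate", y = "true positive rate"
    )
}
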