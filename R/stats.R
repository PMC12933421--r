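#' @name stats_analysis
#' @title Contingency-table analysis of evacuation outcomes
#'
#' @description
#' The analysis layer turns per-condition evacuation counts into the study's
#' inferential results: a chi-square test of independence on the condition x
#' outcome table with adjusted standardized residuals, pooled compliance
#' rates by message framing, grouped logistic regression odds ratios against
#' the control framing, and the a-priori noncentral chi-square sample-size
#' computation.
NULL

#' Build a condition-by-outcome contingency table
#'
#' @param x One of: an `experiment_result` from [run_experiment()], a data
#'   frame with columns `condition_id` (or `condition`), `evacuated` and
#'   `not_evacuated`, or a path to a CSV file with those columns.
#' @return A `contingency_table` list with `row_labels`, a `counts` matrix
#'   (columns `evacuated`, `not_evacuated`), `row_totals`, `col_totals` and
#'   `grand_total`.
#' @export
build_table <- function(x) {
  if (inherits(x, "experiment_result")) x <- x$per_condition_counts
  if (is.character(x) && length(x) == 1) {
    stopifnot(file.exists(x))
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  names(x)[names(x) == "condition"] <- "condition_id"
  need <- c("condition_id", "evacuated", "not_evacuated")
  if (!all(need %in% names(x))) {
    stop("counts input needs columns condition (or condition_id), evacuated, not_evacuated",
         call. = FALSE)
  }
  if (nrow(x) == 0) stop("counts input is empty", call. = FALSE)
  counts <- cbind(evacuated = as.numeric(x$evacuated),
                  not_evacuated = as.numeric(x$not_evacuated))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(row_labels = as.character(x$condition_id),
                 counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = c("contingency_table", "list"))
}

#' Bundled per-condition evacuation counts
#'
#' The packaged reference counts from the original sixteen-condition
#' messaging experiment (one control plus fifteen theory-framed conditions,
#' 3,550 agent-observations, 206 evacuated), used by the analysis examples
#' and regression tests.
#'
#' @return A `contingency_table` with 16 rows.
#' @export
reference_counts <- function() {
  build_table(system.file("extdata", "condition_counts.csv",
                          package = "evactwin"))
}

#' Chi-square test of independence with adjusted standardized residuals
#'
#' Pearson chi-square on the condition x outcome table (no continuity
#' correction), with df = (rows - 1)(cols - 1), the upper-tail p-value, and
#' the cell-level adjusted standardized residuals
#' (O - E) / sqrt(E (1 - row/N)(1 - col/N)), which are approximately
#' standard normal under independence. Cells whose absolute residual
#' exceeds `star_threshold` are flagged; the default threshold is the
#' two-sided Bonferroni z-critical value at level `alpha` over all cells.
#'
#' @param table A `contingency_table`.
#' @param alpha Family-wise level for residual flagging.
#' @param star_threshold Absolute-residual flagging threshold; overrides the
#'   Bonferroni default when supplied.
#' @return A `chi_square_result` list with `statistic`, `df`, `p_value`,
#'   `expected`, `adjusted_residuals` (rows x 2) and logical `starred`.
#' @examples
#' chi_square_test(reference_counts())$statistic
#' @export
chi_square_test <- function(table, alpha = 0.05, star_threshold = NULL) {
  stopifnot(inherits(table, "contingency_table"))
  if (table$grand_total <= 0) stop("grand total must be positive", call. = FALSE)
  if (any(table$row_totals == 0) || any(table$col_totals == 0)) {
    stop("zero row or column marginal: expected counts undefined", call. = FALSE)
  }
  ht <- stats::chisq.test(table$counts, correct = FALSE)
  resid <- ht$stdres
  dimnames(resid) <- dimnames(table$counts)
  rownames(resid) <- table$row_labels
  if (is.null(star_threshold)) {
    star_threshold <- stats::qnorm(1 - alpha / (2 * length(table$counts)))
  }
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 expected = ht$expected,
                 adjusted_residuals = resid,
                 star_threshold = star_threshold,
                 starred = abs(resid) > star_threshold),
            class = c("chi_square_result", "list"))
}

#' Default condition-to-framing grouping
#'
#' Maps the bundled catalog's sixteen condition ids to their six framing
#' categories.
#'
#' @return Named character vector: condition id -> framing.
#' @export
default_framing_map <- function() {
  c(C1 = "control",
    F1 = "fear", F2 = "fear", F3 = "fear",
    E1 = "efficacy", E2 = "efficacy", E3 = "efficacy",
    M1 = "fear_efficacy", M2 = "fear_efficacy", M3 = "fear_efficacy",
    T1 = "norm", T2 = "norm", T3 = "norm",
    FEN1 = "fear_efficacy_norm", FEN2 = "fear_efficacy_norm",
    FEN3 = "fear_efficacy_norm")
}

# Pool a contingency table's rows by framing group, preserving first-seen
# group order.
pool_by_framing <- function(table, grouping) {
  unmapped <- setdiff(table$row_labels, names(grouping))
  if (length(unmapped) > 0) {
    stop(sprintf("condition '%s' has no framing mapping", unmapped[1]),
         call. = FALSE)
  }
  g <- unname(grouping[table$row_labels])
  lev <- unique(g)
  counts <- do.call(rbind, lapply(lev, function(l) {
    colSums(table$counts[g == l, , drop = FALSE])
  }))
  rownames(counts) <- lev
  counts
}

#' Pooled evacuation compliance rates by message framing
#'
#' @param table A `contingency_table`.
#' @param grouping Named vector mapping every condition id to a framing.
#' @return Data frame with `framing`, `n_agents`, `evacuated` and `rate_pct`
#'   (pooled evacuated / pooled n, in percent).
#' @examples
#' framing_rates(reference_counts())
#' @export
framing_rates <- function(table, grouping = default_framing_map()) {
  pooled <- pool_by_framing(table, grouping)
  n <- rowSums(pooled)
  data.frame(framing = rownames(pooled),
             n_agents = as.integer(n),
             evacuated = as.integer(pooled[, "evacuated"]),
             rate_pct = 100 * pooled[, "evacuated"] / n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grouped logistic regression of evacuation on message framing
#'
#' Maximum-likelihood logistic regression of the evacuation outcome on
#' framing dummies fitted to the pooled group counts, reported as odds
#' ratios against the reference framing with Wald confidence intervals on
#' the log-odds scale. Because the dummy coding saturates the grouped table,
#' each fitted odds ratio equals the closed-form 2x2 cross-product ratio
#' (a_group * d_ref) / (b_group * c_ref); the function asserts this identity.
#' If a group's 2x2 against the reference contains a zero cell the estimate
#' is infinite; a warning is raised and that group is reported from the
#' Haldane-Anscombe continuity-corrected table (0.5 added to all four
#' cells), flagged in the output.
#'
#' @inheritParams framing_rates
#' @param reference Framing used as the reference category.
#' @param conf_level Confidence level of the Wald intervals.
#' @return A `logistic_fit` list: `reference`, `baseline_odds` (evacuated /
#'   not evacuated in the reference group) and a data frame `estimates` with
#'   `framing`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `continuity_corrected`.
#' @examples
#' fit_grouped_logistic(reference_counts())$estimates
#' @export
fit_grouped_logistic <- function(table, grouping = default_framing_map(),
                                 reference = "control", conf_level = 0.95) {
  pooled <- pool_by_framing(table, grouping)
  if (!reference %in% rownames(pooled)) {
    stop(sprintf("reference framing '%s' not present", reference), call. = FALSE)
  }
  ref <- pooled[reference, ]
  if (any(ref == 0)) {
    stop("reference framing must have nonzero counts in both outcome columns",
         call. = FALSE)
  }
  lev <- c(reference, setdiff(rownames(pooled), reference))
  df <- data.frame(framing = factor(rownames(pooled), levels = lev),
                   evacuated = pooled[, "evacuated"],
                   not_evacuated = pooled[, "not_evacuated"])
  fit <- stats::glm(cbind(evacuated, not_evacuated) ~ framing,
                    family = stats::binomial(), data = df)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  others <- lev[-1]
  coef_names <- paste0("framing", others)
  est <- data.frame(framing = others,
                    odds_ratio = exp(sm[coef_names, "Estimate"]),
                    ci_low = exp(sm[coef_names, "Estimate"] -
                                   z * sm[coef_names, "Std. Error"]),
                    ci_high = exp(sm[coef_names, "Estimate"] +
                                    z * sm[coef_names, "Std. Error"]),
                    p_value = sm[coef_names, "Pr(>|z|)"],
                    continuity_corrected = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  # saturated-model identity: MLE odds ratio == cross-product ratio
  for (i in seq_along(others)) {
    g <- pooled[others[i], ]
    if (any(c(g, ref) == 0)) {
      warning(sprintf(
        "zero cell in framing '%s' vs reference: infinite MLE, reporting Haldane-Anscombe corrected estimate",
        others[i]), call. = FALSE)
      a <- g["evacuated"] + 0.5; b <- g["not_evacuated"] + 0.5
      cc <- ref["evacuated"] + 0.5; d <- ref["not_evacuated"] + 0.5
      lor <- log((a * d) / (b * cc))
      se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
      est$odds_ratio[i] <- exp(lor)
      est$ci_low[i] <- exp(lor - z * se)
      est$ci_high[i] <- exp(lor + z * se)
      est$p_value[i] <- 2 * stats::pnorm(-abs(lor / se))
      est$continuity_corrected[i] <- TRUE
    } else {
      cpr <- (g["evacuated"] * ref["not_evacuated"]) /
        (g["not_evacuated"] * ref["evacuated"])
      stopifnot(abs(est$odds_ratio[i] - cpr) <= 1e-6 * max(1, cpr))
    }
  }
  structure(list(reference = reference,
                 baseline_odds = unname(ref["evacuated"] / ref["not_evacuated"]),
                 estimates = est, fit = fit),
            class = c("logistic_fit", "list"))
}

#' A-priori sample size for a chi-square test of independence
#'
#' Smallest total n such that a noncentral chi-square variable with
#' noncentrality n * w^2 and the given degrees of freedom exceeds the
#' central critical value at level `alpha` with probability at least
#' `power`.
#'
#' @param w Cohen's w effect size (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param df Degrees of freedom of the test (>= 1).
#' @param n_max Search ceiling; exceeding it raises an unreachable-power
#'   error.
#' @return Minimum required n (integer).
#' @examples
#' required_sample_size(w = 0.3, alpha = 0.05, power = 0.80, df = 1)  # 88
#' @export
required_sample_size <- function(w, alpha = 0.05, power = 0.80, df = 1,
                                 n_max = 1e7) {
  stopifnot(w > 0, alpha > 0, alpha < 1, power > 0, power < 1, df >= 1)
  crit <- stats::qchisq(1 - alpha, df)
  achieved <- function(n) {
    stats::pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
  }
  if (achieved(n_max) < power) {
    stop("target power unreachable within the search ceiling", call. = FALSE)
  }
  lo <- 1; hi <- 1
  while (achieved(hi) < power) hi <- hi * 2
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (achieved(mid) >= power) hi <- mid else lo <- mid + 1
  }
  as.integer(lo)
}
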