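#' Welch's two-sample t-test
#'
#' Location test between two score groups without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom, two-sided p). The degenerate
#' case of two zero-variance groups is defined: equal means give p = 1,
#' different means give p = 0 with an infinite t statistic.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2; at least one
#'   group must have nonzero variance (else the degenerate contract above
#'   applies).
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = Inf, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' ROC curve and AUROC of a score
#'
#' The ROC curve is traced by sweeping the decision threshold over every
#' distinct score value, classifying a case as positive when
#' `score >= threshold` (inclusive). The AUROC equals the pairwise
#' concordance (concordant pairs plus half the tied pairs, over all
#' positive-negative pairs), computed here with the exact midrank identity.
#'
#' @param scores numeric score per case.
#' @param labels logical (or 0/1) positive-finding labels; both classes
#'   must be present.
#' @return an object of class `roc_points`: `data.frame(threshold,
#'   sensitivity, specificity)` ordered by decreasing threshold (an initial
#'   `Inf` row anchors the curve at sensitivity 0), with attribute-free
#'   list elements `points` and `auroc`.
#' @export
roc_auroc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be same-length and complete")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to trace a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n_pos, 0)
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n_neg, 0)
  rk <- rank(scores, ties.method = "average")
  auroc <- (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auroc = auroc, n_positive = n_pos, n_negative = n_neg),
            class = "roc_points")
}

#' @export
print.roc_points <- function(x, ...) {
  cat(sprintf("<roc_points> %d positives / %d negatives, AUROC = %.3f\n",
              x$n_positive, x$n_negative, x$auroc))
  invisible(x)
}

#' @export
plot.roc_points <- function(x, ...) {
  p <- x$points
  plot(1 - p$specificity, p$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3, col = "grey60")
  legend("bottomright", bty = "n", legend = sprintf("AUROC = %.3f", x$auroc))
  invisible(x)
}

#' Operating-point thresholds at a minimum sensitivity or specificity
#'
#' From a ROC curve, returns (a) the threshold with sensitivity at least
#' `min_rate` that maximizes specificity, and (b) the threshold with
#' specificity at least `min_rate` that maximizes sensitivity. Among tied
#' thresholds the larger (more conservative positive call) is reported.
#' When no threshold attains `min_rate`, that operating point reports the
#' best attainable rate and is flagged `attained = FALSE`.
#'
#' @param roc a [roc_auroc()] result.
#' @param min_rate minimum required rate (default 0.90).
#' @return list with `sensitivity_first` and `specificity_first`, each a
#'   list `(threshold, sensitivity, specificity, attained)`.
#' @export
select_thresholds <- function(roc, min_rate = 0.90) {
  stopifnot(inherits(roc, "roc_points"))
  p <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  pick <- function(constraint, objective) {
    ok <- p[[constraint]] >= min_rate
    if (any(ok)) {
      cand <- p[ok, , drop = FALSE]
      cand <- cand[cand[[objective]] == max(cand[[objective]]), , drop = FALSE]
      row <- cand[which.max(cand$threshold), , drop = FALSE]
      attained <- TRUE
    } else {
      cand <- p[p[[constraint]] == max(p[[constraint]]), , drop = FALSE]
      cand <- cand[cand[[objective]] == max(cand[[objective]]), , drop = FALSE]
      row <- cand[which.max(cand$threshold), , drop = FALSE]
      attained <- FALSE
    }
    list(threshold = row$threshold, sensitivity = row$sensitivity,
         specificity = row$specificity, attained = attained)
  }
  list(sensitivity_first = pick("sensitivity", "specificity"),
       specificity_first = pick("specificity", "sensitivity"))
}

#' Cohort score table
#'
#' Per-case 90th DP ratio scores with binary finding labels.
#'
#' @param case_id character case identifiers (unique).
#' @param score numeric finite scores >= 0.
#' @param mpdd,ppa logical labels for duct dilation and parenchymal
#'   atrophy.
#' @return a `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(case_id, score, mpdd, ppa) {
  case_id <- as.character(case_id)
  score <- as.numeric(score)
  if (anyDuplicated(case_id)) stop("case_ids must be unique")
  if (any(!is.finite(score)) || any(score < 0))
    stop("scores must be finite and >= 0")
  out <- data.frame(case_id = case_id, score = score,
                    mpdd = as.logical(mpdd), ppa = as.logical(ppa))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @rdname cohort_table
#' @param path CSV path with columns case_id, score, mpdd, ppa.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path)
  cohort_table(d$case_id, d$score, d$mpdd, d$ppa)
}

#' @rdname cohort_table
#' @param table a `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Three-group comparison with Bonferroni correction
#'
#' Pairwise Welch tests between the three groups of the evaluation design:
#' cases with both findings (MPDD and PPA), cases with MPDD only, and cases
#' with neither. Each p-value is compared against the Bonferroni-corrected
#' level alpha / 3 (0.0167 at alpha = 0.05, conventionally printed as
#' 0.016).
#'
#' @param table a [cohort_table()]; each of the three groups needs >= 2
#'   cases.
#' @param alpha family-wise significance level (default 0.05).
#' @return `data.frame(comparison, t, df, p, significant)` with the
#'   corrected level in attributes `corrected_alpha` (alpha/3) and
#'   `printed_alpha` (the 0.016 convention).
#' @export
three_group_comparison <- function(table, alpha = 0.05) {
  g <- list(
    "mpdd+ppa" = table$score[table$mpdd & table$ppa],
    "mpdd_only" = table$score[table$mpdd & !table$ppa],
    "neither" = table$score[!table$mpdd & !table$ppa])
  for (nm in names(g))
    if (length(g[[nm]]) < 2L)
      stop("group '", nm, "' has fewer than 2 cases")
  pairs <- utils::combn(names(g), 2)
  corrected <- alpha / ncol(pairs)
  res <- apply(pairs, 2, function(pr) {
    w <- welch_t_test(g[[pr[1]]], g[[pr[2]]])
    data.frame(comparison = paste(pr, collapse = " vs "),
               t = w$t, df = w$df, p = w$p, significant = w$p < corrected)
  })
  out <- do.call(rbind, res)
  attr(out, "corrected_alpha") <- corrected
  attr(out, "printed_alpha") <- floor(corrected * 1000) / 1000
  out
}

#' Evaluate a scored cohort
#'
#' The cohort evaluation design: for each finding (MPDD, PPA), group means,
#' a Welch t-test between cases with and without the finding, the ROC curve
#' and AUROC of the score, and the two >= `min_rate` operating points; plus
#' the Bonferroni-corrected three-group comparison when all three groups
#' are populated. A finding with only one class present is skipped with an
#' explicit notice.
#'
#' @param table a [cohort_table()].
#' @param min_rate operating-point requirement (default 0.90).
#' @param alpha significance level (default 0.05).
#' @return an object of class `dp_cohort_eval`.
#' @export
evaluate_cohort <- function(table, min_rate = 0.90, alpha = 0.05) {
  stopifnot(inherits(table, "cohort_table") || is.data.frame(table))
  out <- list(n = nrow(table), alpha = alpha, min_rate = min_rate)
  for (finding in c("mpdd", "ppa")) {
    lab <- table[[finding]]
    if (sum(lab) < 2L || sum(!lab) < 2L) {
      out[[finding]] <- list(skipped = TRUE,
                             reason = sprintf(
                               "fewer than 2 cases with or without %s (%d/%d)",
                               toupper(finding), sum(lab), sum(!lab)))
      next
    }
    w <- welch_t_test(table$score[lab], table$score[!lab])
    roc <- roc_auroc(table$score, lab)
    out[[finding]] <- list(
      skipped = FALSE,
      n_positive = sum(lab), n_negative = sum(!lab),
      mean_positive = mean(table$score[lab]),
      mean_negative = mean(table$score[!lab]),
      range_positive = range(table$score[lab]),
      range_negative = range(table$score[!lab]),
      welch = w, significant = w$p < alpha,
      roc = roc, auroc = roc$auroc,
      operating_points = select_thresholds(roc, min_rate))
  }
  groups_ok <- sum(table$mpdd & table$ppa) >= 2L &&
    sum(table$mpdd & !table$ppa) >= 2L &&
    sum(!table$mpdd & !table$ppa) >= 2L
  out$three_group <- if (groups_ok) three_group_comparison(table, alpha) else NULL
  structure(out, class = "dp_cohort_eval")
}

#' @export
print.dp_cohort_eval <- function(x, ...) {
  cat(sprintf("<dp_cohort_eval> %d cases\n", x$n))
  for (finding in c("mpdd", "ppa")) {
    f <- x[[finding]]
    cat(sprintf("-- %s: ", toupper(finding)))
    if (isTRUE(f$skipped)) {
      cat("skipped (", f$reason, ")\n", sep = "")
      next
    }
    cat(sprintf("mean %.4f (n=%d with) vs %.4f (n=%d without), p=%.3g, AUROC=%.3f\n",
                f$mean_positive, f$n_positive, f$mean_negative, f$n_negative,
                f$welch$p, f$auroc))
    sp <- f$operating_points
    cat(sprintf("   sens>=%.0f%%: thr %.4f (se %.2f, sp %.2f)%s;  spec>=%.0f%%: thr %.4f (se %.2f, sp %.2f)%s\n",
                100 * x$min_rate, sp$sensitivity_first$threshold,
                sp$sensitivity_first$sensitivity, sp$sensitivity_first$specificity,
                if (sp$sensitivity_first$attained) "" else " [not attained]",
                100 * x$min_rate, sp$specificity_first$threshold,
                sp$specificity_first$sensitivity, sp$specificity_first$specificity,
                if (sp$specificity_first$attained) "" else " [not attained]"))
  }
  if (!is.null(x$three_group)) {
    cat(sprintf("-- three-group Welch comparisons (corrected alpha %.4f):\n",
                attr(x$three_group, "corrected_alpha")))
    print(x$three_group, row.names = FALSE)
  }
  invisible(x)
}
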