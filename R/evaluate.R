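#' Mann-Whitney U test
#'
#' Rank-sum test with midrank tie handling. The two-sided p-value comes
#' from the exact permutation distribution of U (computed by dynamic
#' programming over the rank multiset) when `n_a * n_b <= exact_limit`, and
#' otherwise from the normal approximation with tie correction and
#' continuity correction.
#'
#' @param group_a,group_b numeric samples.
#' @param exact_limit product of sample sizes up to which the exact
#'   distribution is enumerated.
#' @return list with `U` (pairs where `group_a` exceeds `group_b`, ties
#'   counting one half), `p`, sample sizes and the method used.
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 400) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na * nb <= exact_limit) {
    r2 <- round(2 * r)  # midranks doubled are integers
    S <- sum(r2)
    # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
    dp <- matrix(0, na + 1, S + 1)
    dp[1, 1] <- 1
    for (item in r2) {
      dp[2:(na + 1), (item + 1):(S + 1)] <-
        dp[2:(na + 1), (item + 1):(S + 1)] + dp[1:na, 1:(S + 1 - item)]
    }
    counts <- dp[na + 1, ]
    u2 <- 0:S - na * (na + 1)          # doubled U for each doubled rank sum
    dev <- abs(u2 - na * nb)           # distance from the null mean (x2)
    obs <- abs(2 * U - na * nb)
    p <- sum(counts[dev >= obs - 1e-9]) / choose(n, na)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(U = U, p = p, n_a = na, n_b = nb, method = method)
}

#' ROC curve and AUC
#'
#' Rank-based AUC with ties contributing one half, together with the full
#' sensitivity/specificity curve and the per-subject placement values used
#' by the DeLong machinery. The AUC equals the Mann-Whitney U statistic
#' divided by `n_pos * n_neg`.
#'
#' @param scores numeric classifier or index values.
#' @param labels class labels.
#' @param positive label of the positive (disease) class.
#' @param direction `"higher"` if larger scores indicate the positive
#'   class, `"lower"` otherwise.
#' @return object of class `roc_result`.
#' @export
roc_auc <- function(scores, labels, positive = "PS",
                    direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present",
                                  call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  s <- if (direction == "lower") -scores else scores
  np <- sum(pos); nn <- sum(!pos)
  r_all <- rank(s)
  v10 <- (r_all[pos] - rank(s[pos])) / nn        # placement of positives
  v01 <- 1 - (r_all[!pos] - rank(s[!pos])) / np  # placement of negatives
  auc <- mean(v10)
  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] < t), numeric(1))
  structure(list(auc = auc, thresholds = thr, sensitivity = sens,
                 specificity = spec, v10 = v10, v01 = v01,
                 n_pos = np, n_neg = nn, oriented_scores = s,
                 is_pos = pos, direction = direction, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (%d pos / %d neg, direction=%s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' DeLong variance of a single AUC
#'
#' @param roc a [roc_auc()] result.
#' @return variance estimate of the AUC.
#' @export
auc_variance <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  stats::var(roc$v10) / roc$n_pos + stats::var(roc$v01) / roc$n_neg
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two ROC curves computed on the same subjects,
#' using the covariance of their placement-value structural components.
#' Comparing a curve with itself yields z = 0, p = 1.
#'
#' @param roc_a,roc_b paired [roc_auc()] results (same subjects, same
#'   order).
#' @return list with both AUCs, the variance of their difference, the z
#'   statistic and the two-sided p-value.
#' @export
delong_compare <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (!identical(roc_a$is_pos, roc_b$is_pos)) {
    stop("ROC curves are not paired (different subjects or order)",
         call. = FALSE)
  }
  s10 <- stats::cov(cbind(roc_a$v10, roc_b$v10))
  s01 <- stats::cov(cbind(roc_a$v01, roc_b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / roc_a$n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / roc_a$n_neg
  d <- roc_a$auc - roc_b$auc
  if (var_diff < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = roc_a$auc, auc_b = roc_b$auc, var_diff = var_diff,
       z = z, p = p)
}

#' Optimal ROC cutoff by Youden's J
#'
#' Selects the threshold maximizing J = sensitivity + specificity - 1
#' (ties resolved toward higher sensitivity) and reports it as the midpoint
#' between adjacent observed scores, on the original score scale.
#'
#' @param roc a [roc_auc()] result.
#' @return list with `cutoff` (on the input score scale; predict positive
#'   when the score is `>=` the cutoff for direction `"higher"`, `<=` for
#'   `"lower"`), the achieved sensitivity/specificity/J, and the confusion
#'   counts `tp`, `fp`, `fn`, `tn` at the cutoff.
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  s <- roc$oriented_scores
  u <- sort(unique(s))
  if (length(u) < 2L) stop("degenerate ROC: all scores tied", call. = FALSE)
  # candidate thresholds: midpoints between adjacent unique scores, plus
  # one below all scores (predict everyone positive)
  cand <- c(u[1] - 1, (u[-length(u)] + u[-1]) / 2)
  sens <- vapply(cand, function(t) mean(s[roc$is_pos] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(s[!roc$is_pos] < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]
  thr <- cand[best]
  tp <- sum(s[roc$is_pos] >= thr); fn <- roc$n_pos - tp
  fp <- sum(s[!roc$is_pos] >= thr); tn <- roc$n_neg - fp
  cutoff <- if (roc$direction == "lower") -thr else thr
  list(cutoff = cutoff, direction = roc$direction,
       sensitivity = sens[best], specificity = spec[best],
       youden_j = j[best], tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Confusion-matrix summary metrics
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as percentages rounded
#' half-up to one decimal. Ratios with a zero denominator are reported as
#' `NA` (undefined), never 0.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return object of class `confusion_metrics`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(cells)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
    ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
    accuracy = pct(tp + tn, n)
  ), class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("sens %.1f  spec %.1f  ppv %.1f  npv %.1f  acc %.1f ",
                     "(tp %d fp %d fn %d tn %d)\n"),
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy,
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

# conventional positivity directions: low uptake/shape ratios and high
# asymmetry/dot-ness/classifier scores indicate disease
default_index_directions <- function() {
  c(sbr_q = "lower", pcr_q = "lower", sbr_v = "lower",
    fd_v = "higher", ai_q = "higher", ai_v = "higher")
}

#' Evaluation report over a labeled cohort
#'
#' Produces the summary the analysis is built around: one row per single
#' index (full-cohort ROC with a resubstitution Youden cutoff) and one row
#' per SVM stage (held-out test-split ROC and cutoff), plus the paired
#' DeLong AUC comparisons between corresponding indices of the two VOI
#' schemes and between the two SVM stages. No multiple-testing correction
#' is applied.
#'
#' @param panels labeled panel data frame (columns `label` and the six
#'   indices).
#' @param svm_results optional named list of [svm_stage()] results (e.g.
#'   `list(svm_q = ..., svm_v = ...)`); stages compared by DeLong must
#'   share the same split.
#' @param directions named vector of per-index positivity directions.
#' @param positive positive class label.
#' @return object of class `dat_report`: `table` (per-index metrics),
#'   `comparisons` (DeLong tests), and `rocs` (the underlying curves).
#' @export
build_report <- function(panels, svm_results = NULL,
                         directions = default_index_directions(),
                         positive = "PS") {
  if (!"label" %in% names(panels) || anyNA(panels$label)) {
    stop("panels must carry complete class labels", call. = FALSE)
  }
  rocs <- list()
  rows <- list()
  for (idx in names(directions)) {
    roc <- roc_auc(panels[[idx]], panels$label, positive, directions[[idx]])
    cut <- optimal_cutoff(roc)
    met <- confusion_metrics(cut$tp, cut$fp, cut$fn, cut$tn)
    rocs[[idx]] <- roc
    rows[[idx]] <- data.frame(
      index = idx, evaluation = "resubstitution", n = nrow(panels),
      auc = roc$auc, cutoff = cut$cutoff,
      tp = met$tp, fp = met$fp, fn = met$fn, tn = met$tn,
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv, accuracy = met$accuracy,
      stringsAsFactors = FALSE)
  }
  for (nm in names(svm_results)) {
    res <- svm_results[[nm]]
    roc <- roc_auc(res$test$score, res$test$label, positive, "higher")
    cut <- optimal_cutoff(roc)
    met <- confusion_metrics(cut$tp, cut$fp, cut$fn, cut$tn)
    rocs[[nm]] <- roc
    rows[[nm]] <- data.frame(
      index = nm, evaluation = "test_split", n = nrow(res$test),
      auc = roc$auc, cutoff = cut$cutoff,
      tp = met$tp, fp = met$fp, fn = met$fn, tn = met$tn,
      sensitivity = met$sensitivity, specificity = met$specificity,
      ppv = met$ppv, npv = met$npv, accuracy = met$accuracy,
      stringsAsFactors = FALSE)
  }
  pairs <- list(c("sbr_q", "sbr_v"), c("pcr_q", "fd_v"), c("ai_q", "ai_v"))
  if (all(c("svm_q", "svm_v") %in% names(rocs))) {
    pairs <- c(pairs, list(c("svm_q", "svm_v")))
  }
  cmp <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(rocs))) return(NULL)
    dl <- delong_compare(rocs[[pr[1]]], rocs[[pr[2]]])
    data.frame(index_a = pr[1], index_b = pr[2], auc_a = dl$auc_a,
               auc_b = dl$auc_b, z = dl$z, p = dl$p,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, unname(rows)),
                 comparisons = do.call(rbind, cmp),
                 rocs = rocs,
                 note = "single-index cutoffs are resubstitution cutoffs; no multiple-testing correction applied"),
            class = "dat_report")
}

#' @export
print.dat_report <- function(x, ...) {
  tab <- x$table
  tab$auc <- round(tab$auc, 3)
  tab$cutoff <- signif(tab$cutoff, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("\nPaired AUC comparisons (DeLong):\n")
    cc <- x$comparisons
    cc$p <- signif(cc$p, 3)
    print(cc, row.names = FALSE)
  }
  invisible(x)
}
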