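# DeLong structural components (midrank formulation).  Rows of `scores`
# are classifiers; returns per-classifier AUCs plus the V10 (case) and V01
# (control) component matrices from which all variances derive.
delong_components <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  is_case <- labels == "case"
  m <- sum(is_case); n <- sum(!is_case)
  assert_that(m >= 1 && n >= 1, "both classes must be present")
  k <- nrow(scores)
  auc <- numeric(k)
  v10 <- matrix(0, k, m); v01 <- matrix(0, k, n)
  for (i in seq_len(k)) {
    x <- scores[i, is_case]; y <- scores[i, !is_case]
    tz <- rank(c(x, y), ties.method = "average")
    tx <- rank(x, ties.method = "average")
    ty <- rank(y, ties.method = "average")
    v10[i, ] <- (tz[seq_len(m)] - tx) / n
    v01[i, ] <- 1 - (tz[m + seq_len(n)] - ty) / m
    auc[i] <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  }
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' Area under the ROC curve
#'
#' AUC by the rank (Mann-Whitney) identity with midrank tie handling, for
#' the convention that cases are expected to score higher; equals the
#' probability a random case outscores a random control, counting ties as
#' one half.  Also returns the full ROC curve.
#'
#' @param scores numeric score per sample.
#' @param labels factor/character with levels case/control.
#' @return list of class `pdmr_roc`: `auc`, `n_case`, `n_control`, `curve`
#'   (data.frame `fpr`, `tpr`, `threshold`, from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  dc <- delong_components(scores, labels)
  structure(list(auc = dc$auc, n_case = dc$m, n_control = dc$n,
                 curve = roc_curve_points(scores, labels),
                 scores = scores, labels = labels),
            class = "pdmr_roc")
}

roc_curve_points <- function(scores, labels) {
  is_case <- labels == "case"
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[is_case] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_case] >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr))
}

#' AUC with DeLong variance and confidence interval
#'
#' Nonparametric (structural-component) variance of the AUC with a
#' normal-approximation CI clipped to `[0, 1]`.  A degenerate zero
#' variance with AUC 0 or 1 collapses the CI to the point estimate and is
#' flagged.
#'
#' @param scores,labels as in [roc_auc].
#' @param level confidence level (default 0.95).
#' @return `pdmr_roc` list with `auc`, `variance`, `ci` (low, high),
#'   `degenerate` flag, `n_case`, `n_control`, `curve`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  dc <- delong_components(scores, labels)
  assert_that(dc$m >= 2 && dc$n >= 2, "DeLong CI needs >= 2 per class")
  v <- stats::var(dc$v10[1, ]) / dc$m + stats::var(dc$v01[1, ]) / dc$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- dc$auc + c(-1, 1) * z * sqrt(v)
  out <- roc_auc(scores, labels)
  out$variance <- v
  out$ci <- pmin(pmax(ci, 0), 1)
  out$degenerate <- v == 0
  out
}

#' DeLong test for two correlated ROC curves
#'
#' Paired z-test on the AUC difference of two score vectors over the same
#' samples, using the joint DeLong covariance of the structural
#' components.  Two-sided p; identical score vectors give a difference of
#' zero with p = 1.
#'
#' @param scores_a,scores_b score vectors over the same samples.
#' @param labels shared labels.
#' @param level confidence level for the difference CI.
#' @return list: `auc_a`, `auc_b`, `delta_auc`, `se`, `ci`, `z`, `pval`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels, level = 0.95) {
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "paired DeLong test needs aligned samples")
  dc <- delong_components(rbind(scores_a, scores_b), labels)
  s10 <- stats::cov(t(dc$v10)); s01 <- stats::cov(t(dc$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / dc$m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / dc$n
  delta <- dc$auc[1] - dc$auc[2]
  if (vd <= 0) {
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else z <- delta / sqrt(vd)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(auc_a = dc$auc[1], auc_b = dc$auc[2], delta_auc = delta,
       se = sqrt(max(vd, 0)),
       ci = delta + c(-1, 1) * zq * sqrt(max(vd, 0)),
       z = z, pval = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
}

#' Univariable single-gene ROC evaluation
#'
#' For each gene, a one-predictor logistic regression produces per-sample
#' scores (fitted case probabilities); AUC and DeLong CI are reported for
#' the case-positive direction of the fitted score, never silently
#' reoriented.  Constant genes are flagged with AUC 0.5.
#'
#' @param x samples x genes matrix.
#' @param labels case/control factor aligned with rows of `x`.
#' @param genes genes to evaluate (default: all columns).
#' @param level CI level.
#' @return list with `table` (data.frame `gene`, `auc`, `variance`,
#'   `ci_low`, `ci_high`, `flag`) and `scores` (genes x samples matrix of
#'   fitted probabilities, for paired comparisons).
#' @export
univariable_panel <- function(x, labels, genes = colnames(x), level = 0.95) {
  assert_that(all(genes %in% colnames(x)),
              "genes absent from the matrix: %s",
              paste(setdiff(genes, colnames(x)), collapse = ", "))
  y <- as.integer(labels == "case")
  scores <- matrix(NA_real_, length(genes), nrow(x),
                   dimnames = list(genes, rownames(x)))
  rows <- lapply(genes, function(g) {
    v <- x[, g]
    if (stats::sd(v) == 0) {
      scores[g, ] <<- 0.5
      return(data.frame(gene = g, auc = 0.5, variance = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    }
    fit <- stats::glm(y ~ v, family = stats::binomial())
    s <- stats::fitted(fit)
    scores[g, ] <<- s
    r <- delong_ci(s, labels, level = level)
    data.frame(gene = g, auc = r$auc, variance = r$variance,
               ci_low = r$ci[1], ci_high = r$ci[2],
               flag = if (isTRUE(r$degenerate)) "degenerate" else "",
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), scores = scores)
}

# Stratified fold assignment: shuffles within each class, deals fold ids
# round-robin so class proportions are preserved as evenly as possible.
stratified_folds <- function(labels, k, seed) {
  assert_that(min(table(labels)) >= k,
              "class counts must be >= k for stratified %d-fold CV", k)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Nested cross-validated LASSO logistic panel
#'
#' Two-stage stratified cross-validation: outer folds provide held-out test
#' parts; within each outer-training part an inner stratified CV over a
#' log-spaced lambda grid minimises binomial deviance, and the
#' regularisation strength is chosen by the one-standard-error rule (the
#' largest lambda whose inner-CV loss is within one SE of the minimum).
#' The tuned model, refit on the outer-training part, predicts the
#' held-out part; out-of-fold probabilities from all rounds are pooled
#' into a single ROC curve and AUC with a DeLong CI, so performance is
#' estimated entirely on samples not used for training.  Features are
#' standardised inside each training part only (no leakage).
#'
#' @param x samples x genes matrix.
#' @param labels case/control factor aligned with rows of `x`.
#' @param k_outer,k_inner fold counts (default 5/5).
#' @param seed integer seed controlling fold assignment (required).
#' @param lambda_grid optional decreasing lambda sequence; by default a
#'   100-point log-spaced grid from the outer-training lambda-max down four
#'   decades.
#' @param nlambda,lambda_min_ratio grid construction parameters.
#' @param inner_loss `"deviance"` (default, the loss the one-SE rule
#'   originates from) or `"auc"`.
#' @return `PanelResult` list: `probs` (pooled out-of-fold probability per
#'   sample), `labels`, `auc`, `variance`, `ci`, `fold` (outer assignment),
#'   `lambda` (per outer fold), `selected_genes` (nonzero-coefficient
#'   genes per outer fold).
#' @export
nested_cv_lasso <- function(x, labels, k_outer = 5, k_inner = 5, seed,
                            lambda_grid = NULL, nlambda = 100,
                            lambda_min_ratio = 1e-4,
                            inner_loss = c("deviance", "auc")) {
  assert_that(!missing(seed), "nested_cv_lasso: seed is required")
  inner_loss <- match.arg(inner_loss)
  y <- as.integer(labels == "case")
  fold <- stratified_folds(labels, k_outer, split_seed(seed, "outer"))
  probs <- rep(NA_real_, length(y))
  lambda_sel <- numeric(k_outer)
  sel_genes <- vector("list", k_outer)
  for (ko in seq_len(k_outer)) {
    tr <- fold != ko; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xt <- scale(x[tr, , drop = FALSE], center = mu, scale = sdv)
    xe <- scale(x[te, , drop = FALSE], center = mu, scale = sdv)
    yt <- y[tr]
    if (all(apply(xt, 2, stats::sd) == 0)) {
      # intercept-only: constant features carry no signal
      probs[te] <- mean(yt)
      lambda_sel[ko] <- NA_real_
      sel_genes[[ko]] <- character(0)
      next
    }
    grid <- lambda_grid
    if (is.null(grid)) {
      lmax <- max(abs(crossprod(xt, yt - mean(yt)))) / length(yt)
      grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
    }
    ifold <- stratified_folds(labels[tr], k_inner,
                              split_seed(seed, paste0("inner", ko)))
    loss <- matrix(NA_real_, k_inner, length(grid))
    for (ki in seq_len(k_inner)) {
      itr <- ifold != ki
      fit <- glmnet::glmnet(xt[itr, , drop = FALSE], yt[itr],
                            family = "binomial", lambda = grid,
                            standardize = FALSE)
      p <- stats::predict(fit, xt[!itr, , drop = FALSE], type = "response")
      # pad in case glmnet stops the path early
      for (li in seq_len(length(grid))) {
        pc <- if (li <= ncol(p)) p[, li] else p[, ncol(p)]
        loss[ki, li] <- if (inner_loss == "deviance")
          binomial_deviance(yt[!itr], pc)
        else -delong_components(pc, labels[tr][!itr])$auc
      }
    }
    cvm <- colMeans(loss)
    cvsd <- apply(loss, 2, stats::sd) / sqrt(k_inner)
    i_min <- which.min(cvm)
    one_se <- cvm[i_min] + cvsd[i_min]
    lam <- grid[which(cvm <= one_se)[1]]   # grid is decreasing: simplest model
    lambda_sel[ko] <- lam
    fit <- glmnet::glmnet(xt, yt, family = "binomial", lambda = grid,
                          standardize = FALSE)
    probs[te] <- as.numeric(stats::predict(fit, xe, type = "response",
                                           s = lam, exact = FALSE))
    cf <- as.matrix(stats::coef(fit, s = lam))[-1, 1]
    sel_genes[[ko]] <- colnames(x)[cf != 0]
  }
  assert_that(!anyNA(probs), "internal error: a sample was never predicted")
  r <- delong_ci(probs, labels)
  structure(list(probs = probs, labels = labels, auc = r$auc,
                 variance = r$variance, ci = r$ci, fold = fold,
                 lambda = lambda_sel, selected_genes = sel_genes),
            class = "pdmr_panel_result")
}

#' Compare single-gene classifiers against the pooled LASSO panel
#'
#' DeLong paired tests of each gene's fitted scores against the panel's
#' pooled out-of-fold probabilities, with Benjamini-Hochberg correction
#' across genes.
#'
#' @param per_gene result of [univariable_panel] (needs `$scores`).
#' @param panel result of [nested_cv_lasso].
#' @param labels shared labels (checked against the panel's).
#' @return data.frame `gene`, `auc_gene`, `auc_panel`, `delta_auc`,
#'   `ci_low`, `ci_high`, `pval`, `fdr`.
#' @export
compare_to_panel <- function(per_gene, panel, labels) {
  assert_that(identical(as.character(labels), as.character(panel$labels)),
              "sample sets/labels misaligned between panel and genes")
  genes <- rownames(per_gene$scores)
  rows <- lapply(genes, function(g) {
    t <- delong_paired_test(per_gene$scores[g, ], panel$probs, labels)
    data.frame(gene = g, auc_gene = t$auc_a, auc_panel = t$auc_b,
               delta_auc = t$delta_auc, ci_low = t$ci[1], ci_high = t$ci[2],
               pval = t$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pval)
  out
}
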