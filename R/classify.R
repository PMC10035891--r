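#' Gaussian naive Bayes on a single feature
#'
#' Closed-form single-feature classifier: per-class Gaussian likelihoods
#' with class priors estimated from the training set, posteriors by Bayes
#' rule. The positive class is `"case"`.
#'
#' @param train_x numeric training features.
#' @param train_y training labels ("control"/"case").
#' @param test_x numeric test features.
#' @return matrix of class posteriors (columns `control`, `case`).
#' @export
nb_fit_predict <- function(train_x, train_y, test_x) {
  train_y <- as.character(train_y)
  classes <- c("control", "case")
  stopifnot(all(train_y %in% classes), length(train_x) == length(train_y))
  for (cl in classes) {
    xs <- train_x[train_y == cl]
    if (length(xs) < 2L)
      stop("need at least 2 training samples in class '", cl, "'")
    if (stats::var(xs) == 0)
      stop("zero variance in class '", cl, "': Gaussian likelihood degenerate")
  }
  lik <- sapply(classes, function(cl) {
    xs <- train_x[train_y == cl]
    stats::dnorm(test_x, mean(xs), stats::sd(xs)) *
      mean(train_y == cl)
  })
  lik <- matrix(lik, ncol = 2L, dimnames = list(NULL, classes))
  tot <- rowSums(lik)
  tot[tot == 0] <- 1                    # far-out point: fall back to priors
  lik / tot
}

#' Balance class counts by resampling
#'
#' `"down"` removes random majority-class samples until counts match;
#' `"up"` resamples the minority class with replacement.
#'
#' @param x features; @param y labels; @param mode "down" or "up";
#' @param seed integer seed.
#' @return list with balanced `x`, `y`, and `idx` into the input.
#' @export
balance_classes <- function(x, y, mode = c("down", "up"), seed = 1L) {
  mode <- match.arg(mode)
  y <- as.character(y)
  set.seed(seed)
  tab <- table(y)
  stopifnot(length(tab) == 2L)
  target <- if (mode == "down") min(tab) else max(tab)
  idx <- unlist(lapply(names(tab), function(cl) {
    i <- which(y == cl)
    if (length(i) == target) i
    else if (length(i) > target) sample(i, target)
    else sample(i, target, replace = TRUE)
  }))
  idx <- sort(idx)
  list(x = x[idx], y = y[idx], idx = idx)
}

#' Rank (Mann-Whitney) AUC
#'
#' Probability that a random case scores above a random control, with ties
#' averaged. Invariant to strictly monotone transforms of the scores; label
#' swap maps AUC to 1 - AUC.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param truth labels ("control"/"case"); `"case"` is positive.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, truth) {
  pos <- truth == "case"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  rk <- rank(scores, ties.method = "average")
  (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

perf_from_scores <- function(score_case, truth) {
  # score_case: posterior P(case); truth: "control"/"case"
  pos <- truth == "case"
  pred_case <- score_case >= 0.5
  tp <- sum(pred_case & pos); fn <- sum(!pred_case & pos)
  tn <- sum(!pred_case & !pos); fp <- sum(pred_case & !pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(auc = rank_auc(score_case, truth),
       balanced_accuracy = mean(c(sens, spec)),
       sensitivity = sens, specificity = spec,
       n_correct = tp + tn, n_total = length(truth))
}

#' Binomial significance of a correct-classification count
#'
#' Upper-tail probability P(X >= n_correct) for X ~ Binomial(n_total,
#' chance): the probability of doing at least this well by guessing.
#'
#' @param n_correct number of correct predictions.
#' @param n_total number of predictions.
#' @param chance chance accuracy (default 0.5).
#' @return p-value.
#' @export
binomial_significance <- function(n_correct, n_total, chance = 0.5) {
  stopifnot(n_correct >= 0, n_correct <= n_total)
  stats::pbinom(n_correct - 1, n_total, chance, lower.tail = FALSE)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- sample(which(y == cl))
    fold[i] <- rep(seq_len(k), length.out = length(i))[
      sample.int(length(i))]
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the naive-Bayes classifier
#'
#' Balances the classes (down-sampling by default), then runs `reps`
#' repetitions of stratified k-fold cross-validation. Within each
#' repetition the held-out posteriors are pooled and the performance
#' metrics computed once; the report averages metrics across repetitions.
#' The binomial p is computed from the pooled correct count of the median
#' repetition (rounded mean correct count over repetitions).
#'
#' @param x features; @param y labels ("control"/"case").
#' @param k folds (default 10); @param reps repetitions (default 20).
#' @param balance_mode "down" (default) or "up".
#' @param seed integer seed.
#' @return list of class `perf_report`: `auc`, `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `binomial_p`, `n_per_class`,
#'   `sampling`, `seed`, `per_rep` (data.frame).
#' @export
repeated_kfold <- function(x, y, k = 10L, reps = 20L,
                           balance_mode = c("down", "up"), seed = 1L) {
  balance_mode <- match.arg(balance_mode)
  bal <- balance_classes(x, y, balance_mode, seed = seed)
  xb <- bal$x; yb <- bal$y
  n <- length(xb)
  if (n < k) stop("n after balancing (", n, ") is below k = ", k)
  set.seed(seed + 1L)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    fold <- stratified_folds(yb, k)
    score <- numeric(n)
    for (f in seq_len(k)) {
      te <- fold == f
      post <- nb_fit_predict(xb[!te], yb[!te], xb[te])
      score[te] <- post[, "case"]
    }
    m <- perf_from_scores(score, yb)
    per_rep[[r]] <- data.frame(rep = r, auc = m$auc,
                               balanced_accuracy = m$balanced_accuracy,
                               sensitivity = m$sensitivity,
                               specificity = m$specificity,
                               n_correct = m$n_correct)
  }
  pr <- do.call(rbind, per_rep)
  n_correct <- round(mean(pr$n_correct))
  structure(list(
    auc = mean(pr$auc), balanced_accuracy = mean(pr$balanced_accuracy),
    sensitivity = mean(pr$sensitivity), specificity = mean(pr$specificity),
    binomial_p = binomial_significance(n_correct, n),
    n_per_class = table(yb), sampling = balance_mode, seed = seed,
    per_rep = pr), class = "perf_report")
}

#' Out-of-sample transfer evaluation
#'
#' Fits the classifier on one balanced dataset and evaluates once on an
#' independently balanced held-out dataset (both down-sampled to
#' `n_balance` per class), reporting AUC, balanced accuracy, sensitivity,
#' specificity and the binomial p of the correct count.
#'
#' @param train_x,train_y training features/labels.
#' @param test_x,test_y held-out features/labels.
#' @param n_balance per-class size after down-sampling (default 53).
#' @param seed integer seed.
#' @return `perf_report`.
#' @export
out_of_sample <- function(train_x, train_y, test_x, test_y,
                          n_balance = 53L, seed = 1L) {
  train_y <- as.character(train_y); test_y <- as.character(test_y)
  for (nm in list(list(train_y, "train"), list(test_y, "test"))) {
    tab <- table(nm[[1L]])
    if (any(tab < n_balance))
      stop(nm[[2L]], " set cannot supply ", n_balance,
           " per class (available: ",
           paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  down_to <- function(x, y, n_b, seed) {
    set.seed(seed)
    idx <- unlist(lapply(unique(y), function(cl)
      sample(which(y == cl), n_b)))
    list(x = x[idx], y = y[idx])
  }
  tr <- down_to(train_x, train_y, n_balance, seed)
  te <- down_to(test_x, test_y, n_balance, seed + 1L)
  post <- nb_fit_predict(tr$x, tr$y, te$x)
  m <- perf_from_scores(post[, "case"], te$y)
  structure(list(
    auc = m$auc, balanced_accuracy = m$balanced_accuracy,
    sensitivity = m$sensitivity, specificity = m$specificity,
    binomial_p = binomial_significance(m$n_correct, m$n_total),
    n_per_class = table(te$y), sampling = "down", seed = seed,
    per_rep = NULL), class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf(
    "perf_report: AUC %.3f | bal.acc %.3f | sens %.3f | spec %.3f | p %.3g\n",
    x$auc, x$balanced_accuracy, x$sensitivity, x$specificity, x$binomial_p))
  invisible(x)
}
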