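#' ICC(1,1): one-way random-effects single-rater agreement
#'
#' Intraclass correlation from the one-way ANOVA decomposition,
#' ICC = (BMS - WMS) / (BMS + (k - 1) WMS), with BMS the between-subject and
#' WMS the within-subject mean square over k runs. Measures absolute
#' agreement of a metric across repeated runs.
#'
#' @param ratings subjects x runs numeric matrix, no missing cells.
#' @return list with `icc`, `bms`, `wms`, `band` (Landis-Koch label).
#' @export
icc_1_1 <- function(ratings) {
  x <- as.matrix(ratings)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L, all(is.finite(x)))
  n <- nrow(x); k <- ncol(x)
  row_means <- rowMeans(x)
  grand <- mean(x)
  bms <- k * sum((row_means - grand)^2) / (n - 1)
  wms <- sum((x - row_means)^2) / (n * (k - 1))
  icc <- if (bms + (k - 1) * wms == 0) 1 else
    (bms - wms) / (bms + (k - 1) * wms)
  list(icc = icc, bms = bms, wms = wms, band = icc_band(icc))
}

#' Landis-Koch band label for an ICC value
#' @param icc ICC value.
#' @return character label.
#' @export
icc_band <- function(icc) {
  if (icc < 0.2) "low"
  else if (icc < 0.4) "fair"
  else if (icc < 0.6) "moderate"
  else if (icc < 0.8) "substantial"
  else "almost perfect"
}

midrank <- function(x) rank(x, ties.method = "average")

#' Aligned Rank Transform (ART) mixed factorial ANOVA
#'
#' Non-parametric 2 x R factorial test with `group` between subjects and
#' `run` within subjects. For each effect the response is aligned
#' (everything except that effect's cell-mean estimate is subtracted),
#' mid-ranked, and a split-plot ANOVA on the ranks (subject as the error
#' stratum for the between effect) yields F, df and p for that effect only.
#' The standard ART diagnostic -- after alignment for one effect, all other
#' effects are stripped (their marginal means constant) -- is computed and
#' returned.
#'
#' @param table data.frame with columns `subject`, `group`, `run`, `value`;
#'   every subject observed in every run, each subject in one group.
#' @return list of class `art_anova` with `effects` (data.frame: effect, F,
#'   df1, df2, p), `diagnostic` (max absolute stripped-effect deviation).
#' @export
art_anova <- function(table) {
  need <- c("subject", "group", "run", "value")
  stopifnot(all(need %in% names(table)))
  d <- data.frame(subject = factor(table$subject),
                  group = factor(table$group),
                  run = factor(table$run),
                  value = as.numeric(table$value))
  if (anyNA(d$value)) stop("missing values not supported (no imputation)")
  tab <- table(d$subject, d$run)
  if (any(tab != 1L))
    stop("every subject must be observed exactly once per run (missing cells)")
  if (nlevels(d$group) != 2L) stop("exactly two groups required")
  if (nlevels(d$run) < 2L) stop("at least two runs required")

  cm <- tapply(d$value, list(d$group, d$run), mean)   # cell means
  mu <- mean(cm)
  a_eff <- rowMeans(cm) - mu                           # group effect
  b_eff <- colMeans(cm) - mu                           # run effect
  ab_eff <- sweep(sweep(cm, 1L, rowMeans(cm)), 2L, colMeans(cm)) + mu
  gi <- as.integer(d$group); ri <- as.integer(d$run)
  resid <- d$value - cm[cbind(gi, ri)]

  aligned <- list(
    group = resid + a_eff[gi],
    run = resid + b_eff[ri],
    `group:run` = resid + ab_eff[cbind(gi, ri)]
  )

  # diagnostic: after aligning for one effect, the others are stripped
  diag_dev <- 0
  check_stripped <- function(y, keep) {
    cmy <- tapply(y, list(d$group, d$run), mean)
    muy <- mean(cmy)
    devs <- c(group = max(abs(rowMeans(cmy) - muy)),
              run = max(abs(colMeans(cmy) - muy)),
              `group:run` = max(abs(sweep(sweep(cmy, 1L, rowMeans(cmy)),
                                          2L, colMeans(cmy)) + muy)))
    max(devs[setdiff(names(devs), keep)])
  }
  for (eff in names(aligned))
    diag_dev <- max(diag_dev, check_stripped(aligned[[eff]], eff))

  res <- lapply(names(aligned), function(eff) {
    r <- midrank(aligned[[eff]])
    fit <- stats::aov(r ~ group * run + Error(subject),
                      data = cbind(d, r = r))
    s <- summary(fit)
    if (eff == "group") {
      tb <- s[["Error: subject"]][[1L]]
      row <- tb[trimws(rownames(tb)) == "group", , drop = FALSE]
    } else {
      tb <- s[["Error: Within"]][[1L]]
      row <- tb[trimws(rownames(tb)) == eff, , drop = FALSE]
    }
    err <- tb[trimws(rownames(tb)) == "Residuals", , drop = FALSE]
    data.frame(effect = eff, F = row[1L, "F value"],
               df1 = row[1L, "Df"], df2 = err[1L, "Df"],
               p = row[1L, "Pr(>F)"])
  })
  structure(list(effects = do.call(rbind, res), diagnostic = diag_dev),
            class = "art_anova")
}

#' Friedman repeated-measures test
#'
#' Chi-squared approximation with mid-ranks and tie correction for a
#' subjects x runs matrix of one metric. Fully tied data (every subject flat
#' across runs) yields chi-squared 0 and p = 1 rather than an indeterminate
#' statistic.
#'
#' @param ratings subjects x runs matrix.
#' @return list with `chisq`, `df`, `p`.
#' @export
friedman_runs <- function(ratings) {
  x <- as.matrix(ratings)
  stopifnot(nrow(x) >= 2L, ncol(x) >= 2L, all(is.finite(x)))
  n <- nrow(x); k <- ncol(x)
  rk <- t(apply(x, 1L, midrank))
  Rj <- colSums(rk)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  # tie correction (Conover): divide by 1 - sum(t^3 - t) / (n k (k^2 - 1))
  tie_sum <- sum(apply(rk, 1L, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  chisq <- if (corr > 0) stat / corr else 0
  df <- k - 1
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Wilcoxon test with Z statistic and effect size r
#'
#' Rank-sum (independent) or signed-rank (paired) test. The Z statistic is
#' the tie-corrected normal approximation with continuity correction; the
#' p-value uses exact enumeration (via [stats::wilcox.test()]) when both
#' sample sizes are at most `exact_max` and the data have no ties (no zero
#' differences for the paired case), otherwise the normal approximation.
#' Effect size r = |Z| / sqrt(N) with N the total number of observations
#' (independent) or the number of non-zero pairs (paired).
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @param exact_max largest per-sample n for exact p (default 25).
#' @return list with `z`, `p`, `r`, `n`, `method`.
#' @export
wilcoxon_z <- function(x, y, paired = FALSE, exact_max = 25L) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(list(z = 0, p = 1, r = 0, n = 0L,
                             method = "signed-rank (all ties)"))
    rk <- midrank(abs(d))
    V <- sum(rk[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (sig2 > 0) (V - mu - sign(V - mu) * 0.5) / sqrt(sig2) else 0
    exact_ok <- n <= exact_max && !any(duplicated(abs(d)))
    p <- if (exact_ok)
      stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    else 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    list(z = z, p = p, r = abs(z) / sqrt(n), n = n,
         method = if (exact_ok) "signed-rank exact" else "signed-rank normal")
  } else {
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    rk <- midrank(c(x, y))
    U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- if (sig2 > 0) (U - mu - sign(U - mu) * 0.5) / sqrt(sig2) else 0
    exact_ok <- n1 <= exact_max && n2 <= exact_max &&
      !any(duplicated(c(x, y)))
    p <- if (exact_ok)
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    else 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    list(z = z, p = p, r = abs(z) / sqrt(n), n = n,
         method = if (exact_ok) "rank-sum exact" else "rank-sum normal")
  }
}

welch_t_stat <- function(m1, v1, n1, m2, v2, n2) {
  den <- sqrt(v1 / n1 + v2 / n2)
  ifelse(den > 0, (m1 - m2) / den, ifelse(m1 == m2, 0, Inf))
}

#' Permutation Welch two-sample t-test
#'
#' Observed Welch t statistic with a Monte Carlo permutation p-value over
#' random relabelings, using the add-one estimator
#' p = (1 + #\{|t*| >= |t_obs|\}) / (n_perm + 1), so p is never exactly 0
#' (floor 1/(n_perm + 1)).
#'
#' @param x,y numeric samples (each n >= 2).
#' @param n_perm number of Monte Carlo permutations (default 9999).
#' @param seed integer seed.
#' @return list with `t`, `df`, `p`, `n_perm`.
#' @export
perm_welch_t <- function(x, y, n_perm = 9999L, seed = 1L) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  set.seed(seed)
  pool <- c(x, y); n <- n1 + n2
  m1 <- mean(x); m2 <- mean(y); v1 <- stats::var(x); v2 <- stats::var(y)
  t_obs <- welch_t_stat(m1, v1, n1, m2, v2, n2)
  df <- if (v1 > 0 || v2 > 0)
    (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)) else NA_real_
  tot_s <- sum(pool); tot_q <- sum(pool^2)
  idx <- replicate(n_perm, sample.int(n, n1))
  xs <- matrix(pool[idx], n1, n_perm)
  s1 <- colSums(xs); q1 <- colSums(xs^2)
  mm1 <- s1 / n1; vv1 <- (q1 - n1 * mm1^2) / (n1 - 1)
  mm2 <- (tot_s - s1) / n2; vv2 <- ((tot_q - q1) - n2 * mm2^2) / (n2 - 1)
  vv1 <- pmax(vv1, 0); vv2 <- pmax(vv2, 0)
  t_star <- welch_t_stat(mm1, vv1, n1, mm2, vv2, n2)
  p <- (1 + sum(abs(t_star) >= abs(t_obs) - 1e-12)) / (n_perm + 1)
  list(t = t_obs, df = df, p = p, n_perm = n_perm)
}

#' Parametric-assumption checks
#'
#' Shapiro-Wilk normality p per sample, Brown-Forsythe (median-centered
#' Levene) variance-homogeneity p, and Cohen's d with pooled sd.
#'
#' @param x,y numeric samples (n >= 3 each for Shapiro-Wilk).
#' @return list with `shapiro_p_x`, `shapiro_p_y`, `levene_p`, `cohens_d`.
#' @export
assumption_checks <- function(x, y) {
  stopifnot(length(x) >= 3L, length(y) >= 3L)
  shapiro_p <- function(v) {
    if (length(v) > 5000L) v <- v[round(seq(1L, length(v), length.out = 5000L))]
    stats::shapiro.test(v)$p.value       # test capped at its n <= 5000 limit
  }
  sx <- shapiro_p(x)
  sy <- shapiro_p(y)
  zx <- abs(x - stats::median(x)); zy <- abs(y - stats::median(y))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- stats::anova(stats::lm(c(zx, zy) ~ g))$`Pr(>F)`[1L]
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  d <- if (sp2 > 0) (mean(x) - mean(y)) / sqrt(sp2) else 0
  list(shapiro_p_x = sx, shapiro_p_y = sy, levene_p = lev, cohens_d = d)
}

#' Bonferroni correction
#'
#' @param p vector of p-values.
#' @param m number of comparisons (default `length(p)`).
#' @return corrected p-values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Non-parametric group-by-run testing flowchart
#'
#' Executes the staged decision logic for comparing two groups across
#' repeated runs of one metric: (1) ART mixed ANOVA; if the interaction is
#' significant, (2) per-group Friedman tests, (3) paired Wilcoxon run
#' drivers, (6) per-run independent Wilcoxon group contrasts; otherwise the
#' main-effect paths: run effect via (4) Friedman and (5) paired Wilcoxon,
#' group effect via (7) an independent Wilcoxon on subject means across
#' runs. Group contrasts are retained only when their effect size exceeds
#' the largest run-driver effect size. All p-values within a family are
#' Bonferroni corrected. With a single run the design degrades to the
#' independent group contrast alone.
#'
#' @param table data.frame with `subject`, `group`, `run`, `value`.
#' @param alpha significance level (default 0.05) applied to corrected p.
#' @return list of class `stats_report` with `trace` (executed steps),
#'   `art`, `contrasts` (per-run group contrasts with retention flags), and
#'   `run_drivers`.
#' @export
flowchart <- function(table, alpha = 0.05) {
  d <- data.frame(subject = as.character(table$subject),
                  group = as.character(table$group),
                  run = table$run, value = as.numeric(table$value))
  groups <- sort(unique(d$group))
  stopifnot(length(groups) == 2L)
  runs <- sort(unique(d$run))
  trace <- character(0)
  note <- function(s) trace <<- c(trace, s)

  run_matrix <- function(sub) {
    out <- sapply(runs, function(r) {
      v <- sub$value[sub$run == r]
      names(v) <- sub$subject[sub$run == r]
      v[sort(unique(sub$subject))]
    })
    matrix(out, ncol = length(runs),
           dimnames = list(sort(unique(sub$subject)), runs))
  }

  group_contrast <- function(run_id) {
    x <- d$value[d$group == groups[1L] & d$run == run_id]
    y <- d$value[d$group == groups[2L] & d$run == run_id]
    w <- wilcoxon_z(x, y)
    data.frame(run = run_id, z = w$z, p = w$p, r = w$r)
  }

  run_drivers <- data.frame()
  contrasts <- data.frame()
  art <- NULL

  if (length(runs) == 1L) {
    note("single-run design: skipping ART/Friedman, independent group contrast only")
    contrasts <- group_contrast(runs[1L])
    contrasts$p_corrected <- contrasts$p
    contrasts$significant <- contrasts$p_corrected < alpha
    contrasts$retained <- contrasts$significant
  } else {
    art <- art_anova(d)
    note("step 1: ART 2xR mixed ANOVA")
    p_art <- bonferroni(art$effects$p, 3L)
    names(p_art) <- art$effects$effect
    inter_sig <- p_art[["group:run"]] < alpha
    run_sig <- p_art[["run"]] < alpha
    group_sig <- p_art[["group"]] < alpha

    paired_run_drivers <- function(sub, label) {
      prs <- utils::combn(length(runs), 2L)
      rows <- lapply(seq_len(ncol(prs)), function(j) {
        r1 <- runs[prs[1L, j]]; r2 <- runs[prs[2L, j]]
        m <- run_matrix(sub)
        w <- wilcoxon_z(m[, as.character(r1)], m[, as.character(r2)],
                        paired = TRUE)
        data.frame(group = label, run_a = r1, run_b = r2,
                   z = w$z, p = w$p, r = w$r)
      })
      do.call(rbind, rows)
    }

    if (inter_sig) {
      note("interaction significant: steps 2, 3, 6")
      for (g in groups) {
        fr <- friedman_runs(run_matrix(d[d$group == g, ]))
        note(sprintf("step 2: Friedman (%s) chisq=%.3f p=%.4g",
                     g, fr$chisq, fr$p))
        run_drivers <- rbind(run_drivers,
                             paired_run_drivers(d[d$group == g, ], g))
      }
      note("step 3: paired Wilcoxon run drivers")
      contrasts <- do.call(rbind, lapply(runs, group_contrast))
      contrasts$p_corrected <- bonferroni(contrasts$p, length(runs))
      note("step 6: independent Wilcoxon per run")
    } else {
      note("interaction not significant: main-effect paths")
      if (run_sig) {
        fr <- friedman_runs(run_matrix(d))
        note(sprintf("step 4: Friedman (all subjects) chisq=%.3f p=%.4g",
                     fr$chisq, fr$p))
        run_drivers <- paired_run_drivers(d, "all")
        note("step 5: paired Wilcoxon run drivers")
      }
      if (group_sig) {
        m <- run_matrix(d)
        subj_group <- d$group[match(rownames(m), d$subject)]
        x <- rowMeans(m)[subj_group == groups[1L]]
        y <- rowMeans(m)[subj_group == groups[2L]]
        w <- wilcoxon_z(x, y)
        contrasts <- data.frame(run = "all", z = w$z, p = w$p, r = w$r)
        contrasts$p_corrected <- contrasts$p
        note("step 7: independent Wilcoxon across all runs")
      }
    }
    if (nrow(run_drivers))
      run_drivers$p_corrected <- bonferroni(run_drivers$p,
                                            nrow(run_drivers))
    if (nrow(contrasts)) {
      contrasts$significant <- contrasts$p_corrected < alpha
      max_driver_r <- if (nrow(run_drivers)) max(run_drivers$r) else 0
      # retention rule: keep only group differences exceeding run effects
      contrasts$retained <- contrasts$significant &
        contrasts$r > max_driver_r
    }
  }
  if (nrow(contrasts) == 0L || !any(contrasts$significant))
    note("no significant group contrasts")
  structure(list(trace = trace, art = art, contrasts = contrasts,
                 run_drivers = run_drivers, alpha = alpha,
                 effect_size_note =
                   "effect size r = |Z|/sqrt(N); retention compares r"),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("stats_report trace:\n")
  for (s in x$trace) cat("  -", s, "\n")
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("group contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}
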