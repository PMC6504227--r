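#' Activity suppression ratio
#'
#' Context-fear memory score: activity during the first 0-2 min of the test
#' session divided by the summed 0-2 min activities of training and test,
#' `test / (train + test)`. 0.5 means no memory-driven suppression; lower
#' values mean stronger contextual memory. The ratio is invariant to a common
#' rescaling of the two activities.
#'
#' @param train_activity_cm,test_activity_cm non-negative activity (distance
#'   moved, cm) over matched 0-2 min windows; vectorized.
#' @return ratios in \[0, 1\]; `NA` (with a warning) where both activities are
#'   zero.
#' @export
activity_suppression_ratio <- function(train_activity_cm, test_activity_cm) {
  if (any(train_activity_cm < 0, na.rm = TRUE) ||
      any(test_activity_cm < 0, na.rm = TRUE))
    stop("activities must be >= 0")
  tot <- train_activity_cm + test_activity_cm
  out <- ifelse(tot > 0, test_activity_cm / tot, NA_real_)
  if (anyNA(out[!is.na(tot)]) || any(tot == 0, na.rm = TRUE))
    if (any(tot == 0, na.rm = TRUE))
      warning("both activities zero for some animals; ratio undefined (NA)")
  out
}

stat_row <- function(test, comparison, statistic, df1 = NA, df2 = NA, p = NA,
                     effect_size = NA, note = NA_character_) {
  data.frame(test = test, comparison = comparison, statistic = statistic,
             df1 = df1, df2 = df2, p = p, effect_size = effect_size,
             note = note, stringsAsFactors = FALSE)
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' Reported as a magnitude: `|mean(a) - mean(b)| / s_pooled` with the pooled
#' SD using n-1 weights, matching common behavioral-phenotyping reporting
#' where the sign carries no information.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return the effect size d; `NA` (with a warning) if the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Two-group comparisons
#'
#' Unpaired pooled-variance t test, paired t test, or Wilcoxon rank-sum test
#' (exact p for small samples without ties). The Wilcoxon statistic `W`
#' follows, by default, the Mann-Whitney U convention for the first-listed
#' group (what [stats::wilcox.test()] reports); set
#' `w_convention = "rank_sum"` to report the classical rank sum
#' `U + n1 (n1 + 1) / 2` instead — the field uses both and rarely says which.
#'
#' @param a,b numeric vectors; for the paired test they must have equal
#'   length and a common animal order.
#' @param test one of `"unpaired_t"`, `"paired_t"`, `"wilcoxon"`.
#' @param w_convention `"mann_whitney"` (default) or `"rank_sum"`.
#' @param comparison label recorded in the result.
#' @return a one-row data frame: `test`, `comparison`, `statistic`, `df1`,
#'   `df2`, `p`, `effect_size` (Cohen's d for the t tests), `note`.
#' @export
group_compare <- function(a, b, test = c("unpaired_t", "paired_t", "wilcoxon"),
                          w_convention = c("mann_whitney", "rank_sum"),
                          comparison = "a vs b") {
  test <- match.arg(test)
  w_convention <- match.arg(w_convention)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (test == "unpaired_t") {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    d <- tryCatch(cohens_d(a, b), warning = function(w) NA_real_)
    stat_row("unpaired_t", comparison, unname(ht$statistic),
             df1 = unname(ht$parameter), p = ht$p.value, effect_size = d)
  } else if (test == "paired_t") {
    if (length(a) != length(b))
      stop("paired test requires equal-length groups in common animal order")
    ht <- stats::t.test(a, b, paired = TRUE)
    stat_row("paired_t", comparison, unname(ht$statistic),
             df1 = unname(ht$parameter), p = ht$p.value)
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && length(a) <= 50 && length(b) <= 50
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
    W <- unname(ht$statistic)
    if (w_convention == "rank_sum")
      W <- W + length(a) * (length(a) + 1) / 2
    d <- tryCatch(cohens_d(a, b), warning = function(w) NA_real_)
    stat_row("wilcoxon", comparison, W, p = ht$p.value, effect_size = d,
             note = paste0("W convention: ", w_convention,
                           if (!exact) "; normal approximation (ties or large n)" else "; exact"))
  }
}

# assemble one endpoint's values and crossed factors from a cohort table
endpoint_frame <- function(table, endpoint, factors) {
  sub <- as.data.frame(table)[as.data.frame(table)$endpoint == endpoint, ]
  if (nrow(sub) == 0) stop("endpoint '", endpoint, "' not present in table")
  for (f in factors) sub[[f]] <- factor(sub[[f]])
  sub
}

#' Two-factor ANOVA with type-III sums of squares
#'
#' The standard four-group gene-rescue analysis: main effects of Cre and
#' genotype plus their interaction, computed with type-III sums of squares
#' (sum-to-zero contrasts, each term dropped from the full model including
#' the interaction) so unbalanced cells are handled the way mainstream
#' behavioral-statistics software does. For balanced designs type-III and
#' sequential sums of squares coincide.
#'
#' @param table a [cohort_table()].
#' @param endpoint which endpoint to analyze.
#' @param factors length-2 character vector of factor columns
#'   (default `c("cre", "genotype")`).
#' @return a data frame with one row per term (two main effects and the
#'   interaction): F statistic, numerator/denominator df, p.
#' @export
two_factor_anova <- function(table, endpoint, factors = c("cre", "genotype")) {
  stopifnot(length(factors) == 2)
  sub <- endpoint_frame(table, endpoint, factors)
  A <- sub[[factors[1]]]; B <- sub[[factors[2]]]
  counts <- table(A, B)
  if (any(counts < 2)) {
    bad <- which(counts < 2, arr.ind = TRUE)[1, ]
    stop("cell (", factors[1], "=", levels(A)[bad[1]], ", ", factors[2], "=",
         levels(B)[bad[2]], ") has fewer than 2 observations")
  }
  dat <- data.frame(y = sub$value, A = A, B = B)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  dr <- stats::drop1(fit, ~., test = "F")
  df_res <- fit$df.residual
  term_lab <- c("A" = factors[1], "B" = factors[2],
                "A:B" = paste0(factors[1], ":", factors[2], " interaction"))
  rows <- lapply(c("A", "B", "A:B"), function(tm) {
    stat_row("two_factor_anova_typeIII", term_lab[[tm]],
             statistic = dr[tm, "F value"], df1 = dr[tm, "Df"],
             df2 = df_res, p = dr[tm, "Pr(>F)"])
  })
  out <- do.call(rbind, rows)
  # zero between-cell variance => F is NaN 0/0; report F = 0, p = 1
  zero <- !is.finite(out$statistic) & stats::var(dat$y) >= 0 &
    isTRUE(all.equal(stats::var(dat$y), 0))
  out$statistic[zero] <- 0; out$p[zero] <- 1
  out
}

#' Mixed (between x within) repeated-measures ANOVA
#'
#' Classical univariate mixed-design ANOVA with subjects as the error stratum
#' for the within factor: between main effect tested against
#' subjects-within-groups, within main effect and interaction against the
#' subject x within residual. Animals missing a within level are excluded
#' with a warning (degrees of freedom adjust accordingly).
#'
#' @param table a [cohort_table()] with a `within` column.
#' @param endpoint endpoint to analyze.
#' @param between between-subjects factor column (default `"genotype"`).
#' @param within name of the within-subjects column (default `"within"`).
#' @return a data frame with rows for the between effect, within effect and
#'   interaction: F, df pair, p.
#' @export
mixed_rm_anova <- function(table, endpoint, between = "genotype",
                           within = "within") {
  sub <- as.data.frame(table)
  if (!within %in% names(sub)) stop("table has no '", within, "' column")
  sub <- sub[sub$endpoint == endpoint, ]
  if (nrow(sub) == 0) stop("endpoint '", endpoint, "' not present in table")
  w_levels <- unique(sub[[within]])
  n_w <- stats::aggregate(sub[[within]], list(id = sub$animal_id),
                          function(x) length(unique(x)))
  incomplete <- n_w$id[n_w$x < length(w_levels)]
  if (length(incomplete)) {
    warning("excluding animal(s) missing a within level: ",
            paste(incomplete, collapse = ", "))
    sub <- sub[!sub$animal_id %in% incomplete, ]
  }
  grp_per_animal <- tapply(sub[[between]], sub$animal_id,
                           function(x) length(unique(x)))
  if (any(grp_per_animal > 1)) stop("an animal appears in two between groups")
  if (length(unique(sub$animal_id)) < 4) stop("need >= 2 animals per group")
  dat <- data.frame(y = sub$value, B = factor(sub[[between]]),
                    W = factor(sub[[within]]), id = factor(sub$animal_id))
  fit <- stats::aov(y ~ B * W + Error(id / W), data = dat)
  sm <- summary(fit)
  ss_floor <- 1e-10 * sum((dat$y - mean(dat$y))^2)  # numerical-noise guard
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- which(trimws(rownames(tab)) == term)
    if (!length(i)) return(NULL)
    resid_i <- which(trimws(rownames(tab)) == "Residuals")
    f <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    if (tab[i, "Sum Sq"] <= ss_floor) { f <- 0; p <- 1 }
    stat_row("mixed_rm_anova", term,
             statistic = f, df1 = tab[i, "Df"],
             df2 = tab[resid_i, "Df"], p = p)
  }
  out <- rbind(pull("Error: id", "B"),
               pull("Error: id:W", "W"),
               pull("Error: id:W", "B:W"))
  out$comparison <- c(between, within, paste0(between, ":", within))
  # degenerate: identical within levels for every animal => W and B:W are 0/0
  out$statistic[is.nan(out$statistic)] <- 0
  out$p[out$statistic == 0 & is.na(out$p)] <- 1
  out$p[is.nan(out$p)] <- 1
  out
}

#' MANOVA (Pillai's trace) across correlated endpoints
#'
#' Joint test of factor effects over several endpoints measured on the same
#' animals (e.g. the three flurothyl seizure-stage latencies). Endpoint
#' columns that are linearly redundant (rank-deficient residual covariance,
#' e.g. duplicated endpoints) are dropped via pivoted QR with a warning so the
#' degenerate case reduces to the univariate ANOVA.
#'
#' @param table a [cohort_table()] with all endpoints present for each animal.
#' @param endpoints character vector of endpoint names
#'   (default `c("clonus", "tc", "the")`).
#' @param factors length-2 character vector of crossed factors.
#' @return a data frame with one row per term: Pillai's trace (`statistic`),
#'   approximate F in `note`-free columns `df1`, `df2`, `p`; for the
#'   rank-1 degenerate case the univariate F is reported and noted.
#' @export
manova_pillai <- function(table, endpoints = c("clonus", "tc", "the"),
                          factors = c("cre", "genotype")) {
  wide <- cohort_wide(as.data.frame(table), endpoints)
  if (anyNA(wide$values))
    stop("every animal needs all endpoints: ", paste(endpoints, collapse = ", "))
  A <- factor(wide$meta[[factors[1]]]); B <- factor(wide$meta[[factors[2]]])
  Y <- wide$values
  res <- stats::residuals(stats::lm(Y ~ A * B))
  rk <- qr(res)$rank
  if (rk < ncol(Y)) {
    keep <- qr(res, LAPACK = FALSE)$pivot[seq_len(max(rk, 1L))]
    warning("within-cell covariance is singular; dropping redundant endpoint(s): ",
            paste(setdiff(colnames(Y), colnames(Y)[keep]), collapse = ", "),
            " (consider dropping them from `endpoints`)")
    Y <- Y[, keep, drop = FALSE]
  }
  if (ncol(Y) == 1L) {
    dat <- data.frame(y = Y[, 1], A = A, B = B)
    tab <- summary(stats::aov(y ~ A * B, data = dat))[[1]]
    terms <- c("A", "B", "A:B")
    out <- do.call(rbind, lapply(terms, function(tm) {
      i <- which(trimws(rownames(tab)) == tm)
      resid_i <- which(trimws(rownames(tab)) == "Residuals")
      stat_row("manova_pillai", tm, statistic = tab[i, "F value"],
               df1 = tab[i, "Df"], df2 = tab[resid_i, "Df"],
               p = tab[i, "Pr(>F)"],
               note = "rank-1 degeneracy: univariate ANOVA reported")
    }))
    out$comparison <- c(factors[1], factors[2], paste0(factors[1], ":", factors[2]))
    return(out)
  }
  fit <- stats::manova(Y ~ A * B)
  sm <- summary(fit, test = "Pillai")$stats
  terms <- c("A", "B", "A:B")
  out <- do.call(rbind, lapply(terms, function(tm) {
    i <- which(trimws(rownames(sm)) == tm)
    stat_row("manova_pillai", tm, statistic = sm[i, "Pillai"],
             df1 = sm[i, "num Df"], df2 = sm[i, "den Df"],
             p = sm[i, "Pr(>F)"],
             note = sprintf("approx F = %.4g", sm[i, "approx F"]))
  }))
  out$comparison <- c(factors[1], factors[2], paste0(factors[1], ":", factors[2]))
  out
}

#' Bonferroni-adjusted pairwise t tests across groups
#'
#' All pairwise unpaired t tests between the groups defined by the crossing
#' of `group_by` columns; each raw p is multiplied by the number of
#' comparisons and capped at 1. With two groups this reduces to the plain
#' unpaired t test.
#'
#' @param table a [cohort_table()].
#' @param endpoint endpoint to compare.
#' @param group_by character vector of grouping columns
#'   (default `c("cre", "genotype")`).
#' @return a data frame with one row per pair: t, df, raw `p`, adjusted
#'   `p_adj`, Cohen's d.
#' @export
bonferroni_pairwise <- function(table, endpoint, group_by = c("cre", "genotype")) {
  sub <- endpoint_frame(table, endpoint, group_by)
  grp <- interaction(sub[group_by], sep = ":", drop = TRUE)
  levs <- levels(grp)
  if (length(levs) < 2) stop("need >= 2 groups")
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(k) {
    a <- sub$value[grp == pairs[1, k]]
    b <- sub$value[grp == pairs[2, k]]
    r <- group_compare(a, b, "unpaired_t",
                       comparison = paste(pairs[1, k], "vs", pairs[2, k]))
    r
  }))
  out$p_adj <- pmin(1, out$p * m)
  out$test <- "bonferroni_pairwise_t"
  out
}
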