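#' Composite socioeconomic-status score
#'
#' Averages the two parental education scores into one family education score
#' and likewise for occupation, z-scores each across the sample (divisor
#' n - 1), and sums the two z-scores into the composite `ses_z`.
#'
#' @param records Data frame with columns `parent_edu_1`, `parent_edu_2`
#'   (1-5 scale) and `parent_occ_1`, `parent_occ_2` (1-10 scale).
#' @return `records` with added columns `family_edu`, `family_occ`, `ses_z`.
#' @examples
#' d <- data.frame(parent_edu_1 = c(2, 4), parent_edu_2 = c(2, 4),
#'                 parent_occ_1 = c(3, 5), parent_occ_2 = c(3, 5))
#' ses_score(d)$ses_z   # -1.414, 1.414
#' @export
ses_score <- function(records) {
  need <- c("parent_edu_1", "parent_edu_2", "parent_occ_1", "parent_occ_2")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) < 2) stop("z-scoring needs at least 2 records")
  if (any(records$parent_edu_1 < 1 | records$parent_edu_1 > 5) ||
      any(records$parent_edu_2 < 1 | records$parent_edu_2 > 5))
    stop("parental education must be on the 1-5 scale")
  if (any(records$parent_occ_1 < 1 | records$parent_occ_1 > 10) ||
      any(records$parent_occ_2 < 1 | records$parent_occ_2 > 10))
    stop("parental occupation must be on the 1-10 scale")
  records$family_edu <- (records$parent_edu_1 + records$parent_edu_2) / 2
  records$family_occ <- (records$parent_occ_1 + records$parent_occ_2) / 2
  if (sd(records$family_edu) < 1e-12)
    stop("zero variance in family education; composite undefined")
  if (sd(records$family_occ) < 1e-12)
    stop("zero variance in family occupation; composite undefined")
  z <- function(x) (x - mean(x)) / sd(x)
  records$ses_z <- z(records$family_edu) + z(records$family_occ)
  records
}

#' Extreme-group split of ranked SES scores
#'
#' Assigns the top `ceil(fraction * n)` subjects by `ses_z` to the `high`
#' group, the bottom as many to `low`, and the remainder to `middle`.
#' Boundary ties are broken by `subject_id` order (deterministic) and
#' reported in attribute `"tie_note"`.
#'
#' @param records Data frame with `ses_z` (see [ses_score()]) and
#'   `subject_id`.
#' @param fraction Tail fraction per group; default 0.27.
#' @return `records` with added factor column `group` (`low`/`middle`/`high`).
#' @examples
#' d <- ses_score(simulate_ses_sample(107, seed = 1))
#' table(extreme_group_split(d)$group)  # 29 / 49 / 29
#' @export
extreme_group_split <- function(records, fraction = 0.27) {
  if (!"ses_z" %in% names(records)) stop("run ses_score() first")
  n <- nrow(records)
  m <- ceiling(fraction * n)
  if (2 * m > n) stop("fraction too large: groups would overlap")
  ord <- order(records$ses_z, records$subject_id)
  grp <- rep("middle", n)
  grp[ord[seq_len(m)]] <- "low"
  grp[ord[seq.int(n - m + 1, n)]] <- "high"
  records$group <- factor(grp, levels = c("low", "middle", "high"))
  bnd <- sort(records$ses_z)[c(m, n - m + 1)]
  if (sum(records$ses_z == bnd[1]) > 1 || sum(records$ses_z == bnd[2]) > 1)
    attr(records, "tie_note") <- "boundary ties broken by subject_id order"
  records
}

#' Pearson correlation between SES and a microstate parameter
#'
#' Wraps `stats::cor.test` (two-sided, t distribution on n - 2 df) in the
#' package's tidy test-result row.
#'
#' @param ses Numeric vector of SES composites.
#' @param parameter Numeric vector of the same length.
#' @return One-row data frame: `r`, `df`, `statistic`, `p`.
#' @export
ms_correlate <- function(ses, parameter) {
  ok <- complete.cases(ses, parameter)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (sd(ses[ok]) < 1e-12 || sd(parameter[ok]) < 1e-12)
    stop("zero variance; correlation undefined")
  ct <- cor.test(ses[ok], parameter[ok])
  data.frame(r = unname(ct$estimate), df = unname(ct$parameter),
             statistic = unname(ct$statistic), p = ct$p.value)
}

#' Mixed-design repeated-measures ANCOVA
#'
#' Two-way mixed ANCOVA on one microstate parameter: between-subject factor
#' `group`, within-subject factor `class` (every subject contributes all K
#' classes), and subject-level covariates age and gender (gender coded as a
#' binary indicator).  Computed via the univariate repeated-measures
#' approach (Type III sums of squares, sum-to-zero contrasts), the
#' convention that yields the familiar df pattern -- e.g. for 58 subjects
#' and K = 4: group F(1, 54), class and group x class F(3, 162), because the
#' within-stratum error absorbs class x covariate terms.  No sphericity
#' correction is applied.  Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within each stratum.
#'
#' @param param_table Long data frame with columns `subject`, `group`,
#'   `class`, `value`, `age`, `gender` (covariates constant within subject).
#' @return Data frame with one row per effect (`group`, `class`,
#'   `group:class`): `df1`, `df2`, `F`, `p`, `partial_eta2`.
#' @export
mixed_ancova <- function(param_table) {
  pt <- param_table
  need <- c("subject", "group", "class", "value", "age", "gender")
  miss <- setdiff(need, names(pt))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  pt$subject <- factor(pt$subject)
  pt$group <- droplevels(factor(pt$group))
  pt$class <- factor(pt$class)
  K <- nlevels(pt$class)
  counts <- table(pt$subject, pt$class)
  bad <- rownames(counts)[rowSums(counts == 1) != K]
  if (length(bad))
    stop("subject(s) missing classes: ", paste(head(bad, 3), collapse = ", "))
  # wide subject x class matrix + subject-level covariates
  wide <- reshape_wide(pt)
  Y <- as.matrix(wide[, paste0("c", seq_len(K))])
  gender_num <- as.numeric(factor(wide$gender)) - 1
  dat <- data.frame(group = wide$group, age = wide$age, gender = gender_num)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mod <- lm(Y ~ group + age + gender, data = dat)
  idata <- data.frame(class = factor(paste0("c", seq_len(K))))
  av <- car::Anova(mod, idata = idata, idesign = ~class, type = 3)
  # sphericity-correction epsilons are not used (univariate uncorrected df)
  tab <- suppressWarnings(summary(av, multivariate = FALSE))$univariate.tests
  pick <- function(row) {
    ss <- tab[row, "Sum Sq"]; ess <- tab[row, "Error SS"]
    data.frame(effect = row, df1 = tab[row, "num Df"],
               df2 = tab[row, "den Df"], F = tab[row, "F value"],
               p = tab[row, "Pr(>F)"],
               partial_eta2 = ss / (ss + ess))
  }
  out <- rbind(pick("group"), pick("class"), pick("group:class"))
  rownames(out) <- NULL
  out
}

reshape_wide <- function(pt) {
  K <- nlevels(pt$class)
  subj <- levels(pt$subject)
  first <- pt[!duplicated(pt$subject), c("subject", "group", "age", "gender")]
  first <- first[match(subj, first$subject), ]
  M <- matrix(NA_real_, length(subj), K,
              dimnames = list(subj, paste0("c", seq_len(K))))
  M[cbind(as.integer(pt$subject), as.integer(pt$class))] <- pt$value
  cbind(first, as.data.frame(M))
}

#' Per-class covariate-adjusted group contrasts with Bonferroni correction
#'
#' For each microstate class, fits an ANCOVA of the parameter on group with
#' age and gender as covariates and tests the group contrast; p-values are
#' multiplied by the number of classes (capped at 1).
#'
#' @inheritParams mixed_ancova
#' @return Data frame per class: `class`, `estimate` (group difference,
#'   second level minus first), `t`, `df`, `p`, `p_adj`, `cohens_d`.
#' @export
posthoc_bonferroni <- function(param_table) {
  pt <- param_table
  pt$group <- droplevels(factor(pt$group))
  pt$class <- factor(pt$class)
  K <- nlevels(pt$class)
  gender_num <- as.numeric(factor(pt$gender)) - 1
  out <- lapply(levels(pt$class), function(cl) {
    d <- pt[pt$class == cl, ]
    gn <- gender_num[pt$class == cl]
    fit <- lm(value ~ group + age + gender, data = transform(d, gender = gn))
    sm <- summary(fit)$coefficients
    row <- grep("^group", rownames(sm))[1]
    sdp <- sqrt(sum(tapply(d$value, d$group, function(x)
      (length(x) - 1) * var(x))) / (nrow(d) - 2))
    data.frame(class = cl, estimate = sm[row, 1], t = sm[row, 3],
               df = fit$df.residual, p = sm[row, 4],
               p_adj = pmin(1, sm[row, 4] * K),
               cohens_d = diff(tapply(d$value, d$group, mean)) / sdp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Independent-samples t-tests on transition probabilities
#'
#' Compares every ordered class pair's transition probability between two
#' groups with a two-sided independent-samples t-test (pooled variance by
#' default, Welch optionally).  P-values are unadjusted by default; set
#' `adjust` for Holm or Bonferroni control over the K(K-1) tests.
#'
#' @param transitions Numeric array `subjects x K x K` of per-subject
#'   transition matrices (or a list of K x K matrices).
#' @param groups Factor/character of group membership, length = subjects.
#' @param var_equal Pooled-variance t (default `TRUE`); `FALSE` = Welch.
#' @param adjust `"none"` (default), `"holm"` or `"bonferroni"`.
#' @return Data frame per ordered pair: `from`, `to`, `mean_1`, `mean_2`
#'   (group means in factor-level order), `t`, `df`, `p`, `p_adj`,
#'   `cohens_d`.  Pairs with zero variance in both groups are returned with
#'   `NA` statistics and flagged in `degenerate`.
#' @export
transition_ttests <- function(transitions, groups, var_equal = TRUE,
                              adjust = c("none", "holm", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (is.list(transitions))
    transitions <- simplify2array(transitions)  # K x K x subjects
  if (length(dim(transitions)) != 3) stop("transitions must be a 3-d array")
  if (dim(transitions)[3] == length(groups)) {
    arr <- transitions                        # K x K x subjects
  } else if (dim(transitions)[1] == length(groups)) {
    arr <- aperm(transitions, c(2, 3, 1))
  } else stop("transitions / groups dimension mismatch")
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("need >= 2 subjects per group")
  K <- dim(arr)[1]
  rows <- list()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    x <- arr[i, j, groups == levels(groups)[1]]
    y <- arr[i, j, groups == levels(groups)[2]]
    degen <- sd(x) < 1e-12 && sd(y) < 1e-12
    if (degen) {
      rows[[length(rows) + 1]] <- data.frame(
        from = i, to = j, mean_1 = mean(x), mean_2 = mean(y),
        t = NA_real_, df = NA_real_, p = NA_real_, cohens_d = NA_real_,
        degenerate = TRUE)
      next
    }
    tt <- t.test(x, y, var.equal = var_equal)
    sdp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                  (length(x) + length(y) - 2))
    rows[[length(rows) + 1]] <- data.frame(
      from = i, to = j, mean_1 = mean(x), mean_2 = mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
      cohens_d = (mean(x) - mean(y)) / sdp, degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "none") out$p else p.adjust(out$p, adjust)
  out
}

#' @importFrom stats p.adjust
NULL
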