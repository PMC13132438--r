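# Association layer: per-SD logistic odds ratios, Firth penalised
# logistic regression, random-intercept linear mixed models, patient-
# label permutation tests, BH-FDR, rank tests with effect sizes, and
# Table-1 style group comparison.

#' Benjamini-Hochberg step-up q-values
#'
#' q_(i) = min over j >= i of p_(j) * m / j (sorted scale), clipped at 1
#' and mapped back to the input order.
#'
#' @param p numeric vector of p-values in `[0,1]`.
#' @return q-values, same length/order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    pb_stop("p-values must lie in [0,1]", "pb_input_error")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Per-SD simple logistic odds ratio
#'
#' Fits `outcome ~ feature` by maximum likelihood. Continuous features
#' are standardised by the sample SD (so the OR is per SD increase);
#' binary features are left unscaled. Wald 95% CI = exp(beta +/- 1.96 SE).
#'
#' @param x feature values.
#' @param y binary outcome (0/1 or logical).
#' @param binary treat `x` as binary (no standardisation)? Auto-detected
#'   when `NULL`.
#' @param name feature label carried into the output row.
#' @return one-row data.frame: feature, or, ci_lo, ci_hi, beta, se,
#'   p_raw, scaling, status.
#' @export
logistic_or_per_sd <- function(x, y, binary = NULL, name = "feature") {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    pb_stop("outcome has a single class", "pb_input_error")
  }
  if (is.null(binary)) binary <- length(unique(x)) <= 2
  scaling <- if (binary) "binary" else "per-SD"
  xs <- if (binary) as.numeric(x) else as.numeric(scale(x))
  fit <- suppressWarnings(stats::glm(y ~ xs, family = stats::binomial()))
  beta <- stats::coef(fit)[2]
  se <- sqrt(diag(stats::vcov(fit)))[2]
  status <- "ok"
  if (!fit$converged || abs(beta) > 15 || se > 100) {
    status <- "non_convergence_consider_firth"
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(feature = name, or = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             beta = unname(beta), se = unname(se), p_raw = unname(p),
             scaling = scaling, status = status, row.names = NULL)
}

#' Association table over several features
#'
#' Runs [logistic_or_per_sd()] per feature and adds BH-FDR q-values. The
#' primary bivariate table in this design is reported without
#' multiplicity correction; q is supplied for analyses that use it.
#'
#' @param data data.frame of features.
#' @param outcome binary outcome vector (or column name in `data`).
#' @param features columns to test; default all except the outcome.
#' @return data.frame, one row per feature, with `q` column.
#' @export
association_table <- function(data, outcome, features = NULL) {
  if (is.character(outcome) && length(outcome) == 1L) {
    y <- data[[outcome]]
    features <- features %||% setdiff(names(data), outcome)
  } else {
    y <- outcome
    features <- features %||% names(data)
  }
  rows <- lapply(features, function(f) {
    logistic_or_per_sd(data[[f]], y, name = f)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p_raw)
  out
}

# penalised log-likelihood: l(beta) + 0.5 log det X'WX
firth_penalised_ll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  ll <- sum(y * eta - log1p(exp(eta)))
  W <- pi * (1 - pi)
  info <- crossprod(X * W, X)
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

#' Firth penalised logistic regression
#'
#' Maximises the Jeffreys-penalised likelihood by Newton iteration on
#' the modified score U*(beta) = X'(y - pi + h (1/2 - pi)), where h are
#' the diagonal elements of the weighted hat matrix. Estimates stay
#' finite under separation. Wald CIs by default.
#'
#' @param X design matrix (intercept added when absent).
#' @param y binary outcome.
#' @param max_iter,tol iteration controls (convergence: gradient
#'   max-norm below `tol`).
#' @return object of class `firth_fit`: coefficients, SEs, Wald CI
#'   (exp scale in `or`, `ci_lo`, `ci_hi`), penalised log-likelihood,
#'   `converged`, `iterations`.
#' @export
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (!all(abs(X[, 1] - 1) < 1e-12)) X <- cbind(`(Intercept)` = 1, X)
  y <- as.numeric(y)
  if (qr(X)$rank < ncol(X)) {
    pb_stop("design matrix is rank-deficient", "pb_input_error")
  }
  beta <- rep(0, ncol(X))
  converged <- FALSE
  ll_old <- firth_penalised_ll(beta, X, y)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    W <- pi * (1 - pi)
    info <- crossprod(X * W, X)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * X) * W
    U <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- drop(info_inv %*% U)
    # step-halving on penalised likelihood decrease
    for (k in 0:10) {
      cand <- beta + step / 2^k
      ll_new <- firth_penalised_ll(cand, X, y)
      if (ll_new >= ll_old - 1e-10) { beta <- cand; ll_old <- ll_new; break }
    }
  }
  eta <- drop(X %*% beta)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X * W, X))))
  structure(list(
    coef = stats::setNames(beta, colnames(X)), se = se,
    or = exp(beta), ci_lo = exp(beta - 1.96 * se),
    ci_hi = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    penalised_ll = ll_old, converged = converged, iterations = it
  ), class = "firth_fit")
}

#' Random-intercept linear mixed model over beat-level features
#'
#' For each feature (standardised across beats), fits
#' `feature ~ outcome + (1 | patient)` by REML via \pkg{lme4} and
#' reports the standardised fixed effect for the outcome with a Wald
#' normal p-value; q by BH-FDR across features.
#'
#' @param features data.frame of beat-level features (rows = beats).
#' @param outcome per-beat binary outcome label (constant within
#'   patient).
#' @param patient per-beat patient identifier.
#' @return object of class `mixed_model_result`: `table` (feature,
#'   beta, se, p_raw, q, var_intercept, var_residual), `n_beats`,
#'   `n_patients`.
#' @export
lmm_random_intercept <- function(features, outcome, patient) {
  outcome <- as.numeric(outcome)
  patient <- as.factor(patient)
  per_pat <- tapply(outcome, patient, function(v) length(unique(v)))
  if (any(per_pat > 1)) {
    pb_stop("outcome varies within a patient", "pb_input_error")
  }
  pat_out <- tapply(outcome, patient, unique)
  if (min(table(pat_out)) < 2) {
    pb_stop("need >= 2 patients per outcome group", "pb_degenerate_design")
  }
  rows <- lapply(names(features), function(f) {
    yraw <- features[[f]]
    if (stats::sd(yraw, na.rm = TRUE) < 1e-12) {
      return(data.frame(feature = f, beta = 0, se = NA_real_,
                        p_raw = NA_real_, var_intercept = 0,
                        var_residual = 0))
    }
    yy <- as.numeric(scale(yraw))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(yy ~ outcome + (1 | patient),
                 REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    co <- summary(fit)$coefficients
    vc <- as.data.frame(lme4::VarCorr(fit))
    data.frame(feature = f, beta = co["outcome", "Estimate"],
               se = co["outcome", "Std. Error"],
               p_raw = 2 * stats::pnorm(-abs(co["outcome", "t value"])),
               var_intercept = vc$vcov[vc$grp == "patient"],
               var_residual = vc$vcov[vc$grp == "Residual"])
  })
  tab <- do.call(rbind, rows)
  tab$q <- NA_real_
  ok <- !is.na(tab$p_raw)
  if (any(ok)) tab$q[ok] <- bh_fdr(tab$p_raw[ok])
  structure(list(table = tab, n_beats = nrow(features),
                 n_patients = nlevels(patient)),
            class = "mixed_model_result")
}

#' Pointwise patient-label permutation test on beat templates
#'
#' Tests, at every time sample, the difference in group mean templates
#' (non-survivors minus survivors) by permuting patient labels (never
#' beats). Exhaustive enumeration is used when the number of distinct
#' label assignments is at most `n_perm`; otherwise seeded Monte-Carlo
#' with the add-one estimator p = (1 + #{|D_perm| >= |D_obs|}) /
#' (n_perm + 1). q by BH-FDR across time samples.
#'
#' @param templates matrix, one row per patient (patient-mean beat
#'   template), columns = time samples.
#' @param labels per-patient binary outcome (1 = non-survivor).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return object of class `permutation_result`: `delta_obs`, `p`, `q`,
#'   `n_perm_used`, `exhaustive`, `seed`.
#' @export
pointwise_permutation <- function(templates, labels, n_perm = 1000,
                                  seed = 1L) {
  templates <- as.matrix(templates)
  labels <- as.numeric(labels)
  n <- nrow(templates)
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == n) pb_stop("a group is empty", "pb_input_error")
  tot <- colSums(templates)
  delta_for <- function(idx1) {
    s1 <- colSums(templates[idx1, , drop = FALSE])
    s1 / length(idx1) - (tot - s1) / (n - length(idx1))
  }
  delta_obs <- delta_for(which(labels == 1))
  n_assign <- choose(n, n1)
  if (n_assign <= n_perm) {
    combs <- utils::combn(n, n1)
    deltas <- apply(combs, 2, delta_for)
    deltas <- matrix(deltas, ncol = ncol(combs))
    exceed <- rowSums(abs(deltas) >= abs(delta_obs) - 1e-12)
    p <- exceed / n_assign        # observed assignment is in the enumeration
    used <- n_assign; exhaustive <- TRUE
  } else {
    perms <- with_seed(seed, replicate(n_perm, sample(n, n1)))
    deltas <- apply(perms, 2, delta_for)
    deltas <- matrix(deltas, ncol = n_perm)
    exceed <- rowSums(abs(deltas) >= abs(delta_obs) - 1e-12)
    p <- (1 + exceed) / (n_perm + 1)
    used <- n_perm; exhaustive <- FALSE
  }
  structure(list(delta_obs = delta_obs, p = p, q = bh_fdr(p),
                 n_perm_used = used, exhaustive = exhaustive, seed = seed),
            class = "permutation_result")
}

#' Mann-Whitney comparison with rank-biserial effect size
#'
#' Exact test when `n_A * n_B <= 400` and there are no ties, normal
#' approximation (with tie correction) otherwise. The U statistic counts
#' pairs where A exceeds B; the rank-biserial effect size is
#' r = 1 - 2U/(n_A n_B), so r is positive when group A is stochastically
#' smaller and negative when A is stochastically larger.
#'
#' @param a,b numeric vectors for groups A and B.
#' @return list: `u`, `p`, `r`, `median_a`, `median_b`, `method`.
#' @export
rank_compare <- function(a, b) {
  if (!length(a) || !length(b)) pb_stop("empty group", "pb_input_error")
  exact <- length(a) * length(b) <= 400 &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  u <- unname(wt$statistic)       # = #{a_i > b_j} (+ ties/2)
  r <- 1 - 2 * u / (length(a) * length(b))
  list(u = u, p = wt$p.value, r = r,
       median_a = stats::median(a), median_b = stats::median(b),
       method = if (exact) "exact" else "normal")
}

#' Descriptive group-comparison ("Table 1") builder
#'
#' Continuous variables: Shapiro-Wilk normality screen per group; when
#' both groups look normal (p > 0.05) means (SD) and a t-test are
#' reported, otherwise medians \[Q1, Q3\] and a Mann-Whitney test.
#' Categorical variables: n (%) with Fisher's exact test when any
#' expected cell is below 5, chi-squared otherwise.
#'
#' @param data data.frame.
#' @param group binary grouping column name.
#' @param vars variables to summarise (default: all other columns).
#' @return data.frame: variable, type, summary per group, test, p.
#' @export
table_one <- function(data, group, vars = NULL) {
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) pb_stop("group column must be binary", "pb_input_error")
  vars <- vars %||% setdiff(names(data), group)
  lv <- levels(g)
  fmt_med <- function(x) sprintf("%.1f [%.1f, %.1f]",
                                 stats::median(x, na.rm = TRUE),
                                 stats::quantile(x, 0.25, na.rm = TRUE),
                                 stats::quantile(x, 0.75, na.rm = TRUE))
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 5) {
      x1 <- x[g == lv[1]]; x2 <- x[g == lv[2]]
      normal <- tryCatch(
        stats::shapiro.test(x1)$p.value > 0.05 &&
          stats::shapiro.test(x2)$p.value > 0.05,
        error = function(e) FALSE)
      if (isTRUE(normal)) {
        p <- stats::t.test(x1, x2)$p.value
        s1 <- sprintf("%.1f (%.1f)", mean(x1, na.rm = TRUE),
                      stats::sd(x1, na.rm = TRUE))
        s2 <- sprintf("%.1f (%.1f)", mean(x2, na.rm = TRUE),
                      stats::sd(x2, na.rm = TRUE))
        test <- "t-test"
      } else {
        if (stats::sd(x, na.rm = TRUE) < 1e-12) {
          p <- 1
        } else {
          p <- rank_compare(x1, x2)$p
        }
        s1 <- fmt_med(x1); s2 <- fmt_med(x2)
        test <- "Mann-Whitney"
      }
      data.frame(variable = v, type = "continuous",
                 group1 = s1, group2 = s2, test = test, p = p)
    } else {
      tab <- table(factor(x), g)
      if (stats::sd(as.numeric(factor(x)), na.rm = TRUE) < 1e-12 ||
          nrow(tab) < 2) {
        lev1 <- rownames(tab)[1]
        s <- sprintf("%d (%.1f)", tab[1, ], 100 * tab[1, ] / colSums(tab))
        return(data.frame(variable = v, type = "categorical",
                          group1 = s[1], group2 = s[2],
                          test = "none", p = 1))
      }
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "Fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chi-squared"
      }
      pos <- if (nrow(tab) == 2) 2 else 1   # report last level for binaries
      s <- sprintf("%d (%.1f)", tab[pos, ], 100 * tab[pos, ] / colSums(tab))
      data.frame(variable = v, type = "categorical",
                 group1 = s[1], group2 = s[2], test = test, p = p)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0("group_", lv)
  out
}
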