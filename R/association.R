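# Association analysis: plaque calling, prevalence tables, chi-square,
# one-way ANOVA with Duncan's multiple range test, and cluster-robust
# logistic marginal models (GEE).

#' Call plaque from intima-media thickness
#'
#' Plaque is present where the intima-media complex exceeds the threshold
#' (strictly greater than 0.3 mm by default).
#'
#' @param thickness Thickness values in mm (> 0).
#' @param threshold Plaque-defining thickness in mm.
#' @param strict Use strict inequality (default TRUE; "exceeds" the
#'   threshold).
#' @return Logical vector.
#' @export
call_plaque <- function(thickness, threshold = 0.3, strict = TRUE) {
  if (any(thickness <= 0, na.rm = TRUE))
    abort("Thickness must be positive (mm).")
  if (strict) thickness > threshold else thickness >= threshold
}

#' Plaque prevalence by ESS quartile
#'
#' Tabulates plaque/no-plaque counts per quartile with the derived
#' percentages: per-quartile prevalence, the overall prevalence, and each
#' quartile's share of all plaques.
#'
#' @param data A data frame with logical `plaque` and integer `quartile`
#'   columns, e.g. from [simulate_pullback()]. Alternatively `NULL` when
#'   `plaque`/`quartile` vectors are given directly.
#' @param plaque,quartile Vectors used when `data` is `NULL`.
#' @return A tibble of class `prevalence_table`, one row per quartile:
#'   `n_plaque`, `n_no_plaque`, `n`, `pct_plaque`, `pct_no_plaque`,
#'   `pct_of_all_plaques`; the overall prevalence (%) is in
#'   `attr(, "overall_pct")`.
#' @export
prevalence_table <- function(data = NULL, plaque = NULL, quartile = NULL) {
  if (!is.null(data)) {
    data <- as_tibble(data)
    if (!all(c("plaque", "quartile") %in% names(data)))
      abort("`data` needs columns `plaque` and `quartile`.")
    plaque <- data$plaque; quartile <- data$quartile
  }
  if (length(plaque) != length(quartile))
    abort("`plaque` and `quartile` lengths differ.")
  if (!all(quartile %in% 1:4)) abort("Quartile labels must be in 1..4.")
  q <- factor(quartile, levels = 1:4)
  out <- tibble(
    quartile = 1:4,
    n_plaque = as.integer(tapply(plaque, q, sum, default = 0L)),
    n_no_plaque = as.integer(tapply(!plaque, q, sum, default = 0L)))
  out$n <- out$n_plaque + out$n_no_plaque
  out$pct_plaque <- 100 * out$n_plaque / out$n
  out$pct_no_plaque <- 100 * out$n_no_plaque / out$n
  out$pct_of_all_plaques <- 100 * out$n_plaque / sum(out$n_plaque)
  attr(out, "overall_pct") <- 100 * sum(out$n_plaque) / sum(out$n)
  class(out) <- c("prevalence_table", class(out))
  out
}

#' @rdname prevalence_table
#' @param n_plaque,n_no_plaque Integer length-4 count vectors (quartiles 1-4)
#'   for rebuilding a table from published counts.
#' @export
prevalence_from_counts <- function(n_plaque, n_no_plaque) {
  stopifnot(length(n_plaque) == 4, length(n_no_plaque) == 4)
  if (any(n_plaque < 0 | n_no_plaque < 0)) abort("Counts must be non-negative.")
  prevalence_table(plaque = rep(rep(c(TRUE, FALSE), 4),
                                times = as.vector(rbind(n_plaque, n_no_plaque))),
                   quartile = rep(1:4, times = n_plaque + n_no_plaque))
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Plaque prevalence by ESS quartile\n")
  for (i in 1:4)
    cat(sprintf("  Q%d: plaque %4d (%.1f%%)   no plaque %4d (%.1f%%)\n",
                x$quartile[i], x$n_plaque[i], x$pct_plaque[i],
                x$n_no_plaque[i], x$pct_no_plaque[i]))
  cat(sprintf("  overall: %d of %d (%.1f%%)\n", sum(x$n_plaque), sum(x$n),
              attr(x, "overall_pct")))
  invisible(x)
}

#' Pearson chi-square test on a prevalence table
#'
#' The 4 x 2 plaque/no-plaque table gives a 3-df Pearson chi-square test of
#' homogeneous prevalence across quartiles (no continuity correction).
#'
#' @param tab A [prevalence_table()] (or a matrix of counts, rows = groups).
#' @return A tibble: `statistic`, `df`, `p.value`, `method`.
#' @export
chi_square <- function(tab) {
  m <- if (inherits(tab, "prevalence_table")) {
    cbind(plaque = tab$n_plaque, no_plaque = tab$n_no_plaque)
  } else as.matrix(tab)
  keep <- rowSums(m) > 0
  m <- m[keep, , drop = FALSE]
  if (any(colSums(m) == 0) || nrow(m) < 2)
    abort("Chi-square test needs non-zero marginals and at least 2 groups.")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ct$expected <= 0)) abort("All expected counts must be positive.")
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = unname(ct$p.value), method = "Pearson chi-square")
}

# Duncan's multiple range test on ordered group means.
# Critical range for means p ranks apart: R_p = q_{1-alpha_p}(p, df) * SE,
# with Duncan's protection level alpha_p = 1 - (1 - alpha)^(p - 1), q the
# studentized-range quantile, SE = sqrt(MSE / n_h), n_h the harmonic mean
# group size. Stepwise: a range whose span does not exceed R_p, or that is
# contained in a non-significant range, is declared homogeneous.
duncan_groups <- function(means, n, mse, df, alpha = 0.05) {
  k <- length(means)
  ord <- order(means)
  m <- means[ord]
  n_h <- k / sum(1 / n)
  se <- sqrt(mse / n_h)
  Rp <- vapply(2:max(k, 2), function(p)
    qtukey(1 - (1 - alpha)^(p - 1), p, df, lower.tail = FALSE) * se,
    numeric(1))
  Rp <- c(NA_real_, Rp)  # index by p

  # ns[i, j]: ranks i..j homogeneous (tested widest-first; containment
  # propagates non-significance inward)
  ns <- matrix(FALSE, k, k)
  diag(ns) <- TRUE
  for (span in rev(seq_len(k - 1))) {
    for (i in seq_len(k - span)) {
      j <- i + span
      contained <- FALSE
      if (span < k - 1) {
        if (i > 1 && ns[i - 1, j]) contained <- TRUE
        if (j < k && ns[i, j + 1]) contained <- TRUE
      }
      ns[i, j] <- contained || (m[j] - m[i] <= Rp[span + 1])
    }
  }
  # letters from maximal homogeneous intervals
  maximal <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (!ns[i, j]) next
    if ((i == 1 || !ns[i - 1, j]) && (j == k || !ns[i, j + 1]))
      maximal[[length(maximal) + 1L]] <- c(i, j)
  }
  letters_vec <- rep("", k)
  for (g in seq_along(maximal)) {
    rng <- maximal[[g]]
    letters_vec[rng[1]:rng[2]] <- paste0(letters_vec[rng[1]:rng[2]],
                                         letters[g])
  }
  out <- letters_vec[order(ord)]  # back to input group order
  list(letters = out, ranges = Rp, harmonic_n = n_h)
}

#' One-way ANOVA with Duncan's multiple range test
#'
#' Fits a one-way ANOVA of `value ~ group` and follows it with Duncan's
#' multiple range test: ordered group means are compared with
#' studentized-range critical values at Duncan's protection levels
#' \eqn{\alpha_p = 1 - (1-\alpha)^{p-1}}, and homogeneous subsets are
#' reported as a letter display. Unequal group sizes use the harmonic mean
#' size.
#'
#' @param data A data frame, or `NULL` when vectors are supplied.
#' @param value,group Column names (strings) when `data` is given, otherwise
#'   numeric values and group labels.
#' @param alpha Familywise level of the range test (default 0.05).
#' @return An object of class `anova_duncan`: list with `anova` (tibble:
#'   `statistic`, `df`, `df_resid`, `p.value`), `groups` (tibble: `group`,
#'   `n`, `mean`, `letters`), `alpha`, `mse`.
#' @export
anova_duncan <- function(data = NULL, value = "value", group = "group",
                         alpha = 0.05) {
  if (!is.null(data)) {
    v <- data[[value]]; g <- data[[group]]
  } else {
    v <- value; g <- group
  }
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- factor(g[keep])
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) < 2)) abort("Need at least 2 values per group.")
  if (var(v) == 0) abort("Constant input: zero total variance.")
  fit <- aov(v ~ g)
  at <- anova(fit)
  mse <- at["Residuals", "Mean Sq"]
  dfr <- at["Residuals", "Df"]
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  dg <- duncan_groups(as.vector(means), as.vector(ns), mse, dfr, alpha)
  structure(list(
    anova = tibble(statistic = at["g", "F value"], df = at["g", "Df"],
                   df_resid = dfr, p.value = at["g", "Pr(>F)"],
                   method = "one-way ANOVA"),
    groups = tibble(group = levels(g), n = as.integer(ns),
                    mean = as.vector(means), letters = dg$letters),
    alpha = alpha, mse = mse, harmonic_n = dg$harmonic_n),
    class = "anova_duncan")
}

#' @export
print.anova_duncan <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df, x$anova$df_resid, x$anova$statistic, x$anova$p.value))
  cat(sprintf("Duncan's multiple range test (alpha = %.2f):\n", x$alpha))
  g <- x$groups[order(x$groups$mean), ]
  for (i in seq_len(nrow(g)))
    cat(sprintf("  %-10s n=%4d  mean %8.4f  %s\n",
                g$group[i], g$n[i], g$mean[i], g$letters[i]))
  invisible(x)
}

#' Per-tissue composition ANOVA with Duncan grouping
#'
#' One [anova_duncan()] per tissue class (fibrous, fibrofatty, necrotic,
#' calcified) across ESS quartiles, restricted to analyzable records.
#'
#' @param data Measurement table with the four fraction columns, `quartile`,
#'   and (optionally) `analyzable`.
#' @param alpha Level for the range tests.
#' @return A tibble of class `composition_anova`, one row per tissue:
#'   `tissue`, `statistic`, `df`, `df_resid`, `p.value`, and a list-column
#'   `duncan` of the full fits.
#' @export
composition_anova <- function(data, alpha = 0.05) {
  data <- as_tibble(data)
  tissues <- c("fibrous", "fibrofatty", "necrotic", "calcified")
  if (!all(c(tissues, "quartile") %in% names(data)))
    abort("`data` needs the four tissue fraction columns and `quartile`.")
  if ("analyzable" %in% names(data)) data <- data[data$analyzable %in% TRUE, ]
  if (nrow(data) == 0) abort("No analyzable records.")
  if (length(unique(data$quartile)) < 2)
    abort("Composition comparison needs at least 2 quartiles present.")
  fits <- lapply(tissues, function(tt)
    anova_duncan(data.frame(value = data[[tt]], group = data$quartile),
                 alpha = alpha))
  out <- tibble(
    tissue = tissues,
    statistic = vapply(fits, function(f) f$anova$statistic, numeric(1)),
    df = vapply(fits, function(f) f$anova$df, numeric(1)),
    df_resid = vapply(fits, function(f) f$anova$df_resid, numeric(1)),
    p.value = vapply(fits, function(f) f$anova$p.value, numeric(1)),
    duncan = fits)
  class(out) <- c("composition_anova", class(out))
  out
}

#' Cluster-robust logistic marginal model (GEE)
#'
#' Fits the marginal logistic regression of a binary outcome on the ESS
#' quartile by generalized estimating equations with an exchangeable working
#' correlation, and reports robust (sandwich) standard errors that account
#' for the clustering of measurements within vessels. With all clusters of
#' size one the estimates coincide with ordinary logistic regression.
#'
#' @param data A data frame, or `NULL` when vectors are supplied.
#' @param outcome,quartile,cluster Column names (strings) if `data` is
#'   given, otherwise the vectors themselves: logical/0-1 outcome, quartile
#'   labels (treated as a factor), cluster ids.
#' @param max_iter,tol Fisher-scoring iteration controls.
#' @return An object of class `gee_fit`: coefficients on the logit scale
#'   (quartile contrasts vs quartile 1), robust and naive SEs, Wald
#'   p-values, the working correlation estimate `alpha`, and convergence
#'   info.
#' @export
fit_clustered_binary <- function(data = NULL, outcome = "plaque",
                                 quartile = "quartile", cluster = "vessel",
                                 max_iter = 50, tol = 1e-10) {
  if (!is.null(data)) {
    y <- data[[outcome]]; q <- data[[quartile]]; cl <- data[[cluster]]
  } else {
    y <- outcome; q <- quartile; cl <- cluster
  }
  keep <- !is.na(y) & !is.na(q) & !is.na(cl)
  y <- as.numeric(y[keep]); q <- factor(q[keep]); cl <- factor(cl[keep])
  if (nlevels(cl) < 2) abort("Need at least 2 clusters.")
  if (all(y == y[1]))
    abort("Outcome is constant: the model is degenerate (complete separation).")
  X <- stats::model.matrix(~ q)
  p <- ncol(X)
  n <- length(y)
  idx <- split(seq_len(n), cl)

  beta <- coef(glm(y ~ q, family = binomial()))
  phi <- 1
  alpha <- 0
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    if (any(mu < 1e-12 | mu > 1 - 1e-12))
      abort("Fitted probabilities numerically 0 or 1: separation detected.")
    w <- mu * (1 - mu)           # variance function = d mu / d eta for logit
    r <- (y - mu) / sqrt(w)      # Pearson residuals
    phi <- sum(r^2) / (n - p)
    # moment estimator of the exchangeable correlation
    num <- 0; den <- 0
    for (ii in idx) {
      m <- length(ii)
      if (m > 1) {
        s <- sum(r[ii])
        num <- num + (s^2 - sum(r[ii]^2)) / 2
        den <- den + m * (m - 1) / 2
      }
    }
    alpha <- if (den > p) num / ((den - p) * phi) else 0
    alpha <- max(min(alpha, 0.99), -0.99)

    U <- numeric(p); H <- matrix(0, p, p); M <- matrix(0, p, p)
    for (ii in idx) {
      m <- length(ii)
      A2 <- sqrt(w[ii])
      D <- X[ii, , drop = FALSE] * w[ii]        # d mu / d beta
      R <- matrix(alpha, m, m); diag(R) <- 1
      Vinv <- chol2inv(chol(R * phi)) / outer(A2, A2)
      DtV <- crossprod(D, Vinv)
      U <- U + DtV %*% (y[ii] - mu[ii])
      H <- H + DtV %*% D
      s_c <- DtV %*% (y[ii] - mu[ii])
      M <- M + tcrossprod(s_c)
    }
    step <- solve(H, U)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  if (max(abs(step)) >= tol)
    abort(sprintf("GEE did not converge in %d iterations.", max_iter))
  if (max(abs(beta)) > 30)
    abort("Diverging coefficients: separation detected (not silently corrected).")

  bread <- solve(H)
  vcov_robust <- bread %*% M %*% bread
  vcov_naive <- bread * phi
  se_r <- sqrt(diag(vcov_robust))
  se_n <- sqrt(pmax(diag(vcov_naive), 0))
  z <- beta / se_r
  structure(list(
    coefficients = setNames(as.vector(beta), colnames(X)),
    robust_se = setNames(se_r, colnames(X)),
    naive_se = setNames(se_n, colnames(X)),
    wald_z = setNames(z, colnames(X)),
    p.value = setNames(2 * pnorm(-abs(z)), colnames(X)),
    alpha = alpha, phi = phi, iterations = it,
    n = n, n_clusters = nlevels(cl),
    vcov_robust = vcov_robust, vcov_naive = vcov_naive),
    class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(paste0("GEE logistic marginal model (exchangeable working ",
                     "correlation)\n  %d observations in %d clusters, ",
                     "alpha-hat = %.3f\n"), x$n, x$n_clusters, x$alpha))
  tab <- cbind(estimate = x$coefficients, robust_se = x$robust_se,
               z = x$wald_z, p = x$p.value)
  print(round(tab, 4))
  invisible(x)
}
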