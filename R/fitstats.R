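#' Least-squares 4-parameter logistic fit
#'
#' Fits `y = lower + (upper - lower) / (1 + exp(-k (x - x0)))` by
#' Levenberg-Marquardt least squares with data-driven starting values. A flat
#' response (range below `flat_tol` of the median absolute level, or below
#' machine noise) is reported as degenerate rather than fitted.
#'
#' @param x,y numeric vectors (>= 8 points).
#' @param flat_tol relative range below which the response is flat.
#' @return A `san_logistic4` object: named `parameters` (`lower`, `upper`,
#'   `x0`, `k`), `rss`, `converged`, `degenerate`, `n`, `fitted`.
#' @export
fit_logistic4 <- function(x, y, flat_tol = 1e-3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 8) stop("need at least 8 points")
  rng <- diff(range(y))
  scale_ref <- max(abs(median(y)), 1e-12)
  if (rng <= flat_tol * scale_ref) {
    return(structure(
      list(
        parameters = c(lower = mean(y), upper = mean(y), x0 = NA_real_,
                       k = NA_real_),
        rss = sum((y - mean(y))^2), converged = FALSE, degenerate = TRUE,
        n = length(x), fitted = rep(mean(y), length(x)), x = x, y = y
      ),
      class = "san_logistic4"
    ))
  }
  lo0 <- quantile(y, 0.05, names = FALSE)
  hi0 <- quantile(y, 0.95, names = FALSE)
  # start x0 at the split point that best separates below-midpoint from
  # above-midpoint responses (robust to edge artefacts), with the overall
  # x-median as a fallback start; keep the best-RSS fit
  ord <- order(x)
  ys <- ma_smooth(y[ord], max(3L, round(length(y) / 20)))
  mid <- (lo0 + hi0) / 2
  above <- ys > mid
  score <- cumsum(!above) + rev(cumsum(rev(above))) - above  # left-below + right-above
  x00_split <- x[ord][which.max(score)]
  k0 <- 4 / (0.25 * diff(range(x)))
  dir <- if (suppressWarnings(stats::cor(x, y)) < 0) -1 else 1
  try_fit <- function(x00, kk) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ lower + (upper - lower) / (1 + exp(-k * (x - x0))),
        start = list(lower = lo0, upper = hi0, x0 = x00, k = kk),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  fits <- list(
    try_fit(x00_split, dir * k0), try_fit(x00_split, dir * 4 * k0),
    try_fit(median(x), dir * k0)
  )
  fits <- Filter(Negate(is.null), fits)
  fit <- NULL
  if (length(fits) > 0) {
    rss_all <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
    fit <- fits[[which.min(rss_all)]]
  }
  if (is.null(fit)) {
    x00 <- x00_split
    return(structure(
      list(
        parameters = c(lower = lo0, upper = hi0, x0 = x00, k = dir * k0),
        rss = NA_real_, converged = FALSE, degenerate = FALSE,
        n = length(x), fitted = rep(NA_real_, length(x)), x = x, y = y
      ),
      class = "san_logistic4"
    ))
  }
  p <- coef(fit)
  # normalise so 'lower' is the left (small-x) asymptote
  if (p["k"] < 0) {
    p <- c(lower = unname(p["upper"]), upper = unname(p["lower"]),
           x0 = unname(p["x0"]), k = unname(-p["k"]))
  }
  structure(
    list(
      parameters = p,
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      degenerate = FALSE,
      n = length(x),
      fitted = stats::fitted(fit),
      x = x, y = y,
      vcov = tryCatch(stats::vcov(fit), error = function(e) NULL)
    ),
    class = "san_logistic4"
  )
}

#' @export
print.san_logistic4 <- function(x, ...) {
  if (x$degenerate) {
    cat("<san_logistic4> degenerate (flat response)\n")
  } else {
    p <- x$parameters
    cat(sprintf(
      "<san_logistic4> lower %.3g, upper %.3g, x0 %.3g, k %.3g (rss %.3g)\n",
      p["lower"], p["upper"], p["x0"], p["k"], x$rss
    ))
  }
  invisible(x)
}

#' @export
tidy.san_logistic4 <- function(x, ...) {
  se <- if (!is.null(x$vcov)) sqrt(diag(x$vcov)) else rep(NA_real_, 4)
  tibble::tibble(
    term = names(x$parameters),
    estimate = unname(x$parameters),
    std.error = unname(se[seq_along(x$parameters)])
  )
}

#' @export
glance.san_logistic4 <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged, degenerate = x$degenerate, n = x$n
  )
}

# ---------------------------------------------------------------------------
# 1D Gaussian mixture via EM
# ---------------------------------------------------------------------------

em_once <- function(x, k, mu0, tol = 1e-8, max_iter = 500) {
  n <- length(x)
  w <- rep(1 / k, k)
  mu <- mu0
  s2 <- rep(var(x) / k, k)
  floor_s2 <- max(var(x), 1e-12) * 1e-6
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sqrt(s2[j])),
                   numeric(n))
    dens <- matrix(dens, n, k)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) break  # component collapsed
    w <- nk / n
    mu <- colSums(resp * x) / nk
    s2 <- vapply(seq_len(k), function(j) {
      sum(resp[, j] * (x - mu[j])^2) / nk[j]
    }, numeric(1))
    s2 <- pmax(s2, floor_s2)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sqrt(s2), loglik = ll_old, converged = converged)
}

#' Maximum-likelihood 1D Gaussian mixture (EM with seeded restarts)
#'
#' @param x numeric data (n >= 30).
#' @param k number of components.
#' @param restarts number of EM restarts from quantile-jittered starting
#'   centers; the best log-likelihood wins.
#' @param seed RNG seed for the restarts (fits are deterministic given it).
#' @param tol relative log-likelihood convergence tolerance.
#' @return A `san_mixture`: `k`, `weights`, `centers`, `widths` (component
#'   SDs), sorted by center; `loglik`, `bic`, `converged`, `degenerate`, `n`.
#' @export
fit_gaussian_mixture <- function(x, k, restarts = 10, seed = 1L, tol = 1e-8) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 30) stop("need at least 30 values")
  if (sd(x) == 0) {
    return(structure(
      list(k = 1L, weights = 1, centers = x[1], widths = 0,
           loglik = NA_real_, bic = NA_real_, converged = FALSE,
           degenerate = TRUE, n = n),
      class = "san_mixture"
    ))
  }
  if (k == 1) {
    mu <- mean(x)
    s <- sqrt(var(x) * (n - 1) / n)
    ll <- sum(dnorm(x, mu, s, log = TRUE))
    return(structure(
      list(k = 1L, weights = 1, centers = mu, widths = s,
           loglik = ll, bic = -2 * ll + 2 * log(n), converged = TRUE,
           degenerate = FALSE, n = n),
      class = "san_mixture"
    ))
  }
  best <- NULL
  with_seed(seed, {
    # first start: evenly spaced quantiles; then jittered restarts
    starts <- list(quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
    for (r in seq_len(restarts - 1)) {
      starts[[r + 1]] <- sort(sample(x, k)) + rnorm(k, sd = sd(x) / 10)
    }
    for (mu0 in starts) {
      fit <- em_once(x, k, mu0, tol = tol)
      if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  ord <- order(best$mu)
  p <- 3 * k - 1
  structure(
    list(
      k = as.integer(k),
      weights = best$w[ord],
      centers = best$mu[ord],
      widths = best$sigma[ord],
      loglik = best$loglik,
      bic = -2 * best$loglik + p * log(n),
      converged = best$converged,
      degenerate = FALSE,
      n = n
    ),
    class = "san_mixture"
  )
}

#' @export
print.san_mixture <- function(x, ...) {
  cat(sprintf("<san_mixture> k = %d (BIC %.1f, n = %d)\n", x$k, x$bic, x$n))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: weight %.2f, center %.3g, width %.3g\n",
                j, x$weights[j], x$centers[j], x$widths[j]))
  }
  invisible(x)
}

#' @export
tidy.san_mixture <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$k),
    weight = x$weights,
    center = x$centers,
    width = x$widths
  )
}

#' @export
glance.san_mixture <- function(x, ...) {
  tibble::tibble(
    k = x$k, loglik = x$loglik, bic = x$bic,
    converged = x$converged, degenerate = x$degenerate, n = x$n
  )
}

# ---------------------------------------------------------------------------
# Group comparisons
# ---------------------------------------------------------------------------

signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "NS"
  )
}

#' Two-group (or multi-group) statistical comparison
#'
#' Routes to the conventional test: Student's t for two normally distributed
#' groups (Shapiro-Wilk at alpha = 0.05 on each group, or on the paired
#' deltas), Mann-Whitney/Wilcoxon otherwise; one-way ANOVA followed by a
#' Tukey multiple-comparison test when more than two groups are supplied as
#' a list. Significance is annotated as NS / * / ** / *** at the 0.05, 0.01
#' and 0.001 levels.
#'
#' @param a,b numeric vectors (two-group mode), or `a` a named list of >= 3
#'   numeric vectors with `b = NULL` (ANOVA mode).
#' @param paired logical, two-group mode only.
#' @return A tibble: `test`, `statistic`, `p_value`, `significance`,
#'   `normal` (did the data pass normality), `flagged` (zero variance). In
#'   ANOVA mode the Tukey pairwise rows follow the omnibus row.
#' @export
group_compare <- function(a, b = NULL, paired = FALSE) {
  if (is.list(a) && !is.data.frame(a) && is.null(b)) {
    if (length(a) < 3) stop("ANOVA mode needs >= 3 groups")
    if (is.null(names(a))) names(a) <- paste0("group", seq_along(a))
    df <- data.frame(
      value = unlist(a, use.names = FALSE),
      group = factor(rep(names(a), lengths(a)))
    )
    fit <- aov(value ~ group, data = df)
    p_om <- summary(fit)[[1]][["Pr(>F)"]][1]
    out <- tibble::tibble(
      test = "anova", statistic = summary(fit)[[1]][["F value"]][1],
      p_value = p_om, significance = signif_stars(p_om),
      normal = NA, flagged = FALSE, comparison = "omnibus"
    )
    tk <- TukeyHSD(fit)$group
    out <- dplyr::bind_rows(out, tibble::tibble(
      test = "tukey", statistic = tk[, "diff"], p_value = tk[, "p adj"],
      significance = signif_stars(tk[, "p adj"]),
      normal = NA, flagged = FALSE, comparison = rownames(tk)
    ))
    return(out)
  }
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (paired && length(a) == length(b) && sd(a - b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    return(tibble::tibble(
      test = "none (identical pairs)", statistic = NA_real_, p_value = p,
      significance = signif_stars(p), normal = NA, flagged = TRUE,
      comparison = "a vs b"
    ))
  }
  if (var(a) == 0 && var(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
    return(tibble::tibble(
      test = "none (zero variance)", statistic = NA_real_, p_value = p,
      significance = signif_stars(p), normal = NA, flagged = TRUE,
      comparison = "a vs b"
    ))
  }
  sh_ok <- function(x) {
    if (length(unique(x)) < 3 || length(x) < 3) return(FALSE)
    if (length(x) > 4999) x <- sample(x, 4999)
    shapiro.test(x)$p.value > 0.05
  }
  normal <- if (paired) sh_ok(a - b) else (sh_ok(a) && sh_ok(b))
  if (normal) {
    ht <- t.test(a, b, paired = paired)
    test <- if (paired) "paired t" else "t"
  } else {
    ht <- suppressWarnings(wilcox.test(a, b, paired = paired, exact = FALSE))
    test <- if (paired) "wilcoxon signed-rank" else "mann-whitney"
  }
  tibble::tibble(
    test = test, statistic = unname(ht$statistic), p_value = ht$p.value,
    significance = signif_stars(ht$p.value), normal = normal,
    flagged = FALSE, comparison = "a vs b"
  )
}
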