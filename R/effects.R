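#' Percent change between two treatment groups with a bootstrap interval
#'
#' Point estimate `100 (mean_treat - mean_ref) / mean_ref` with a seeded
#' bootstrap confidence interval (groups resampled independently). The
#' default interval is studentized (percentile-t, with a delta-method
#' standard error for the ratio of means inside each resample), which
#' keeps close-to-nominal coverage at the small per-cell sample sizes
#' typical of glasshouse experiments; `type = "percentile"` gives the
#' plain percentile interval.
#'
#' @param data A data frame in long form.
#' @param value Column holding the trait values (tidy-eval).
#' @param group Column holding the two group labels (tidy-eval).
#' @param ref Label of the reference group.
#' @param treat Label of the treatment group; defaults to the only other
#'   level present.
#' @param B Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed RNG seed for the resamples.
#' @param type Interval type: `"studentized"` (default) or
#'   `"percentile"`.
#' @return A one-row tibble: `contrast`, `percent_change`, `conf.low`,
#'   `conf.high`, `conf.level`, `n_ref`, `n_treat`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 4),
#'                 y = c(10, 10, 10, 10, 12, 12, 12, 12))
#' percent_change(d, y, g, ref = "a", seed = 1)
#' @export
percent_change <- function(data, value, group, ref, treat = NULL,
                           B = 2000, conf = 0.95, seed = 1,
                           type = c("studentized", "percentile")) {
  type <- match.arg(type)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  x_ref <- v[g == ref]
  if (is.null(treat)) {
    others <- setdiff(unique(g), ref)
    if (length(others) != 1) {
      stop("group has ", length(others) + 1,
           " levels; name the treatment level explicitly", call. = FALSE)
    }
    treat <- others
  }
  x_trt <- v[g == treat]
  x_ref <- x_ref[!is.na(x_ref)]; x_trt <- x_trt[!is.na(x_trt)]
  if (length(x_ref) < 2 || length(x_trt) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (mean(x_ref) <= 0) {
    stop("reference mean is not positive; percent change undefined",
         call. = FALSE)
  }
  pc <- function(trt, rf) 100 * (mean(trt) - mean(rf)) / mean(rf)
  est <- pc(x_trt, x_ref)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n1 <- length(x_trt); n0 <- length(x_ref)
  bm_t <- matrix(sample(x_trt, n1 * B, replace = TRUE), nrow = B)
  bm_r <- matrix(sample(x_ref, n0 * B, replace = TRUE), nrow = B)
  boot <- 100 * (rowMeans(bm_t) - rowMeans(bm_r)) / rowMeans(bm_r)
  alpha <- c((1 - conf) / 2, (1 + conf) / 2)
  if (type == "percentile") {
    qs <- stats::quantile(boot, alpha, names = FALSE)
  } else {
    # percentile-t: pivot each resample with its own delta-method
    # standard error of the ratio of means, then invert
    row_vars <- function(m) rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
    se_delta <- function(mt, mr, vt, vr) {
      100 * sqrt(vt / n1 / mr^2 + mt^2 * vr / n0 / mr^4)
    }
    se_hat <- se_delta(mean(x_trt), mean(x_ref),
                       stats::var(x_trt), stats::var(x_ref))
    if (se_hat == 0) {
      qs <- c(est, est)
    } else {
      se_b <- se_delta(rowMeans(bm_t), rowMeans(bm_r),
                       row_vars(bm_t), row_vars(bm_r))
      tstar <- (boot - est) / se_b
      tstar <- tstar[is.finite(tstar)]
      tq <- stats::quantile(tstar, rev(alpha), names = FALSE)
      qs <- est - tq * se_hat
    }
  }
  tibble::tibble(
    contrast = paste(treat, "vs", ref),
    percent_change = est,
    conf.low = qs[1], conf.high = qs[2], conf.level = conf,
    n_ref = n0, n_treat = n1)
}

#' Factorial analysis of variance of a trait
#'
#' Least-squares decomposition of a trait over crossed experimental factors
#' with all interactions (sequential sums of squares; for the balanced
#' designs this package generates all SS types coincide and term order is
#' immaterial).
#'
#' @param data A data frame.
#' @param response Name of the response column (string).
#' @param factors Character vector of factor column names, e.g.
#'   `c("cultivar", "co2", "hs_regime")`.
#' @return A tibble with one row per model term: `term`, `df`, `sumsq`,
#'   `meansq`, `statistic`, `p.value` (the residual row carries `NA`
#'   statistics).
#' @export
factorial_anova <- function(data, response,
                            factors = c("cultivar", "co2", "hs_regime")) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- dplyr::mutate(data,
                        dplyr::across(dplyr::all_of(factors), as.factor))
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  counts <- dplyr::count(data, !!!rlang::syms(factors), .drop = FALSE)
  if (any(counts$n == 0)) {
    bad <- counts[counts$n == 0, factors, drop = FALSE][1, ]
    stop("empty design cell: ",
         paste(factors, unlist(lapply(bad, as.character)),
               sep = " = ", collapse = ", "), call. = FALSE)
  }
  for (f in factors) {
    if (nlevels(data[[f]]) < 2) {
      stop("factor ", f, " has fewer than 2 levels", call. = FALSE)
    }
  }
  fml <- stats::reformulate(paste(factors, collapse = " * "),
                            response = response)
  fit <- stats::aov(fml, data = data)
  tab <- stats::anova(fit)
  tibble::tibble(
    term = trimws(rownames(tab)),
    df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
    statistic = tab$`F value`, p.value = tab$`Pr(>F)`)
}

#' Compact letter display from a Tukey studentized-range ranking
#'
#' All-pairs comparison of cell means by the studentized-range criterion
#' (Tukey's honestly-significant-difference test) followed by the
#' insert-absorb algorithm for a compact letter display: cells sharing a
#' letter are not significantly different at level `alpha`.
#'
#' @param means Named vector of cell means.
#' @param s2 Pooled within-cell variance.
#' @param n Replicates per cell (balanced; for unbalanced cells pass the
#'   harmonic mean).
#' @param df Residual degrees of freedom of the pooled variance.
#' @param alpha Significance level.
#' @return A tibble with `group`, `mean` and `letters`, sorted by
#'   decreasing mean.
#' @examples
#' tukey_letters(c(a = 10, b = 10.1, c = 20), s2 = 0.5, n = 5, df = 12)
#' @export
tukey_letters <- function(means, s2, n, df, alpha = 0.05) {
  if (df < 1) stop("residual degrees of freedom must be >= 1",
                   call. = FALSE)
  stopifnot(s2 >= 0, n >= 2, !is.null(names(means)))
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  se <- sqrt(s2 / n)  # standard error of a cell mean

  # p-value of each pair under the studentized range distribution
  differs <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(m[i] - m[j]) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
      differs[i, j] <- differs[j, i] <- (p < alpha)
    }
  }

  # insert-absorb: start with one all-inclusive letter column; for each
  # significant pair split every column containing both members, then
  # absorb any column whose member set is contained in another's
  cols <- list(rep(TRUE, k))
  absorb <- function(cols) {
    cols <- unique(cols)
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a == b || !keep[b]) next
        subset_of_a <- all(!cols[[b]] | cols[[a]])
        if (subset_of_a && sum(cols[[b]]) < sum(cols[[a]])) keep[b] <- FALSE
      }
    }
    cols[keep]
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!differs[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- absorb(new_cols)
    }
  }
  letters_out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))

  tibble::tibble(group = names(m), mean = unname(m), letters = letters_out)
}
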