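#' Per-layer summaries of arousal and valence
#'
#' For every layer in the rating table: number of ratings and the mean,
#' median, first and third quartile of each scale (quantile type 7).
#'
#' @param ratings data.frame with columns `layer_name`, `arousal`, `valence`.
#' @param inventory optional character vector fixing the row order; layers
#'   absent from the ratings are dropped.
#' @return data.frame with one row per layer.
#' @export
layer_summaries <- function(ratings, inventory = NULL) {
  stopifnot(nrow(ratings) >= 1L,
            all(c("layer_name", "arousal", "valence") %in% names(ratings)))
  layers <- unique(ratings$layer_name)
  if (!is.null(inventory)) layers <- inventory[inventory %in% layers]
  one <- function(lay) {
    d <- ratings[ratings$layer_name == lay, ]
    qa <- stats::quantile(d$arousal, c(0.25, 0.5, 0.75), names = FALSE)
    qv <- stats::quantile(d$valence, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(layer = lay, n = nrow(d),
               arousal_mean = mean(d$arousal), arousal_median = qa[2],
               arousal_q1 = qa[1], arousal_q3 = qa[3],
               valence_mean = mean(d$valence), valence_median = qv[2],
               valence_q1 = qv[1], valence_q3 = qv[3],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(layers, one))
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix with pairwise p values
#'
#' Standard Pearson r for every pair of columns, with two-sided p values
#' from [stats::cor.test()]. Constant columns yield NA correlations and a
#' warning rather than an error.
#'
#' @param columns numeric data.frame or matrix with at least 3 rows.
#' @return list with `r` (symmetric, unit diagonal), `p`, and `n`.
#' @export
pearson_matrix <- function(columns) {
  x <- as.data.frame(columns)
  stopifnot(nrow(x) >= 3L, all(vapply(x, is.numeric, TRUE)))
  k <- ncol(x)
  constant <- vapply(x, function(v) stats::sd(v) == 0, TRUE)
  if (any(constant))
    warning("constant columns, correlations undefined: ",
            paste(names(x)[constant], collapse = ", "), call. = FALSE)
  r <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  p <- r
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i || constant[i] || constant[j]) next
    ct <- stats::cor.test(x[[i]], x[[j]])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(x))
}

#' Multiple linear regression of a layer-level outcome on image features
#'
#' Ordinary least squares of `y` on the columns of `X` with an intercept:
#' coefficients with classical standard errors, t statistics on
#' `n - k - 1` degrees of freedom, p values, R-squared, adjusted R-squared,
#' and the overall F statistic on (k, n - k - 1) degrees of freedom. The
#' identity `F = (R2 / k) / ((1 - R2) / (n - k - 1))` holds exactly.
#'
#' @param y numeric outcome (one value per case, e.g. per-layer mean arousal).
#' @param X numeric data.frame or matrix of predictors (e.g. the six image
#'   features averaged per layer).
#' @return object of class `regression_result`: list with `coefficients`
#'   (data.frame: term, estimate, se, t, p), `r_squared`, `adj_r_squared`,
#'   `f`, `df1`, `df2`, `f_p`, `n`.
#' @export
ols_fit <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y); k <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= k + 1L) stop("need n > k + 1 cases", call. = FALSE)
  fit <- stats::lm(y ~ ., data = cbind(y = y, X))
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  fs <- sm$fstatistic
  structure(list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                              se = ct[, 2], t = ct[, 3], p = ct[, 4],
                              stringsAsFactors = FALSE, row.names = NULL),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
    f_p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE),
    n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: F(%d, %d) = %.3f, p = %.4g, R2 = %.3f (adj %.3f), n = %d\n",
              x$df1, x$df2, x$f, x$f_p, x$r_squared, x$adj_r_squared, x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' One-way analysis of variance
#'
#' Between/within decomposition with `F` on
#' (groups - 1, n - groups) degrees of freedom. Data with zero
#' between-group sum of squares (including all-identical data) give F = 0.
#'
#' @param values numeric response.
#' @param group_labels grouping factor (at least two non-empty groups).
#' @return list with `f`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(values, group_labels) {
  g <- factor(group_labels)
  stopifnot(length(values) == length(g), nlevels(g) >= 2L,
            all(table(g) >= 1L))
  fit <- stats::lm(values ~ g)
  av <- suppressWarnings(stats::anova(fit))
  ssb <- av$`Sum Sq`[1]; ssw <- av$`Sum Sq`[2]
  df1 <- av$Df[1]; df2 <- av$Df[2]
  # guard the 0/0 case (all-identical data) against floating-point residue
  degenerate <- ssb <= 1e-12 * max(sum(values^2), .Machine$double.eps)
  f <- if (degenerate) 0 else unname(av$`F value`[1])
  p <- if (degenerate) 1 else unname(av$`Pr(>F)`[1])
  list(f = f, df_between = df1, df_within = df2, p = p)
}

#' Per-layer neutrality tests against the scale midpoint
#'
#' One-sample Wilcoxon signed-rank test of each layer's ratings against the
#' neutral value (50) for both scales, with Benjamini-Hochberg adjusted p
#' values across layers and the direction of departure (sign of
#' median - 50). Layers with fewer than `min_n` ratings are dropped with a
#' warning; layers whose ratings all equal the null value are degenerate and
#' reported as non-significant (p = 1, direction 0).
#'
#' @param ratings data.frame with `layer_name`, `arousal`, `valence`.
#' @param null neutral value (default 50).
#' @param min_n minimum ratings per layer (default 6).
#' @return data.frame with one row per layer and scale: `layer`, `scale`,
#'   `n`, `median`, `direction`, `p`, `p_adj`.
#' @export
neutrality_test <- function(ratings, null = 50, min_n = 6L) {
  stopifnot(all(c("layer_name", "arousal", "valence") %in% names(ratings)))
  counts <- table(ratings$layer_name)
  small <- names(counts)[counts < min_n]
  if (length(small)) {
    warning("dropping layers with n < ", min_n, ": ",
            paste(small, collapse = ", "), call. = FALSE)
    ratings <- ratings[!ratings$layer_name %in% small, ]
  }
  layers <- unique(ratings$layer_name)
  if (!length(layers))
    return(data.frame(layer = character(), scale = character(),
                      n = integer(), median = numeric(),
                      direction = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  one <- function(lay, scale) {
    x <- ratings[ratings$layer_name == lay, scale]
    med <- stats::median(x)
    p <- if (all(x == null)) 1 else
      suppressWarnings(stats::wilcox.test(x, mu = null, exact = FALSE)$p.value)
    data.frame(layer = lay, scale = scale, n = length(x), median = med,
               direction = sign(med - null), p = p,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(layers, one, "arousal"),
                          lapply(layers, one, "valence")))
  out$p_adj <- stats::ave(out$p, out$scale,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

#' Compare layer families defined by name patterns
#'
#' Pools ratings into families of layers selected by regular expressions
#' (e.g. `"^mixed[345][a-e]_pool$"` vs `"^mixed[345][a-e]_[35]x[35]_pre_relu$"`)
#' and runs a two-sample Mann-Whitney (Wilcoxon rank-sum) test between every
#' pair of families for each scale. Patterns must match at least one layer
#' and the matched families must be disjoint.
#'
#' @param ratings data.frame with `layer_name`, `arousal`, `valence`.
#' @param pattern_groups named character vector/list of regular expressions.
#' @return list with `members` (named list of matched layer names) and
#'   `tests` (data.frame: scale, group1, group2, n1, n2, statistic, p).
#' @export
group_compare <- function(ratings, pattern_groups) {
  stopifnot(length(pattern_groups) >= 2L, !is.null(names(pattern_groups)))
  layers <- unique(ratings$layer_name)
  members <- lapply(pattern_groups, function(p) layers[grepl(p, layers)])
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty))
    stop("patterns match no layers: ",
         paste(sprintf("%s ('%s')", empty, pattern_groups[empty]),
               collapse = ", "), call. = FALSE)
  all_m <- unlist(members)
  if (anyDuplicated(all_m))
    stop("layer families are not disjoint: ",
         paste(unique(all_m[duplicated(all_m)]), collapse = ", "),
         call. = FALSE)
  pairs <- utils::combn(names(members), 2L, simplify = FALSE)
  rows <- list()
  for (scale in c("arousal", "valence")) for (pr in pairs) {
    x <- ratings[ratings$layer_name %in% members[[pr[1]]], scale]
    y <- ratings[ratings$layer_name %in% members[[pr[2]]], scale]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    rows[[length(rows) + 1L]] <-
      data.frame(scale = scale, group1 = pr[1], group2 = pr[2],
                 n1 = length(x), n2 = length(y),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
  }
  list(members = members, tests = do.call(rbind, rows))
}
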