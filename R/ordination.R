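#' Arcsine-square-root transform for proportions
#'
#' Variance-stabilizing transform for compositional fatty-acid data:
#' \code{asin(sqrt(p))}, monotone from [0, 1] onto [0, pi/2].
#'
#' @param p numeric vector of fractions in [0, 1].
#' @return Transformed vector.
#' @export
arcsine_sqrt <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

# fix axis signs so the largest-magnitude loading on each axis is positive
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis (centered SVD)
#'
#' Column-centered (and, by default, unit-variance scaled) singular value
#' decomposition. Explained-variance shares come from the squared
#' singular values; axis signs follow a fixed convention (the largest-
#' magnitude loading on each axis is positive) so results are
#' deterministic.
#'
#' @param x numeric sample x variable matrix (no missing entries).
#' @param scale scale columns to unit variance (default TRUE, matching a
#'   correlation-matrix PCA).
#' @return A list of class \code{pfw_ordination}: \code{scores}
#'   (sample x dimension), \code{loadings} (variable x dimension),
#'   \code{explained_variance}, \code{sdev}.
#' @export
pfw_pca <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing entries not allowed in PCA input")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs >= 2 samples and >= 2 variables")
  sds <- apply(x, 2, stats::sd)
  if (scale && any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant column cannot be scaled: ", paste(bad, collapse = ", "))
  }
  xc <- scale(x, center = TRUE, scale = scale)
  s <- svd(xc)
  r <- sum(s$d > max(s$d) * 1e-12)
  d <- s$d[seq_len(r)]
  scores <- s$u[, seq_len(r), drop = FALSE] %*% diag(d, r, r)
  loadings <- s$v[, seq_len(r), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(r)))
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(r)))
  fs <- fix_signs(scores, loadings)
  structure(list(scores = fs$scores, loadings = fs$loadings,
                 explained_variance = d^2 / sum(s$d^2),
                 sdev = d / sqrt(nrow(x) - 1)),
            class = "pfw_ordination")
}

#' 95% normal-theory group ellipses for ordination scores
#'
#' Per-group confidence ellipses from the score covariance on two chosen
#' dimensions, scaled by \code{sqrt(qchisq(level, 2))} (2.4477 at 95%) —
#' a plotting convention, not an inference.
#'
#' @param ord a \code{pfw_ordination} (or \code{pfw_mfa}).
#' @param groups group label per sample.
#' @param dims two dimension indices (default 1:2).
#' @param level confidence level (default 0.95).
#' @return A data.frame per group: center, covariance terms and the
#'   scaling radius.
#' @export
ordination_ellipses <- function(ord, groups, dims = 1:2, level = 0.95) {
  sc <- ord$scores[, dims, drop = FALSE]
  groups <- as.character(groups)
  if (length(groups) != nrow(sc))
    stop("one group label per sample required")
  radius <- sqrt(stats::qchisq(level, 2))
  out <- do.call(rbind, lapply(split(seq_along(groups), groups),
                               function(idx) {
    v <- stats::cov(sc[idx, , drop = FALSE])
    data.frame(group = groups[idx[1]],
               center_1 = mean(sc[idx, 1]), center_2 = mean(sc[idx, 2]),
               var_1 = v[1, 1], var_2 = v[2, 2], cov_12 = v[1, 2],
               radius = radius, n = length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' One-way MANOVA with Pillai's trace
#'
#' Between-group (H) and within-group (E) cross-product matrices of the
#' response matrix; Pillai's trace is \code{tr(H (H + E)^-1)}, bounded by
#' \code{min(p, g - 1)}. The standard F approximation and its degrees of
#' freedom are reported.
#'
#' @param x numeric sample x response matrix.
#' @param groups group label per sample; >= 2 groups with >= 2 samples
#'   each.
#' @return A list of class \code{pfw_manova}: \code{pillai_trace},
#'   \code{f_approx}, \code{df_num}, \code{df_den}, \code{p_value},
#'   plus H and E.
#' @export
manova_pillai <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nrow(x) != length(groups)) stop("one group label per sample")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  p <- ncol(x)
  g <- nlevels(groups)
  n <- nrow(x)
  grand <- colMeans(x)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(groups)) {
    sub <- x[groups == lev, , drop = FALSE]
    d <- colMeans(sub) - grand
    H <- H + nrow(sub) * tcrossprod(d)
    cc <- sweep(sub, 2, colMeans(sub))
    E <- E + crossprod(cc)
  }
  T_ <- H + E
  qrT <- qr(T_)
  if (qrT$rank < p)
    stop("singular total cross-product matrix; reduce the response set")
  V <- sum(diag(solve(T_, H)))
  s <- min(p, g - 1)
  m <- (abs(p - g + 1) - 1) / 2
  nn <- (n - g - p - 1) / 2
  df_num <- s * (2 * m + s + 1)
  df_den <- s * (2 * nn + s + 1)
  f_approx <- ((2 * nn + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  structure(list(pillai_trace = V, f_approx = f_approx,
                 df_num = df_num, df_den = df_den,
                 p_value = stats::pf(f_approx, df_num, df_den,
                                     lower.tail = FALSE),
                 H = H, E = E),
            class = "pfw_manova")
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Classical one-way ANOVA followed by all pairwise comparisons on the
#' studentized-range scale. Unequal group sizes use Kramer's
#' harmonic-mean form \code{q = |mi - mj| / sqrt(MSE/2 (1/ni + 1/nj))};
#' with equal sizes this is exactly Tukey's HSD. Family-wise adjusted
#' p-values come from the studentized range distribution.
#'
#' @param values numeric response vector.
#' @param groups group label per value; every group needs >= 2 samples.
#' @return A list of class \code{pfw_posthoc}: \code{f}, \code{df1},
#'   \code{df2}, \code{p_value} for the ANOVA and a \code{pairs}
#'   data.frame (difference, q statistic, adjusted p per pair).
#' @export
anova_tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("one group label per value")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  means <- vapply(split(values, groups), mean, 0)
  ns <- vapply(split(values, groups), length, 0L)
  g <- nlevels(groups)
  n <- length(values)
  ssb <- sum(ns * (means - mean(values))^2)
  sse <- sum((values - ave(values, groups))^2)
  df1 <- g - 1
  df2 <- n - g
  mse <- sse / df2
  # degenerate zero-variance input: no spread, no signal
  f <- if (mse == 0) (if (ssb == 0) 0 else Inf) else (ssb / df1) / mse
  combs <- utils::combn(levels(groups), 2)
  pairs <- data.frame(group_i = combs[1, ], group_j = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$difference <- unname(means[pairs$group_j] - means[pairs$group_i])
  se <- unname(sqrt(mse / 2 * (1 / ns[pairs$group_i] +
                                 1 / ns[pairs$group_j])))
  pairs$q <- ifelse(se == 0, ifelse(pairs$difference == 0, 0, Inf),
                    abs(pairs$difference) / se)
  pairs$p_adjusted <- stats::ptukey(pairs$q, g, df2, lower.tail = FALSE)
  rownames(pairs) <- NULL
  structure(list(f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 mse = mse, pairs = pairs),
            class = "pfw_posthoc")
}

#' Multiple factor analysis
#'
#' Balances several groups of variables observed on the same samples:
#' each group's columns are standardized and divided by the square root
#' of the group's first PCA eigenvalue (so every group's dominant
#' direction contributes unit inertia), then a global centered PCA is run
#' on the concatenated weighted columns. Group weights are the reciprocal
#' first eigenvalues; variable-dimension correlations are reported for
#' loading plots, with a correlation test at \code{alpha} marking
#' "significant" associations.
#'
#' @param tables named list of numeric matrices/data.frames sharing the
#'   same rows (samples).
#' @param alpha significance level for the variable-dimension
#'   correlation test (default 0.05).
#' @return A list of class \code{pfw_mfa}: \code{group_weights},
#'   \code{scores}, \code{loadings}, \code{explained_variance},
#'   \code{dimension_correlations} (with p-values and a significance
#'   flag), \code{group_first_eigenvalues}.
#' @export
mfa <- function(tables, alpha = 0.05) {
  if (!is.list(tables) || length(tables) == 0L)
    stop("tables must be a nonempty named list")
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("every variable group needs a name")
  mats <- lapply(tables, as.matrix)
  ns <- vapply(mats, nrow, 0L)
  if (length(unique(ns)) != 1L)
    stop("all groups must share the same samples (row counts differ)")
  n <- ns[[1]]
  lambda1 <- numeric(length(mats))
  weighted <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable in group '", names(tables)[i], "'")
    z <- scale(m, center = TRUE, scale = TRUE)
    d1 <- svd(z, nu = 0, nv = 0)$d[1]
    lambda1[i] <- d1^2 / (n - 1)          # first eigenvalue, correlation PCA
    weighted[[i]] <- z / sqrt(lambda1[i])
    colnames(weighted[[i]]) <- paste(names(tables)[i],
                                     colnames(m) %||% seq_len(ncol(m)),
                                     sep = ".")
  }
  gw <- 1 / lambda1
  names(gw) <- names(tables)
  global <- do.call(cbind, weighted)
  s <- svd(global)
  r <- sum(s$d > max(s$d) * 1e-12)
  d <- s$d[seq_len(r)]
  scores <- s$u[, seq_len(r), drop = FALSE] %*% diag(d, r, r)
  loadings <- s$v[, seq_len(r), drop = FALSE]
  dimnames(scores) <- list(rownames(global), paste0("Dim", seq_len(r)))
  dimnames(loadings) <- list(colnames(global), paste0("Dim", seq_len(r)))
  fs <- fix_signs(scores, loadings)
  scores <- fs$scores; loadings <- fs$loadings
  ndim <- min(r, 5L)
  corr <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    do.call(rbind, lapply(seq_len(ncol(m)), function(j) {
      vn <- (colnames(m) %||% seq_len(ncol(m)))[j]
      do.call(rbind, lapply(seq_len(ndim), function(dd) {
        ct <- stats::cor.test(m[, j], scores[, dd])
        data.frame(group = names(tables)[i], variable = vn,
                   dimension = dd, correlation = unname(ct$estimate),
                   p_value = ct$p.value,
                   significant = ct$p.value <= alpha,
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(corr) <- NULL
  structure(list(group_weights = gw,
                 group_first_eigenvalues = stats::setNames(lambda1,
                                                           names(tables)),
                 scores = scores, loadings = loadings,
                 explained_variance = d^2 / sum(s$d^2),
                 dimension_correlations = corr),
            class = "pfw_mfa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fatty-acid signature matrix
#'
#' Builds the sample x fatty-acid matrix (optionally arcsine-square-root
#' transformed) and the group vector from a tidy signature table, ready
#' for [pfw_pca()] / [manova_pillai()].
#'
#' @param signatures data.frame with columns \code{sample_id},
#'   \code{group}, \code{fatty_acid}, \code{proportion}.
#' @param transform apply [arcsine_sqrt()] (default TRUE).
#' @return list with \code{x} (matrix) and \code{groups}.
#' @export
fa_matrix <- function(signatures, transform = TRUE) {
  samples <- unique(signatures$sample_id)
  fas <- unique(signatures$fatty_acid)
  m <- matrix(NA_real_, length(samples), length(fas),
              dimnames = list(samples, fas))
  m[cbind(match(signatures$sample_id, samples),
          match(signatures$fatty_acid, fas))] <- signatures$proportion
  if (anyNA(m)) stop("incomplete fatty-acid panel for some samples")
  if (transform) m[] <- arcsine_sqrt(m)
  groups <- signatures$group[match(samples, signatures$sample_id)]
  list(x = m, groups = groups)
}
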