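#' Discriminant analysis of principal components (DAPC)
#'
#' Characterizes how symbiont community composition separates host species:
#' features (by convention the `ln(x) + 1`-transformed per-clade 28S
#' quantities, absent clades entered as 0) are centered and scaled,
#' projected onto leading principal components, and a linear discriminant
#' analysis is run on the group labels in PC space. Axes are reported with
#' their percent of discriminable variance, per-sample scores, and
#' per-variable loadings.
#'
#' @param data Data frame or matrix of numeric features, one row per
#'   sample.
#' @param groups Group labels (e.g., host species), length `nrow(data)`,
#'   at least 2 distinct values.
#' @param n_pca Number of principal components retained before the
#'   discriminant step. Default: the smallest number retaining >= 95% of
#'   the total variance (capped at the matrix rank and at `n - G`).
#' @param n_axes Number of discriminant axes reported (default
#'   `min(G - 1, n_pca)`).
#' @param ridge Ridge added to the within-group scatter before inversion
#'   (as a fraction of its mean diagonal). 0 by default; applied
#'   automatically (and recorded) if the scatter is singular.
#' @return A `dapc_fit` object: `eig` (discriminant eigenvalues),
#'   `var_pct` (percent of discriminable variance per axis, non-increasing,
#'   summing to <= 100), `scores` (tibble of per-sample axis scores),
#'   `loadings` (per original variable), `correlations`
#'   ([axis_correlations()] of every variable against every axis),
#'   `n_pca`, and `ridge_used`.
#' @export
dapc <- function(data, groups, n_pca = NULL, n_axes = NULL, ridge = 0) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  groups <- as.factor(groups)
  if (length(groups) != nrow(x)) {
    abort("`groups` must have one label per row of `data`.")
  }
  g <- nlevels(droplevels(groups))
  if (g < 2) abort("DAPC needs at least 2 groups.")
  small <- names(which(table(groups) < 2))
  if (length(small) > 0) {
    warn(paste0("Group(s) with fewer than 2 samples (retained): ",
                paste(small, collapse = ", ")))
  }

  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  xs <- scale(x, center = TRUE, scale = sds)
  pca <- prcomp(xs, center = FALSE, scale. = FALSE)
  pos <- pca$sdev > 1e-10 * pca$sdev[1]
  rank <- sum(pos)
  if (is.null(n_pca)) {
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    n_pca <- which(cum >= 0.95)[1]
  }
  n_pca <- min(n_pca, rank, nrow(x) - g)
  if (n_pca < 1) abort("Not enough samples for the principal-component step.")
  pc <- pca$x[, seq_len(n_pca), drop = FALSE]

  sc <- scatter_matrices(pc, groups)
  eps <- ridge * mean(diag(sc$W))
  ridge_used <- eps
  chol_ok <- function(e) tryCatch(chol(sc$W + e * diag(n_pca)),
                                  error = function(cnd) NULL)
  R <- chol_ok(eps)
  if (is.null(R)) {
    ridge_used <- 1e-8 * mean(diag(sc$W))
    warn(sprintf("Within-group scatter singular; ridge %.3g applied.",
                 ridge_used))
    R <- chol_ok(ridge_used)
    if (is.null(R)) abort("Within-group scatter could not be regularized.")
  }
  Rinv <- backsolve(R, diag(n_pca))
  M <- t(Rinv) %*% sc$B %*% Rinv
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep_all <- which(ed$values > max(ed$values[1], 0) * 1e-12)
  keep_all <- head(keep_all, g - 1)
  eig_all <- ed$values[keep_all]
  if (is.null(n_axes)) n_axes <- min(g - 1, n_pca)
  n_axes <- min(n_axes, length(eig_all))
  A <- Rinv %*% ed$vectors[, keep_all[seq_len(n_axes)], drop = FALSE]

  ld_scores <- pc %*% A
  colnames(ld_scores) <- paste0("LD", seq_len(n_axes))
  var_pct <- 100 * eig_all[seq_len(n_axes)] / sum(eig_all)

  rot <- pca$rotation[, seq_len(n_pca), drop = FALSE] %*% A
  colnames(rot) <- colnames(ld_scores)
  vars <- colnames(x) %||% paste0("V", seq_len(ncol(x)))

  scores <- tibble::as_tibble(ld_scores) |>
    dplyr::mutate(group = groups, .before = 1)
  loadings <- tibble::as_tibble(rot) |>
    dplyr::mutate(variable = vars, .before = 1)
  correlations <- axis_correlations(ld_scores, x)

  centroids <- rowsum(ld_scores, groups)
  centroids <- centroids / as.vector(table(groups)[rownames(centroids)])

  structure(
    list(eig = eig_all[seq_len(n_axes)], var_pct = var_pct,
         scores = scores, loadings = loadings,
         correlations = correlations, n_pca = n_pca, n_axes = n_axes,
         n_groups = g, ridge_used = ridge_used,
         projection = list(center = attr(xs, "scaled:center"), scale = sds,
                           rotation = pca$rotation[, seq_len(n_pca),
                                                   drop = FALSE],
                           discriminants = A),
         centroids = centroids),
    class = "dapc_fit"
  )
}

#' Project new samples onto fitted discriminant axes
#'
#' Applies the fitted centering/scaling, PCA rotation and discriminant
#' transform to new feature rows, and assigns each to the group with the
#' nearest centroid in discriminant space.
#'
#' @param object A `dapc_fit`.
#' @param newdata Data frame or matrix with the same feature columns the
#'   fit was trained on.
#' @param ... Unused.
#' @return A tibble of LD scores with an `assigned` group column.
#' @export
predict.dapc_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  pr <- object$projection
  xs <- sweep(sweep(x, 2, pr$center), 2, pr$scale, "/")
  ld <- xs %*% pr$rotation %*% pr$discriminants
  colnames(ld) <- paste0("LD", seq_len(ncol(ld)))
  cent <- object$centroids
  assigned <- apply(ld, 1, function(row) {
    rownames(cent)[which.min(colSums((t(cent) - row)^2))]
  })
  tibble::as_tibble(ld) |>
    dplyr::mutate(assigned = assigned)
}

scatter_matrices <- function(pc, groups) {
  groups <- droplevels(groups)
  n <- nrow(pc)
  lv <- levels(groups)
  g <- length(lv)
  counts <- as.vector(table(groups)[lv])
  gm <- do.call(rbind, lapply(lv, function(l) {
    colMeans(pc[groups == l, , drop = FALSE])
  }))
  centered <- pc - gm[match(groups, lv), , drop = FALSE]
  W <- crossprod(centered) / (n - g)
  m <- colMeans(pc)
  dev <- sweep(gm, 2, m)
  B <- crossprod(dev * sqrt(counts)) / (g - 1)
  list(W = W, B = B)
}

#' @export
print.dapc_fit <- function(x, ...) {
  cat("<dapc_fit> ", x$n_groups, " groups, ", x$n_pca,
      " PCs retained, ", x$n_axes, " discriminant axes\n", sep = "")
  cat("  % of discriminable variance:",
      paste0(sprintf("%.1f", x$var_pct), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dapc_fit <- function(x, ...) {
  tibble::tibble(
    axis = paste0("LD", seq_along(x$eig)),
    eigenvalue = x$eig,
    var_pct = x$var_pct
  )
}

#' @exportS3Method generics::glance
glance.dapc_fit <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), n_groups = x$n_groups, n_pca = x$n_pca,
    n_axes = x$n_axes, total_var_pct = sum(x$var_pct),
    ridge = x$ridge_used
  )
}

#' @exportS3Method generics::augment
augment.dapc_fit <- function(x, ...) x$scores

#' @rdname plot_cladeqpcr
#' @exportS3Method ggplot2::autoplot
autoplot.dapc_fit <- function(object, axes = c(1, 2), ...) {
  ax <- paste0("LD", axes)
  if (length(object$eig) < 2) {
    p <- ggplot2::ggplot(object$scores,
                         ggplot2::aes(x = .data[[ax[1]]],
                                      fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.5)
    return(p + ggplot2::theme_minimal())
  }
  lab <- sprintf("%s (%.1f%%)", ax, object$var_pct[axes])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.9, na.rm = TRUE) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "group") +
    ggplot2::theme_minimal()
}

#' Pearson correlations of variables against ordination axes
#'
#' For each feature and each discriminant axis: Pearson r, the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))`, and the two-sided p-value on
#' `n - 2` degrees of freedom. Perfectly correlated variables report
#' infinite t and a zero (below machine floor) p; zero-variance variables
#' report `NA`.
#'
#' @param scores Numeric vector or matrix of per-sample axis scores.
#' @param variables Numeric vector, matrix or data frame of per-sample
#'   feature values (same number of rows).
#' @return A tibble: `variable`, `axis`, `r`, `statistic`, `df`,
#'   `p.value`.
#' @export
axis_correlations <- function(scores, variables) {
  s <- as.matrix(scores)
  v <- as.matrix(variables)
  storage.mode(s) <- storage.mode(v) <- "double"
  if (nrow(s) != nrow(v)) abort("`scores` and `variables` lengths differ.")
  n <- nrow(s)
  if (n < 3) abort("Need at least 3 observations.")
  if (is.null(colnames(s))) colnames(s) <- paste0("LD", seq_len(ncol(s)))
  if (is.null(colnames(v))) colnames(v) <- paste0("V", seq_len(ncol(v)))
  grid <- tidyr::crossing(variable = colnames(v), axis = colnames(s))
  purrr::pmap_dfr(grid, function(variable, axis) {
    x <- v[, variable]
    y <- s[, axis]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(variable = variable, axis = axis, r = NA_real_,
                            statistic = NA_real_, df = n - 2,
                            p.value = NA_real_))
    }
    r <- cor(x, y)
    tstat <- if (abs(r) >= 1 - 1e-12) sign(r) * Inf else
      r * sqrt((n - 2) / (1 - r^2))
    tibble::tibble(variable = variable, axis = axis, r = r,
                   statistic = tstat, df = n - 2,
                   p.value = 2 * pt(-abs(tstat), n - 2))
  })
}
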