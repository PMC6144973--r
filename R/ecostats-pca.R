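#' Trait log-transformation and correlation-matrix PCA
#'
#' The seven appearance variables (spot number, mean spot size, spottiness,
#' background and spot VIS reflectance, background and spot UV reflectance)
#' are log-transformed to linearize their relationships and summarized by a
#' PCA of their correlation matrix. PC1 is oriented so the background-VIS
#' loading is positive (positive scores = lighter eggs); PC2 so the spot-size
#' loading is positive (positive scores = fewer, larger spots).
#'
#' @name ecostats-pca
NULL

trait_names <- function() c("spot_number", "spot_size", "spottiness",
                            "B_VIS", "S_VIS", "B_UV", "S_UV")

#' Log-transform the seven trait variables
#'
#' Natural log throughout; spot_number uses log(x + 1) so spotless eggs
#' remain admissible; eggs with zero spottiness are marked in an `exclude`
#' column (log 0 is undefined) rather than silently dropped.
#'
#' @param table data.frame containing the seven trait columns (see
#'   `trait_names()`).
#' @return the table with traits replaced by their logs and an `exclude`
#'   logical column appended.
#' @export
log_traits <- function(table) {
  tn <- trait_names()
  missing_cols <- setdiff(tn, names(table))
  if (length(missing_cols) > 0) {
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(table[tn] < 0, na.rm = TRUE)) stop("domain error: negative trait value")
  out <- table
  out$exclude <- !is.na(table$spottiness) & table$spottiness == 0
  out$spot_number <- log(table$spot_number + 1)
  for (v in setdiff(tn, "spot_number")) {
    x <- table[[v]]
    x[!is.na(x) & x == 0] <- NA
    out[[v]] <- log(x)
  }
  out
}

#' Correlation-matrix PCA of the log traits
#'
#' Eigen-decomposition of the Pearson correlation matrix of the seven
#' (already log-transformed) traits over complete rows.
#'
#' @param table data.frame with the log trait columns.
#' @param n_components number of score columns to return (all loadings are
#'   kept).
#' @return an object of class `pca_result`: `loadings` (7 x 7, unit-norm
#'   orthogonal columns), `eigenvalues`, `variance_fraction`, `scores`
#'   (complete rows x n_components), `complete` (row filter used), and
#'   `sign_flipped` (per retained component).
#' @export
pca_corr <- function(table, n_components = 2) {
  tn <- trait_names()
  X <- as.matrix(table[, tn, drop = FALSE])
  if (!is.null(table$exclude)) X[table$exclude, ] <- NA
  complete <- stats::complete.cases(X)
  if (sum(complete) < 8) stop("PCA requires at least 8 complete rows")
  X <- X[complete, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate correlation matrix: constant column ",
         paste(tn[sds == 0], collapse = ", "))
  }
  Cm <- stats::cor(X)
  es <- eigen(Cm, symmetric = TRUE)
  load <- es$vectors
  rownames(load) <- tn
  colnames(load) <- paste0("PC", seq_len(ncol(load)))
  Z <- scale(X)
  flipped <- logical(ncol(load))
  # sign conventions on the two retained axes
  if (load["B_VIS", 1] < 0) { load[, 1] <- -load[, 1]; flipped[1] <- TRUE }
  if (ncol(load) >= 2 && load["spot_size", 2] < 0) { load[, 2] <- -load[, 2]; flipped[2] <- TRUE }
  scores <- Z %*% load[, seq_len(n_components), drop = FALSE]
  structure(list(loadings = load, eigenvalues = es$values,
                 variance_fraction = es$values / sum(es$values),
                 scores = scores, complete = complete,
                 sign_flipped = flipped, n = nrow(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:2])
  cat(sprintf("<pca_result> n = %d; PC1 %d%%, PC2 %d%% of variance\n", x$n, vf[1], vf[2]))
  print(round(x$loadings[, 1:2], 3))
  invisible(x)
}

#' Validate loading vectors for unit norm and mutual orthogonality
#'
#' The structural check applied to every `pca_result` and usable on
#' externally reported eigenvectors: each loading column must have unit
#' Euclidean norm and distinct columns must be orthogonal.
#'
#' @param loadings matrix whose columns are loading vectors.
#' @param tol tolerance on |1 - norm| and on absolute pairwise dot products.
#' @return invisibly, a list with `norm_dev` (per column) and `max_dot`;
#'   throws if the tolerance is exceeded.
#' @export
validate_loadings <- function(loadings, tol = 0.01) {
  loadings <- as.matrix(loadings)
  norms <- sqrt(colSums(loadings^2))
  norm_dev <- abs(1 - norms)
  G <- crossprod(loadings)
  max_dot <- if (ncol(loadings) > 1) max(abs(G[upper.tri(G)])) else 0
  if (any(norm_dev >= tol)) stop("loading column without unit norm")
  if (max_dot >= tol) stop("loading columns are not orthogonal")
  invisible(list(norm_dev = norm_dev, max_dot = max_dot))
}
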