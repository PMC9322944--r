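# Eigendecomposition of the FC matrix and its split into cognitive-mode
# (CM) and default-mode (DM) component matrices.
#
# "Component weights" are the eigenvalues of the symmetric FC matrix.
# Components whose eigenvalue exceeds the threshold form the CM matrix by
# default (the task-dominant side during a Stroop block design); the
# remainder form the DM matrix. The two always sum exactly back to the
# input.

#' Spectral decomposition of a connectivity matrix
#'
#' Full eigendecomposition with eigenvalues sorted descending and a
#' deterministic eigenvector sign convention: the largest-magnitude entry
#' of each eigenvector is made positive (first such entry on ties), so the
#' decomposition is reproducible across platforms.
#'
#' @param m Symmetric numeric matrix (e.g. the retained submatrix of an
#'   [fc_matrix()]).
#' @param tol Symmetry tolerance.
#' @return List with `values` (descending) and `vectors` (orthonormal
#'   columns).
#' @export
eigendecompose <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol) {
    stop_stroopfc("input must be symmetric (tolerance ", tol, ")")
  }
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  list(values = e$values, vectors = v)
}

#' Select the component-weight threshold
#'
#' Strategies:
#' * `mean_eigenvalue` (default): the mean of the spectrum. For a
#'   correlation matrix the mean eigenvalue is 1, so components carrying
#'   more than an average channel's share of variance land above it.
#' * `fixed_count_k`: exactly `fixed_k` components above the threshold.
#' * `elbow_max_gap`: the midpoint of the largest gap between consecutive
#'   sorted eigenvalues.
#'
#' When all eigenvalues are (numerically) equal there is no spectrum
#' structure to split; `-Inf` is returned so every component lands on the
#' CM side by convention.
#'
#' @param eigenvalues Numeric vector sorted in descending order.
#' @param strategy Threshold strategy.
#' @param fixed_k Number of components above threshold for
#'   `fixed_count_k` (0..n).
#' @return Threshold value (possibly `-Inf`/`Inf` at the extremes).
#' @export
select_threshold <- function(eigenvalues,
                             strategy = c("mean_eigenvalue", "fixed_count_k",
                                          "elbow_max_gap"),
                             fixed_k = NULL) {
  strategy <- match.arg(strategy)
  ev <- as.numeric(eigenvalues)
  n <- length(ev)
  if (n < 2) stop_stroopfc("need at least 2 eigenvalues")
  if (is.unsorted(rev(ev))) stop_stroopfc("eigenvalues must be sorted descending")
  spread <- ev[1] - ev[n]
  tie_tol <- 1e-12 * max(1, abs(ev[1]))
  if (spread <= tie_tol) return(-Inf)          # tie: everything to CM
  switch(strategy,
    mean_eigenvalue = mean(ev),
    fixed_count_k = {
      if (is.null(fixed_k) || fixed_k < 0 || fixed_k > n) {
        stop_stroopfc("fixed_k must be in 0..", n)
      }
      if (fixed_k == 0) Inf
      else if (fixed_k == n) -Inf
      else (ev[fixed_k] + ev[fixed_k + 1]) / 2
    },
    elbow_max_gap = {
      gaps <- ev[-n] - ev[-1]
      i <- which.max(gaps)
      (ev[i] + ev[i + 1]) / 2
    }
  )
}

#' Reconstruct CM and DM component matrices
#'
#' `cm = sum_{lambda_k > theta} lambda_k v_k v_k'` and
#' `dm = sum_{lambda_k <= theta} lambda_k v_k v_k'` (sides swapped when
#' `cm_is_above = FALSE`). By the spectral theorem `cm + dm` equals the
#' decomposed matrix for every threshold.
#'
#' @param decomp List from [eigendecompose()].
#' @param threshold Component-weight threshold.
#' @param cm_is_above If `TRUE` (default) the above-threshold components
#'   form the CM matrix.
#' @return List with symmetric matrices `cm` and `dm`.
#' @export
reconstruct_components <- function(decomp, threshold, cm_is_above = TRUE) {
  v <- decomp$vectors
  ev <- decomp$values
  part <- function(sel) {
    if (!any(sel)) return(matrix(0, nrow(v), nrow(v)))
    vs <- v[, sel, drop = FALSE]
    vs %*% (ev[sel] * t(vs))
  }
  above <- ev > threshold
  if (cm_is_above) list(cm = part(above), dm = part(!above))
  else list(cm = part(!above), dm = part(above))
}

#' Decompose an FC matrix into CM and DM networks
#'
#' Operates on the retained-channel submatrix of the connectivity
#' container.
#'
#' @param fc An [fc_matrix()] or a plain symmetric matrix.
#' @param strategy,fixed_k Passed to [select_threshold()].
#' @param cm_is_above Passed to [reconstruct_components()].
#' @return An object of class `network_decomposition` with fields
#'   `eigenvalues`, `eigenvectors`, `threshold`, `cm_matrix`, `dm_matrix`,
#'   and `channel_ids`.
#' @export
decompose_fc <- function(fc, strategy = "mean_eigenvalue", fixed_k = NULL,
                         cm_is_above = TRUE) {
  if (inherits(fc, "fc_matrix")) {
    keep <- fc$retained
    m <- fc$values[keep, keep, drop = FALSE]
    ids <- fc$channel_ids[keep]
  } else {
    m <- as.matrix(fc)
    ids <- rownames(m) %||% channel_col_names(nrow(m))
  }
  dec <- eigendecompose(m)
  theta <- select_threshold(dec$values, strategy = strategy, fixed_k = fixed_k)
  comp <- reconstruct_components(dec, theta, cm_is_above = cm_is_above)
  dimnames(comp$cm) <- dimnames(comp$dm) <- list(ids, ids)
  structure(
    list(eigenvalues = dec$values, eigenvectors = dec$vectors,
         threshold = theta, cm_matrix = comp$cm, dm_matrix = comp$dm,
         channel_ids = ids, strategy = strategy),
    class = "network_decomposition"
  )
}
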