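# Soft-margin SVM trained by sequential minimal optimization (SMO).
#
# Solves the standard dual
#   min 1/2 a' Q a - e' a,  0 <= a <= C,  y' a = 0,   Q = (y y') * K
# with maximal-violating-pair working-set selection and the Karush-Kuhn-
# Tucker gap  m(a) - M(a) <= tol  as the stopping rule, the classic SMO
# formulation. Deterministic: ties in the working-set selection resolve to
# the lowest index, so identical inputs give identical models. Multiclass
# is one-vs-one with pairwise voting; ties break by largest aggregate
# decision value, then class order.

smo_binary <- function(K, y, C, tol = 1e-8, max_iter = NULL) {
  n <- length(y)
  if (is.null(max_iter)) max_iter <- max(200L * n, 20000L)
  alpha <- numeric(n)
  grad <- rep(-1, n)                     # gradient of the dual at alpha = 0
  Qy <- y * t(K * y)                     # Q[i, j] = y_i y_j K_ij (as columns)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y < 0 & alpha < C) | (y > 0 & alpha > 0)
    yg <- -y * grad
    if (!any(up) || !any(lo)) break
    m_val <- max(yg[up])
    M_val <- min(yg[lo])
    if (m_val - M_val <= tol) break
    if (iter > max_iter) {
      warning("SMO hit the iteration cap before reaching tolerance ", tol)
      break
    }
    i <- which(up)[which.max(yg[up])]
    j <- which(lo)[which.min(yg[lo])]
    # analytic two-variable solve (Platt), bounds preserving y'a = 0
    s <- y[i] * y[j]
    if (s < 0) {
      L <- max(0, alpha[j] - alpha[i])
      H <- min(C, C + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - C)
      H <- min(C, alpha[i] + alpha[j])
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    # E_i - E_j in terms of the dual gradient: E_k = u_k - y_k with
    # u_k = y_k (grad_k + 1), so E_i - E_j = y_i grad_i - y_j grad_j
    diffE <- y[i] * grad[i] - y[j] * grad[j]
    aj_new <- if (eta > 1e-12) {
      min(max(alpha[j] + y[j] * diffE / eta, L), H)
    } else {
      # flat direction (duplicate points): move to the better endpoint
      if (y[j] * diffE > 0) H else L
    }
    if (abs(aj_new - alpha[j]) < 1e-14) {
      # numerically stuck pair; KKT gap above says not converged, but no
      # progress is possible in this direction - treat as converged
      break
    }
    ai_new <- alpha[i] + s * (alpha[j] - aj_new)
    d_i <- ai_new - alpha[i]
    d_j <- aj_new - alpha[j]
    grad <- grad + Qy[, i] * d_i + Qy[, j] * d_j
    alpha[i] <- ai_new
    alpha[j] <- aj_new
  }
  # bias from the KKT interval midpoint (decision f(x) = sum a y K + b)
  up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
  lo <- (y < 0 & alpha < C) | (y > 0 & alpha > 0)
  yg <- -y * grad
  b <- if (any(up) && any(lo)) (max(yg[up]) + min(yg[lo])) / 2 else 0
  list(alpha = alpha, b = b, iterations = iter)
}

svm_fit <- function(x, y, params, tol = 1e-8) {
  lv <- levels(y)
  K <- puk_gram(x, x, params$omega, params$sigma)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    sel <- which(y %in% pr)
    ybin <- ifelse(y[sel] == pr[1], 1, -1)
    fit <- smo_binary(K[sel, sel, drop = FALSE], ybin,
                      C = params$c_regularization, tol = tol)
    keep <- fit$alpha > 1e-12
    list(pair = pr, sv_index = sel[keep],
         coef = (fit$alpha * ybin)[keep], b = fit$b)
  })
  list(levels = lv, models = models, xtrain = x, params = params)
}

svm_decision <- function(fit, m, x) {
  Kx <- puk_gram(x, fit$xtrain[m$sv_index, , drop = FALSE],
                 fit$params$omega, fit$params$sigma)
  drop(Kx %*% m$coef) + m$b
}

svm_predict <- function(fit, x) {
  lv <- fit$levels
  votes <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
  margin <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
  for (m in fit$models) {
    d <- svm_decision(fit, m, x)
    win <- ifelse(d >= 0, m$pair[1], m$pair[2])
    for (r in seq_along(d)) votes[r, win[r]] <- votes[r, win[r]] + 1
    margin[, m$pair[1]] <- margin[, m$pair[1]] + d
    margin[, m$pair[2]] <- margin[, m$pair[2]] - d
  }
  pick <- vapply(seq_len(nrow(x)), function(r) {
    top <- which(votes[r, ] == max(votes[r, ]))
    if (length(top) > 1) {
      top <- top[order(-margin[r, top], top)]   # margin, then class order
    }
    top[1]
  }, integer(1))
  factor(lv[pick], levels = lv)
}
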