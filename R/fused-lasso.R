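# Fused-lasso multi-task regression across time points: the regression
# model behind each DRMN module. For one module, coefficients Theta
# (features x times) minimize
#
#   sum_c || x_c - Y_c theta_c ||_2^2
#     + rho1 * ||Theta||_1
#     + rho2 * sum_{consecutive c,c'} ||theta_c - theta_c'||_1
#     + rho3 * sum_features ||Theta[feature, ]||_2
#
# All three penalties act row-wise (per feature across time), so the exact
# proximal operator is the composition
#   group-L2 shrink  o  soft-threshold  o  1-D TV prox
# computed in compiled code. The solver is proximal gradient with FISTA
# momentum and a descent safeguard (the momentum step is replaced by the
# plain proximal-gradient step whenever it would increase the objective),
# so the reported objective trace is non-increasing.

#' 1-D total-variation proximal operator
#'
#' Exact solution of `argmin_x 0.5 * ||x - y||^2 + lam * TV(x)` with
#' `TV(x) = sum |x[i+1] - x[i]|`, by Condat's direct algorithm.
#'
#' @param y Numeric vector.
#' @param lam Non-negative penalty.
#' @return Numeric vector of the same length.
#' @export
prox_tv1d <- function(y, lam) {
  check_number(lam, "lam", 0)
  as.numeric(.prox_tv1d_cpp(as.numeric(y), lam))
}

#' DRMN hyperparameters
#'
#' @param rho1 Sparsity (L1) penalty.
#' @param rho2 Consecutive-time fusion penalty.
#' @param rho3 Across-time group (L2 per feature) penalty.
#' @return A named list of class `drmn_hyper`.
#' @export
drmn_hyper <- function(rho1 = 5, rho2 = 45, rho3 = 0) {
  check_number(rho1, "rho1", 0); check_number(rho2, "rho2", 0)
  check_number(rho3, "rho3", 0)
  structure(list(rho1 = rho1, rho2 = rho2, rho3 = rho3),
            class = "drmn_hyper")
}

#' Objective value of the fused-lasso module regression
#'
#' @param theta Features x times coefficient matrix.
#' @param x_list,y_list Per-time response vectors and design matrices.
#' @param hyper A [drmn_hyper()].
#' @param intercepts Optional per-time intercepts (default zero).
#' @return A single number.
#' @export
fused_lasso_objective <- function(theta, x_list, y_list, hyper,
                                  intercepts = NULL) {
  C <- length(x_list)
  intercepts <- intercepts %||% rep(0, C)
  loss <- sum(vapply(seq_len(C), function(cc) {
    if (!length(x_list[[cc]])) return(0)
    r <- x_list[[cc]] - intercepts[cc] - as.vector(y_list[[cc]] %*% theta[, cc])
    sum(r^2)
  }, numeric(1)))
  pen <- hyper$rho1 * sum(abs(theta)) +
    hyper$rho2 * sum(abs(theta[, -1, drop = FALSE] -
                           theta[, -ncol(theta), drop = FALSE])) +
    hyper$rho3 * sum(sqrt(rowSums(theta^2)))
  loss + pen
}

#' Fit one fused-lasso module regression across time points
#'
#' @param x_list List (over time points) of numeric response vectors
#'   (expression of the module's genes at that time).
#' @param y_list List of design matrices (genes x features), same feature
#'   set everywhere. A time point with zero rows contributes only the
#'   penalties.
#' @param hyper A [drmn_hyper()].
#' @param intercept Fit an unpenalized per-time intercept (default TRUE).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum iterations.
#' @return List with `theta` (features x times, exact zeros from the L1
#'   prox), `intercepts`, `objective`, `obj_trace` (non-increasing),
#'   `iterations`, `converged`.
#' @export
fit_fused_lasso <- function(x_list, y_list, hyper = drmn_hyper(),
                            intercept = TRUE, tol = 1e-6, max_iter = 10000) {
  stopifnot(length(x_list) == length(y_list), length(x_list) >= 1)
  C <- length(x_list)
  p <- ncol(y_list[[which.max(vapply(y_list, NROW, integer(1)))]])
  if (is.null(p) || p == 0) stop_bad_arg("design matrices have zero features")
  xm <- numeric(C); ym <- vector("list", C)
  xt <- vector("list", C); yt <- vector("list", C)
  for (cc in seq_len(C)) {
    y <- as.matrix(y_list[[cc]]); x <- as.numeric(x_list[[cc]])
    if (NROW(y) != length(x)) stop_bad_arg("row mismatch at time %d", cc)
    if (NROW(y) > 0 && ncol(y) != p) stop_bad_arg("feature mismatch at time %d", cc)
    if (intercept && length(x)) {
      xm[cc] <- mean(x); ym[[cc]] <- colMeans(y)
      x <- x - xm[cc]; y <- sweep(y, 2, ym[[cc]])
    } else {
      ym[[cc]] <- rep(0, p)
    }
    xt[[cc]] <- x; yt[[cc]] <- y
  }
  G <- map(yt, crossprod)                      # p x p Gram per time
  H <- vapply(seq_len(C), function(cc) {
    if (length(xt[[cc]])) as.numeric(crossprod(yt[[cc]], xt[[cc]]))
    else numeric(p)
  }, numeric(p))
  H <- matrix(H, nrow = p)
  const <- sum(vapply(xt, function(x) sum(x^2), numeric(1)))
  lip <- 2 * max(c(1e-12, vapply(G, function(g) {
    if (all(g == 0)) 0 else max(eigen(g, symmetric = TRUE,
                                      only.values = TRUE)$values)
  }, numeric(1))))
  step <- 1 / lip

  fval <- function(th) {
    s <- 0
    for (cc in seq_len(C)) {
      s <- s + sum(th[, cc] * (G[[cc]] %*% th[, cc])) - 2 * sum(th[, cc] * H[, cc])
    }
    s + const
  }
  grad <- function(th) {
    g <- matrix(0, p, C)
    for (cc in seq_len(C)) g[, cc] <- 2 * (G[[cc]] %*% th[, cc] - H[, cc])
    g
  }
  pen <- function(th) {
    hyper$rho1 * sum(abs(th)) +
      hyper$rho2 * sum(abs(th[, -1, drop = FALSE] - th[, -C, drop = FALSE])) +
      hyper$rho3 * sum(sqrt(rowSums(th^2)))
  }
  prox <- function(v) {
    .prox_fused_rows_cpp(v, step * hyper$rho1, step * hyper$rho2,
                         step * hyper$rho3)
  }

  theta <- matrix(0, p, C)
  obj <- fval(theta) + pen(theta)
  trace <- obj
  extr <- theta
  tk <- 1
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    cand <- prox(extr - step * grad(extr))
    obj_cand <- fval(cand) + pen(cand)
    if (obj_cand > obj) {
      # momentum overshoot: fall back to the plain proximal-gradient step,
      # which cannot increase the objective at step 1/L, and restart
      cand <- prox(theta - step * grad(theta))
      obj_cand <- fval(cand) + pen(cand)
      tk <- 1
      extr <- cand
    } else {
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      extr <- cand + ((tk - 1) / tk_new) * (cand - theta)
      tk <- tk_new
    }
    if (obj_cand <= obj) {
      done <- abs(obj - obj_cand) <= tol * (1 + abs(obj_cand))
      theta <- cand
      obj <- obj_cand
      trace <- c(trace, obj)
      if (done) { converged <- TRUE; break }
    } else {
      trace <- c(trace, obj)
      # safeguarded step failed to improve: at the solution
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("fused-lasso solver hit max_iter = %d (last rel change %.2e)",
                 max_iter,
                 abs(diff(tail(trace, 2))) / (1 + abs(tail(trace, 1)))))
  }
  intercepts <- vapply(seq_len(C), function(cc) {
    xm[cc] - sum(ym[[cc]] * theta[, cc])
  }, numeric(1))
  rownames(theta) <- colnames(y_list[[which.max(vapply(y_list, NROW, integer(1)))]])
  list(theta = theta, intercepts = intercepts, objective = obj,
       obj_trace = trace, iterations = it, converged = converged)
}
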