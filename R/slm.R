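# Sparse Levenberg-Marquardt for structured nonlinear least squares.
#
# Bundle adjustment and regularized triangulation are both least-squares
# problems whose Jacobian is extremely sparse (each residual depends on
# one camera and/or a handful of 3D points). The engine below exploits
# that structure twice: the Jacobian is obtained by *colored* forward
# differences (parameters that share no residual are perturbed together,
# so a handful of residual evaluations yields the full Jacobian), and the
# normal equations are solved with Matrix's sparse Cholesky.

#' Solve a sparse nonlinear least-squares problem
#'
#' Minimizes `0.5 * sum(resid_fn(theta)^2)` by Levenberg-Marquardt. The
#' caller describes the Jacobian sparsity with `param_rows` (for each
#' parameter, the residual rows it influences) and `groups` (sets of
#' parameters with disjoint row sets, perturbed together when forming the
#' finite-difference Jacobian).
#'
#' @param theta Numeric start vector.
#' @param resid_fn Function `theta -> residual vector` (fixed length).
#' @param param_rows List (length `length(theta)`) of integer row indices.
#' @param groups List of integer parameter-index vectors covering all
#'   parameters; parameters within a group must not share residual rows.
#' @param max_iter Maximum accepted LM steps.
#' @param ftol Relative cost-decrease tolerance.
#' @param xtol Step-size tolerance (relative).
#' @param fd_step Relative forward-difference step.
#' @param verbose Print per-iteration cost.
#' @return List with `theta`, `residuals`, `cost`, `initial_cost`,
#'   `n_iter`, `converged`.
#' @export
slm_least_squares <- function(theta, resid_fn, param_rows, groups,
                              max_iter = 50L, ftol = 1e-8, xtol = 1e-10,
                              fd_step = 1e-6, verbose = FALSE) {
  theta <- as.numeric(theta)
  n <- length(theta)
  r <- resid_fn(theta)
  if (any(!is.finite(r))) abort("non-finite residuals at the starting point")
  m <- length(r)
  cost0 <- 0.5 * sum(r^2)
  cost <- cost0
  lambda <- 1e-4
  converged <- FALSE
  n_acc <- 0L

  jacobian <- function(th, r0) {
    ii <- vector("list", length(groups))
    jj <- vector("list", length(groups))
    xx <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      h <- fd_step * pmax(abs(th[idx]), 1)
      th2 <- th
      th2[idx] <- th2[idx] + h
      r2 <- resid_fn(th2)
      d <- r2 - r0
      rows_list <- param_rows[idx]
      lens <- lengths(rows_list)
      rows_g <- unlist(rows_list, use.names = FALSE)
      ii[[g]] <- rows_g
      jj[[g]] <- rep.int(idx, lens)
      xx[[g]] <- d[rows_g] / rep.int(h, lens)
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = c(m, n))
  }

  J <- jacobian(theta, r)
  for (iter in seq_len(max_iter * 4L)) {
    if (n_acc >= max_iter) break
    JtJ <- Matrix::crossprod(J)
    g <- as.numeric(Matrix::crossprod(J, r))
    if (max(abs(g)) < 1e-12) { converged <- TRUE; break }
    D <- Matrix::Diagonal(n, pmax(Matrix::diag(JtJ), 1e-10))
    step_ok <- FALSE
    for (tries in 1:8) {
      A <- JtJ + lambda * D
      delta <- tryCatch(as.numeric(Matrix::solve(A, -g)),
                        error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) {
        lambda <- lambda * 10
        next
      }
      theta_new <- theta + delta
      r_new <- resid_fn(theta_new)
      cost_new <- 0.5 * sum(r_new^2)
      if (is.finite(cost_new) && cost_new < cost) {
        rel <- (cost - cost_new) / max(cost, 1e-300)
        small_step <- max(abs(delta) / pmax(abs(theta), 1)) < xtol
        theta <- theta_new
        r <- r_new
        cost <- cost_new
        lambda <- max(lambda / 3, 1e-12)
        n_acc <- n_acc + 1L
        step_ok <- TRUE
        if (verbose) message(sprintf("  lm iter %d cost %.6g", n_acc, cost))
        if (rel < ftol || small_step) converged <- TRUE
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok || converged) {
      if (!step_ok) converged <- TRUE # stuck: accept current iterate
      break
    }
    J <- jacobian(theta, r)
  }

  list(theta = theta, residuals = r, cost = cost, initial_cost = cost0,
       n_iter = n_acc, converged = converged)
}

# Robust-norm residual transform (scipy-style, applied elementwise):
# returns r~ with sum(r~^2) = sum(rho(r^2)) for the chosen loss.
robustify_residuals <- function(r, loss = c("linear", "huber", "soft_l1"),
                                scale = 10) {
  loss <- match.arg(loss)
  if (loss == "linear") return(r)
  z <- (r / scale)^2
  rho <- switch(loss,
    huber = ifelse(z <= 1, z, 2 * sqrt(pmax(z, 1)) - 1),
    soft_l1 = 2 * (sqrt(1 + z) - 1)
  )
  sign(r) * scale * sqrt(rho)
}
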