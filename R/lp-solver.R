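# Dense two-phase simplex and branch-and-bound MILP.
#
# The constraint-based modelling layer (FBA, FVA-style consistency checks,
# INIT extraction) needs a linear-programming kernel with exact, deterministic
# behaviour at toy-model scale (tens of metabolites, ~100 columns). Problems
# are solved as   min/max c'v  s.t.  A v {<=,=,>=} rhs,  lb <= v <= ub,
# with all bounds finite.

SIMPLEX_TOL <- 1e-9

#' Solve a dense linear program
#'
#' Two-phase primal simplex on the full tableau. Variables are shifted to
#' zero lower bounds and finite upper bounds become explicit rows, so the
#' method is intended for small, fully bounded problems such as flux balance
#' analysis on toy networks.
#'
#' @param obj numeric objective coefficients (length n).
#' @param mat constraint matrix (m x n), dense or sparse.
#' @param dir character vector of constraint directions: `"<="`, `"="`, `">="`.
#' @param rhs numeric right-hand sides (length m).
#' @param lb,ub numeric variable bounds (finite; length n or scalar).
#' @param maximize logical; maximize (default) or minimize.
#' @param max_iter pivot limit before giving up with an error.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution on the original scale) and `objval`.
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb = 0, ub = Inf,
                     maximize = TRUE, max_iter = 100000L) {
  mat <- as.matrix(mat)
  n <- length(obj)
  m <- nrow(mat)
  stopifnot(ncol(mat) == n, length(rhs) == m, length(dir) == m)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(lb > ub + SIMPLEX_TOL)) return(list(status = "infeasible", x = NULL, objval = NA_real_))
  # work in minimization form on shifted variables x = v - lb
  cvec <- if (maximize) -as.numeric(obj) else as.numeric(obj)
  rhs2 <- as.numeric(rhs) - as.vector(mat %*% lb)
  dir2 <- dir
  # finite upper bounds become rows x_j <= ub_j - lb_j
  has_ub <- which(is.finite(ub))
  if (length(has_ub)) {
    ubrows <- matrix(0, length(has_ub), n)
    ubrows[cbind(seq_along(has_ub), has_ub)] <- 1
    mat2 <- rbind(mat, ubrows)
    rhs2 <- c(rhs2, ub[has_ub] - lb[has_ub])
    dir2 <- c(dir2, rep("<=", length(has_ub)))
  } else mat2 <- mat
  m2 <- nrow(mat2)
  # normalize rows to rhs >= 0
  neg <- rhs2 < 0
  if (any(neg)) {
    mat2[neg, ] <- -mat2[neg, , drop = FALSE]
    rhs2[neg] <- -rhs2[neg]
    dir2[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir2[neg]]
  }
  # slack / surplus / artificial bookkeeping
  n_slack <- sum(dir2 == "<=")
  n_surp <- sum(dir2 == ">=")
  n_art <- sum(dir2 != "<=")
  ncols <- n + n_slack + n_surp + n_art
  A <- matrix(0, m2, ncols)
  A[, seq_len(n)] <- mat2
  basis <- integer(m2)
  js <- n; jp <- n + n_slack; ja <- n + n_slack + n_surp
  for (i in seq_len(m2)) {
    if (dir2[i] == "<=") {
      js <- js + 1L; A[i, js] <- 1; basis[i] <- js
    } else if (dir2[i] == ">=") {
      jp <- jp + 1L; A[i, jp] <- -1
      ja <- ja + 1L; A[i, ja] <- 1; basis[i] <- ja
    } else {
      ja <- ja + 1L; A[i, ja] <- 1; basis[i] <- ja
    }
  }
  art_cols <- seq.int(n + n_slack + n_surp + 1L, length.out = n_art)
  A_full <- A
  rhs_full <- rhs2
  # One simplex phase with refactorization: after the compiled kernel reports
  # optimality, the basic solution is recomputed exactly from the original
  # data; if accumulated pivot error left the basis infeasible or the clean
  # tableau non-optimal, iteration continues from a refactored tableau.
  # `forbid` columns (artificials in phase 2) are excluded from pricing.
  phase_run <- function(Tab, basis, cvec, rows, bland, forbid = integer(),
                        K = 120L) {
    if (length(forbid)) Tab[, forbid] <- 0
    budget <- max_iter
    prev_obj <- NA_real_; stalls <- 0L
    repeat {
      res <- simplex_iterate(Tab, basis, cvec, min(K, budget), bland)
      budget <- budget - K
      if (res$status == "unbounded") return(res)
      basis <- res$basis
      B <- A_full[rows, basis, drop = FALSE]
      xb <- tryCatch(solve(B, rhs_full[rows]), error = function(e) NULL)
      feas_tol <- 1e-6 * max(1, max(abs(rhs_full)))
      if (is.null(xb) || min(xb) < -feas_tol) return("breakdown")
      xb <- pmax(xb, 0)
      if (res$status == "optimal") {
        yv <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
        if (is.null(yv)) return("breakdown")
        rc <- cvec - as.vector(crossprod(A_full[rows, , drop = FALSE], yv))
        rc[c(basis, forbid)] <- 0
        opt_tol <- 1e-7 * max(1, max(abs(cvec)), max(abs(yv)))
        if (min(rc) >= -opt_tol)
          return(list(status = "optimal", basis = basis, xb = xb,
                      objval = sum(cvec[basis] * xb)))
      }
      if (budget <= 0) stop("simplex iteration limit reached")
      # anti-cycling: persistent stalling switches to Bland's rule
      if (!is.na(prev_obj) && abs(res$objval - prev_obj) < 1e-12) {
        stalls <- stalls + 1L
        if (stalls >= 5L) bland <- TRUE
      } else stalls <- 0L
      prev_obj <- res$objval
      # refactor the tableau from the original data and keep iterating
      Tb <- tryCatch(solve(B, A_full[rows, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(Tb)) return("breakdown")
      Tab <- cbind(Tb, xb)
      if (length(forbid)) Tab[, forbid] <- 0
    }
  }
  run_phases <- function(bland_start, K = 120L) {
    rows <- seq_len(m2)
    basis_l <- basis
    Tab <- cbind(A, rhs2)
    forbid2 <- integer()
    if (n_art > 0) {
      c1 <- c(rep(0, ncols - n_art), rep(1, n_art))
      res <- phase_run(Tab, basis_l, c1, rows, bland_start, K = K)
      if (identical(res, "breakdown")) return(res)
      if (res$status == "unbounded") return("breakdown")  # phase 1 is bounded
      if (res$objval > 1e-7)
        return(list(status = "infeasible", x = NULL, objval = NA_real_))
      basis_l <- res$basis
      # artificials still basic sit in redundant rows: pivot them out where
      # possible (on a clean refactored tableau), else drop their rows
      stuck_art <- which(basis_l %in% art_cols)
      if (length(stuck_art)) {
        B <- A_full[rows, basis_l, drop = FALSE]
        Tb <- tryCatch(solve(B, A_full[rows, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(Tb)) return("breakdown")
        for (i in stuck_art) {
          p <- setdiff(which(abs(Tb[i, ]) > 1e-7), art_cols)
          if (length(p)) {
            Tb <- simplex_pivot(cbind(Tb, 0), i, p[1])[, -(ncols + 1), drop = FALSE]
            basis_l[i] <- p[1]
          }
        }
        stuck_art <- which(basis_l %in% art_cols)
        if (length(stuck_art)) {
          rows <- rows[-stuck_art]
          basis_l <- basis_l[-stuck_art]
        }
      }
      B <- A_full[rows, basis_l, drop = FALSE]
      xb <- tryCatch(solve(B, rhs_full[rows]), error = function(e) NULL)
      Tb <- tryCatch(solve(B, A_full[rows, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(xb) || is.null(Tb)) return("breakdown")
      Tab <- cbind(Tb, pmax(xb, 0))
      forbid2 <- art_cols
    }
    c2 <- c(cvec, rep(0, ncols - n))
    res <- phase_run(Tab, basis_l, c2, rows, bland_start, forbid = forbid2,
                     K = K)
    if (identical(res, "breakdown")) return(res)
    if (res$status == "unbounded")
      return(list(status = "unbounded", x = NULL, objval = NA_real_))
    xfull <- numeric(ncols)
    xfull[res$basis] <- res$xb
    x <- xfull[seq_len(n)] + lb
    list(status = "optimal", x = x, objval = sum(obj * x))
  }
  # retry ladder: default; short refactorization interval; Bland's rule
  out <- run_phases(FALSE, 120L)
  if (identical(out, "breakdown")) out <- run_phases(FALSE, 25L)
  if (identical(out, "breakdown")) out <- run_phases(TRUE, 25L)
  if (identical(out, "breakdown"))
    stop("simplex lost primal feasibility (numerical breakdown)")
  out
}

# One simplex phase: minimize cvec'x from a feasible basis. Dantzig rule with
# Bland fallback for anti-cycling; the inner loop is compiled (src/simplex.cpp).
simplex_iterate <- function(Tab, basis, cvec, max_iter, bland_start = FALSE) {
  .simplex_phase_cpp(Tab, as.integer(basis), as.numeric(cvec),
                     as.integer(max_iter), as.integer(bland_start))
}

simplex_pivot <- function(Tab, r, p) {
  piv <- Tab[r, p]
  Tab[r, ] <- Tab[r, ] / piv
  col <- Tab[, p]
  col[r] <- 0
  Tab <- Tab - outer(col, Tab[r, ])
  Tab[, p] <- 0
  Tab[r, p] <- 1
  Tab
}

#' Solve a mixed binary-integer linear program by branch and bound
#'
#' Depth-first branch and bound over binary variables on top of [solve_lp()].
#' Fully deterministic: branching selects the fractional binary with the
#' largest absolute objective coefficient (ties to the lowest index) and
#' explores the branch nearest the relaxation value first.
#'
#' Zero-objective binaries (e.g. inclusion indicators of reactions without
#' expression evidence in the INIT formulation) are handled by an exact repair
#' step: at a node whose only fractional binaries carry zero cost, they are
#' fixed to 1 (or 0) and the fix is accepted only if a feasibility re-solve
#' preserves the node bound; otherwise the variable is branched normally.
#'
#' @inheritParams solve_lp
#' @param binary integer indices of binary variables.
#' @param node_limit maximum branch-and-bound nodes.
#' @return list with `status`, `x`, `objval`, `nodes` (nodes explored) and
#'   `gap` (absolute bound gap at termination, 0 when proven optimal).
#' @export
solve_milp <- function(obj, mat, dir, rhs, lb = 0, ub = Inf, binary = integer(),
                       maximize = TRUE, node_limit = 200000L) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  binary <- as.integer(binary)
  lb[binary] <- pmax(lb[binary], 0)
  ub[binary] <- pmin(ub[binary], 1)
  sgn <- if (maximize) 1 else -1
  best <- list(objval = -Inf, x = NULL)
  nodes <- 0L
  itol <- 1e-7
  # LIFO stack of nodes: each holds bound overrides for binaries
  stack <- list(list(lb = lb, ub = ub))
  root_bound <- NA_real_
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit)
      return(list(status = "node_limit", x = best$x,
                  objval = sgn * best$objval, nodes = nodes,
                  gap = if (is.na(root_bound)) Inf else root_bound - best$objval))
    rel <- solve_lp(sgn * obj, mat, dir, rhs, node$lb, node$ub, maximize = TRUE)
    if (rel$status != "optimal") next
    if (nodes == 1L) root_bound <- rel$objval
    if (rel$objval <= best$objval + 1e-9) next
    y <- rel$x[binary]
    frac <- which(y > itol & y < 1 - itol)
    if (nodes == 1L && length(frac)) {
      # rounding heuristic: fixing all fractional binaries up (then down)
      # often yields a strong incumbent before any branching
      for (val in c(1, 0)) {
        lbh <- node$lb; ubh <- node$ub
        j <- binary[frac]
        if (val == 1) lbh[j] <- 1 else ubh[j] <- 0
        h <- solve_lp(sgn * obj, mat, dir, rhs, lbh, ubh, maximize = TRUE)
        if (h$status == "optimal") {
          yh <- h$x[binary]
          if (all(yh < itol | yh > 1 - itol) && h$objval > best$objval + 1e-9) {
            xh <- h$x; xh[binary] <- round(yh)
            best <- list(objval = h$objval, x = xh)
          }
        }
      }
      if (rel$objval <= best$objval + 1e-9) next
    }
    if (length(frac)) {
      coefs <- abs(obj[binary][frac])
      nzf <- frac[coefs > 1e-12]
      if (!length(nzf)) {
        # all fractional binaries are cost-free: try exact repair
        rep_res <- milp_zero_repair(obj * sgn, mat, dir, rhs, node, binary, frac,
                                    y, rel$objval)
        if (rep_res$ok) {
          if (rep_res$objval > best$objval + 1e-9)
            best <- list(objval = rep_res$objval, x = rep_res$x)
          next
        }
        bvar <- rep_res$branch_var
      } else {
        bvar <- nzf[which.max(abs(obj[binary][nzf]))]
      }
      j <- binary[bvar]
      lo <- node; hi <- node
      lo$ub[j] <- 0; hi$lb[j] <- 1
      # explore the up child first: in indicator-coupled problems (INIT) the
      # connectivity-preserving branch reaches strong incumbents quickly
      stack <- c(stack, list(lo), list(hi))
      next
    }
    # integral solution
    if (rel$objval > best$objval + 1e-9) {
      x <- rel$x
      x[binary] <- round(x[binary])
      best <- list(objval = rel$objval, x = x)
    }
  }
  if (is.null(best$x))
    return(list(status = "infeasible", x = NULL, objval = NA_real_,
                nodes = nodes, gap = NA_real_))
  list(status = "optimal", x = best$x, objval = sgn * best$objval,
       nodes = nodes, gap = 0)
}

# Repair a relaxation whose fractional binaries all have zero objective
# weight. Iteratively: try the all-at-once fix to 1 first; then, while any
# binary is fractional, fix zero-cost ones (to 1 if the bound survives, else
# to 0) and re-solve. Feasibility with an unchanged objective proves the
# completion optimal for this node; a fractional nonzero-cost binary (or an
# unfixable zero-cost one) is handed back for ordinary branching.
milp_zero_repair <- function(obj_max, mat, dir, rhs, node, binary, frac, y, bound) {
  lb <- node$lb; ub <- node$ub
  itol <- 1e-7
  accept <- function(rel) {
    yfin <- rel$x[binary]
    if (any(yfin > itol & yfin < 1 - itol)) return(NULL)
    x <- rel$x; x[binary] <- round(yfin)
    list(ok = TRUE, objval = rel$objval, x = x)
  }
  lb1 <- lb; lb1[binary[frac]] <- 1
  rel <- solve_lp(obj_max, mat, dir, rhs, lb1, ub, maximize = TRUE)
  if (rel$status == "optimal" && rel$objval >= bound - 1e-7) {
    res <- accept(rel)
    if (!is.null(res)) return(res)
  }
  rel <- solve_lp(obj_max, mat, dir, rhs, lb, ub, maximize = TRUE)
  for (pass in seq_len(length(binary) + 1L)) {
    if (rel$status != "optimal" || rel$objval < bound - 1e-7)
      return(list(ok = FALSE, branch_var = frac[1]))
    yv <- rel$x[binary]
    fr <- which(yv > itol & yv < 1 - itol)
    if (!length(fr)) {
      x <- rel$x; x[binary] <- round(yv)
      return(list(ok = TRUE, objval = rel$objval, x = x))
    }
    if (any(abs(obj_max[binary][fr]) > 1e-12))
      return(list(ok = FALSE,
                  branch_var = fr[which.max(abs(obj_max[binary][fr]))]))
    j <- binary[fr[1]]
    lb_try <- lb; lb_try[j] <- 1
    r1 <- solve_lp(obj_max, mat, dir, rhs, lb_try, ub, maximize = TRUE)
    if (r1$status == "optimal" && r1$objval >= bound - 1e-7) {
      lb <- lb_try; rel <- r1; next
    }
    ub_try <- ub; ub_try[j] <- 0
    r0 <- solve_lp(obj_max, mat, dir, rhs, lb, ub_try, maximize = TRUE)
    if (r0$status == "optimal" && r0$objval >= bound - 1e-7) {
      ub <- ub_try; rel <- r0; next
    }
    return(list(ok = FALSE, branch_var = fr[1]))
  }
  list(ok = FALSE, branch_var = frac[1])
}
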