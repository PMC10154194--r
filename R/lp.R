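## Dense two-phase primal simplex for the moderate LPs assembled by
## build_problem() (a few hundred variables and constraints). Entirely
## deterministic. Numerical safeguards, all standard: row/column
## equilibration, lexicographic ratio-test tie-breaking (anti-cycling),
## periodic exact refactorization of the tableau, exact reduced-cost
## verification of the final basis, and a retry ladder (more frequent
## refactorization, then Bland pricing) when verification fails.

#' Solve a linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A x (dir) rhs`, `x >= 0`,
#' with `dir` in `{"<=", ">=", "="}` per row. Two-phase tableau simplex with
#' equilibration and exact basis verification; intended for the problem
#' sizes this package builds.
#'
#' @param obj objective coefficients (length n)
#' @param A dense constraint matrix (m x n)
#' @param dir character vector of row directions
#' @param rhs right-hand sides (length m)
#' @param maximize maximize instead of minimize
#' @param tol reduced-cost tolerance on the equilibrated problem
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (the structural solution), and `objective`
#' @export
simplex_lp <- function(obj, A, dir, rhs, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m)
  obj <- as.numeric(obj); rhs <- as.numeric(rhs)
  if (maximize) obj <- -obj

  ## equilibrate coefficients (variables and rows in natural units can
  ## differ by many orders of magnitude): alternate row and column
  ## scaling by the max |coefficient|, never folding the rhs into the
  ## scale. The solution is unscaled on return.
  col_scale <- rep(1, n)
  for (pass in 1:2) {
    rs <- apply(abs(A), 1, max)
    rs[rs < 1e-12] <- 1
    A <- A / rs; rhs <- rhs / rs
    cs <- apply(abs(A), 2, max)
    cs[cs < 1e-12] <- 1
    A <- sweep(A, 2, cs, "/")
    obj <- obj / cs
    col_scale <- col_scale * cs
  }
  for (i in seq_len(m)) {
    if (rhs[i] < 0) {
      A[i, ] <- -A[i, ]; rhs[i] <- -rhs[i]
      dir[i] <- switch(dir[i], "<=" = ">=", ">=" = "<=", "=" = "=")
    }
    if (dir[i] == ">=" && rhs[i] == 0) {
      ## homogeneous >= rows are <= rows in disguise; writing them that
      ## way gives them a slack basis and keeps phase 1 small
      A[i, ] <- -A[i, ]; dir[i] <- "<="
    }
  }
  rhs_scale <- max(abs(rhs), 1)

  n_le <- sum(dir == "<="); n_ge <- sum(dir == ">=")
  n_art <- sum(dir %in% c(">=", "="))
  ncols <- n + n_le + n_ge + n_art

  build_start <- function() {
    T_ <- matrix(0, m, ncols + 1)
    T_[, seq_len(n)] <- A
    T_[, ncols + 1] <- rhs
    basis <- integer(m); id_cols <- integer(m)
    slack_j <- n; art_j <- n + n_le + n_ge
    art_cols <- integer(0)
    for (i in seq_len(m)) {
      if (dir[i] == "<=") {
        slack_j <- slack_j + 1
        T_[i, slack_j] <- 1
        basis[i] <- slack_j
      } else {
        if (dir[i] == ">=") {
          slack_j <- slack_j + 1
          T_[i, slack_j] <- -1
        }
        art_j <- art_j + 1
        T_[i, art_j] <- 1
        basis[i] <- art_j
        art_cols <- c(art_cols, art_j)
      }
      id_cols[i] <- basis[i]
    }
    list(T_ = T_, basis = basis, id_cols = id_cols, art_cols = art_cols)
  }

  st0 <- build_start()
  A_ext <- st0$T_[, seq_len(ncols), drop = FALSE]  # pristine columns

  ## rebuild the tableau exactly for a given basis (kills pivot roundoff)
  refactor <- function(basis, keep_rows) {
    B <- A_ext[keep_rows, basis, drop = FALSE]
    out <- tryCatch(solve(B, cbind(A_ext[keep_rows, , drop = FALSE],
                                   rhs[keep_rows])),
                    error = function(e) NULL)
    if (!is.null(out)) {
      b <- out[, ncols + 1]
      b[b > -1e-6 * rhs_scale & b < 0] <- 0
      if (any(b < 0)) return(NULL)  # basis clearly primal infeasible
      out[, ncols + 1] <- b
    }
    out
  }

  run_phase <- function(T_, basis, cost, allowed, id_cols, keep_rows,
                        enter_tol, refactor_every, bland) {
    mm <- nrow(T_)
    z <- cost[basis] %*% T_[, seq_len(ncols), drop = FALSE] - cost
    it <- 0
    max_it <- 500L * (mm + 50L)
    repeat {
      it <- it + 1
      if (it > max_it) stop_cf("simplex iteration limit reached")
      if (it %% refactor_every == 0) {
        Tr <- refactor(basis, keep_rows)
        if (!is.null(Tr)) T_ <- Tr
        z <- cost[basis] %*% T_[, seq_len(ncols), drop = FALSE] - cost
      }
      cand <- which(allowed & z > enter_tol)
      if (length(cand) == 0)
        return(list(T_ = T_, basis = basis, status = "optimal"))
      q <- if (bland) cand[1] else cand[which.max(z[cand])]
      col <- T_[, q]
      pos <- which(col > 1e-9)
      if (length(pos) == 0)
        return(list(T_ = T_, basis = basis, status = "unbounded",
                    entering = q))
      ratio <- T_[pos, ncols + 1] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + 1e-9 * (1 + abs(rmin))]
      r <- if (length(ties) == 1) ties else {
        ## lexicographic tie-break over B^-1 rows scaled by the pivot
        left <- ties
        for (jc in id_cols) {
          vals <- T_[left, jc] / col[left]
          vmin <- min(vals)
          left <- left[vals <= vmin + 1e-12 * (1 + abs(vmin))]
          if (length(left) == 1) break
        }
        left[which.min(basis[left])]
      }
      piv <- T_[r, q]
      T_[r, ] <- T_[r, ] / piv
      upd <- which(abs(T_[, q]) > 0 & seq_len(mm) != r)
      if (length(upd) > 0)
        T_[upd, ] <- T_[upd, ] - outer(T_[upd, q], T_[r, ])
      z <- z - z[q] * T_[r, seq_len(ncols)]
      basis[r] <- q
    }
  }

  ## run a phase to completion: after the working tableau reports
  ## optimality, refactorize exactly and keep pivoting with a shrinking
  ## entering tolerance until exact reduced costs certify the optimum
  run_verified <- function(T_, basis, cost, allowed, id_cols, keep_rows,
                           refactor_every, bland) {
    verify_tol <- 1e-12
    ph <- NULL
    for (round in 1:10) {
      et <- max(tol / 100^(round - 1), verify_tol)
      ph <- run_phase(T_, basis, cost, allowed, id_cols, keep_rows,
                      enter_tol = et, refactor_every = refactor_every,
                      bland = bland)
      if (ph$status != "optimal") { ph$verified <- FALSE; return(ph) }
      T_ <- ph$T_; basis <- ph$basis
      Tr <- refactor(basis, keep_rows)
      if (is.null(Tr)) { ph$verified <- FALSE; return(ph) }
      T_ <- Tr
      z <- as.numeric(cost[basis] %*% T_[, seq_len(ncols), drop = FALSE]) -
        cost
      z[basis] <- 0
      if (max(z[allowed]) <= verify_tol)
        return(list(T_ = T_, basis = basis, status = "optimal",
                    objective = as.numeric(cost[basis] %*% T_[, ncols + 1]),
                    verified = TRUE))
    }
    ph$verified <- FALSE
    ph
  }

  solve_once <- function(refactor_every, bland) {
    st <- build_start()
    T_ <- st$T_; basis <- st$basis; id_cols <- st$id_cols
    art_cols <- st$art_cols
    keep_rows <- seq_len(m)
    if (n_art > 0) {
      cost1 <- numeric(ncols); cost1[art_cols] <- 1
      ph1 <- run_verified(T_, basis, cost1, rep(TRUE, ncols), id_cols,
                          keep_rows, refactor_every, bland)
      if (ph1$status != "optimal")
        return(list(outcome = "infeasible", residual = NA_real_))
      obj1 <- as.numeric(cost1[ph1$basis] %*% ph1$T_[, ncols + 1])
      if (obj1 > 1e-7 * rhs_scale)
        return(list(outcome = "infeasible", residual = obj1,
                    verified = isTRUE(ph1$verified)))
      T_ <- ph1$T_; basis <- ph1$basis
      ## drive leftover basic artificials out or drop redundant rows
      keep <- rep(TRUE, nrow(T_))
      for (i in seq_len(nrow(T_))) {
        if (basis[i] %in% art_cols) {
          j <- which(abs(T_[i, seq_len(n + n_le + n_ge)]) > 1e-9)
          if (length(j) > 0) {
            q <- j[1]; piv <- T_[i, q]
            T_[i, ] <- T_[i, ] / piv
            upd <- which(abs(T_[, q]) > 0 & seq_len(nrow(T_)) != i)
            if (length(upd) > 0)
              T_[upd, ] <- T_[upd, ] - outer(T_[upd, q], T_[i, ])
            basis[i] <- q
          } else keep[i] <- FALSE
        }
      }
      if (!all(keep)) {
        T_ <- T_[keep, , drop = FALSE]
        basis <- basis[keep]
        id_cols <- id_cols[keep]
        keep_rows <- keep_rows[keep]
      }
    }
    cost2 <- numeric(ncols)
    cost2[seq_len(n)] <- obj
    allowed2 <- rep(TRUE, ncols)
    allowed2[art_cols] <- FALSE
    ph2 <- run_verified(T_, basis, cost2, allowed2, id_cols, keep_rows,
                        refactor_every, bland)
    if (ph2$status == "unbounded")
      return(list(outcome = "unbounded", entering = ph2$entering))
    list(outcome = "optimal", T_ = ph2$T_, basis = ph2$basis,
         keep_rows = keep_rows, verified = isTRUE(ph2$verified))
  }

  ## retry ladder: only accept an unverified solve as a last resort;
  ## a strategy that stalls out (iteration limit) falls through to the next
  strategies <- list(c(300, FALSE), c(50, FALSE), c(25, TRUE))
  res <- NULL
  for (si in seq_along(strategies)) {
    s <- strategies[[si]]
    res <- tryCatch(solve_once(refactor_every = s[1], bland = as.logical(s[2])),
                    error = function(e) {
                      if (si == length(strategies)) stop(e)
                      list(outcome = "error",
                           message = conditionMessage(e))
                    })
    if (res$outcome == "error") next
    if (res$outcome == "unbounded")
      return(list(status = "unbounded", x = NULL, objective = NA_real_,
                  unbounded_col = res$entering))
    if (res$outcome == "infeasible" && isTRUE(res$verified))
      return(list(status = "infeasible", x = NULL, objective = NA_real_,
                  phase1_residual = res$residual))
    if (res$outcome == "optimal" && isTRUE(res$verified)) break
  }
  if (res$outcome == "infeasible")
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                phase1_residual = res$residual))

  ## final refinement: recompute the basic solution exactly
  x <- numeric(ncols)
  B <- A_ext[res$keep_rows, res$basis, drop = FALSE]
  xb <- tryCatch(solve(B, rhs[res$keep_rows]), error = function(e) NULL)
  if (is.null(xb)) x[res$basis] <- res$T_[, ncols + 1] else x[res$basis] <- xb
  xs <- pmax(x[seq_len(n)], 0) / col_scale
  objective <- sum(obj * col_scale * xs)
  list(status = "optimal", x = xs,
       objective = if (maximize) -objective else objective)
}
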