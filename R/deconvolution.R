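#' Estimate blood cell-subset proportions from methylation
#'
#' Reference-based deconvolution: for each sample, the vector of beta values
#' at the reference's discriminating probes is projected onto the reference
#' profiles by least squares under the constraints that every proportion is
#' non-negative and the proportions sum to at most one. The solution is the
#' exact constrained optimum (active-set quadratic programming), so the
#' estimates are deterministic and interpretable as fractions.
#'
#' @param betas Samples-by-probes beta matrix.
#' @param ref Probes-by-cell-types reference matrix, e.g. from
#'   [load_reference_profiles()].
#' @return A data frame with `sample_id`, one column of proportions per cell
#'   type, and `residual_norm` (Euclidean norm of the fit residual).
#' @export
estimate_cell_proportions <- function(betas, ref) {
  validate_beta_matrix(betas)
  common <- intersect(colnames(betas), rownames(ref))
  if (length(common) < 10)
    stop(sprintf(paste0("only %d probes overlap between the beta matrix and ",
                        "the reference; at least 10 are required"),
                 length(common)))
  R <- ref[common, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    cc <- cor(R)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
    stop(sprintf("reference is rank-deficient; cell types %s and %s are collinear",
                 colnames(R)[worst[1L]], colnames(R)[worst[2L]]))
  }
  out <- matrix(NA_real_, nrow(betas), ncol(R),
                dimnames = list(rownames(betas), colnames(R)))
  resid <- numeric(nrow(betas))
  Y <- betas[, common, drop = FALSE]
  # fast path: the unconstrained least-squares solution is the constrained
  # optimum whenever it is already feasible (w >= 0, sum <= 1); solve it for
  # all complete samples in one pass and fall back to the active-set solver
  # only where a constraint binds or values are missing
  complete <- !apply(is.na(Y), 1, any)
  done <- rep(FALSE, nrow(Y))
  if (any(complete)) {
    Wu <- t(solve(crossprod(R), crossprod(R, t(Y[complete, , drop = FALSE]))))
    feas <- apply(Wu, 1, function(w) all(w >= 0) && sum(w) <= 1 + 1e-10)
    idx <- which(complete)[feas]
    out[idx, ] <- Wu[feas, , drop = FALSE]
    done[idx] <- TRUE
  }
  for (i in which(!done)) {
    y <- Y[i, ]
    keep <- !is.na(y)
    if (sum(keep) < 10)
      stop("sample ", rownames(betas)[i],
           " has fewer than 10 non-missing reference probes")
    out[i, ] <- solve_simplex_ls(R[keep, , drop = FALSE], y[keep])
  }
  for (i in seq_len(nrow(Y))) {
    keep <- !is.na(Y[i, ])
    resid[i] <- sqrt(sum((R[keep, , drop = FALSE] %*% out[i, ] - Y[i, keep])^2))
  }
  df <- data.frame(sample_id = rownames(betas), out, resid,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   row.names = NULL)
  names(df) <- c("sample_id", colnames(R), "residual_norm")
  df
}

# Least squares min ||R w - y||^2 subject to w >= 0 and sum(w) <= 1.
# Stage 1: plain non-negative least squares (Lawson-Hanson). If its solution
# already satisfies the sum constraint it is the global constrained optimum.
# Stage 2 (sum constraint active): active-set iteration on the equality-
# constrained problem sum(w) = 1, w >= 0, solving the KKT system on the free
# set and exchanging bound variables until the KKT conditions hold.
solve_simplex_ls <- function(R, y, tol = 1e-10) {
  K <- ncol(R)
  w <- pracma::lsqnonneg(R, y)$x
  if (sum(w) <= 1 + tol) return(pmax(w, 0))

  A <- crossprod(R)          # K x K
  b <- drop(crossprod(R, y))
  free <- rep(TRUE, K)
  for (iter in seq_len(100 * K)) {
    f <- which(free)
    kkt <- rbind(cbind(2 * A[f, f, drop = FALSE], 1),
                 c(rep(1, length(f)), 0))
    rhs <- c(2 * b[f], 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) { # degenerate face: drop to pseudo-inverse
      sol <- drop(pracma::pinv(kkt) %*% rhs)
    }
    w_f <- sol[seq_along(f)]
    lambda <- sol[length(sol)]
    if (any(w_f < -tol)) {
      free[f[which.min(w_f)]] <- FALSE
      if (!any(free)) stop("simplex least-squares failed: empty free set")
      next
    }
    w <- rep(0, K)
    w[f] <- pmax(w_f, 0)
    # KKT multiplier check for variables at their bound
    g <- 2 * (A %*% w - b) + lambda
    bound <- which(!free)
    viol <- bound[g[bound] < -tol]
    if (length(viol) == 0) break
    free[viol[which.min(g[viol])]] <- TRUE
  }
  w <- pmax(w, 0)
  if (sum(w) > 1) w <- w / sum(w)
  w
}

#' Compare estimated cell proportions between gout cases and controls
#'
#' Per cell type, a rank-based two-group location test (Wilcoxon rank-sum)
#' of the estimated proportions between gout cases and non-gout controls.
#'
#' @param props Data frame from [estimate_cell_proportions()].
#' @param samples Sample table with `sample_id` and a 0/1 `gout` column.
#' @return A data frame with `cell_type`, `statistic`, `p`, and group medians.
#' @export
compare_proportions <- function(props, samples) {
  m <- merge(props, samples[, c("sample_id", "gout")], by = "sample_id")
  if (!all(c(0, 1) %in% m$gout))
    stop("both gout classes must be present to compare proportions")
  cell_types <- setdiff(names(props), c("sample_id", "residual_norm"))
  rows <- lapply(cell_types, function(ct) {
    wt <- suppressWarnings(wilcox.test(m[[ct]][m$gout == 1],
                                       m[[ct]][m$gout == 0], exact = FALSE))
    data.frame(cell_type = ct, statistic = unname(wt$statistic),
               p = wt$p.value,
               median_gout = stats::median(m[[ct]][m$gout == 1]),
               median_control = stats::median(m[[ct]][m$gout == 0]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
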