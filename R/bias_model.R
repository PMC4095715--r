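#' Binary differential labels on the network node set
#'
#' @param net A `metabolite_network`.
#' @param interesting Character vector of interesting (e.g. differential)
#'   metabolite IDs; entries absent from the network are ignored with a
#'   logged count.
#' @return Named integer vector over `net$nodes`: 1 for interesting
#'   metabolites, 0 otherwise.
#' @export
make_labels <- function(net, interesting) {
  ids <- unique(canonicalize_cid(interesting))
  hit <- ids %in% net$nodes
  if (!any(hit)) stop("no interesting metabolites in network")
  if (any(!hit)) {
    mpinet_log(sum(!hit), " interesting metabolite(s) not in network")
  }
  y <- as.integer(net$nodes %in% ids)
  names(y) <- net$nodes
  y
}

#' Cubic regression spline basis on GN scores
#'
#' Builds a cubic regression spline basis whose knots sit at the
#' equally-spaced quantiles (linear-interpolation type) of the GN-score
#' distribution. The basis parameterizes the function by its values at the
#' knots with natural boundary conditions (mgcv's `"cr"` construction), so
#' it spans constants, and carries the integrated squared second derivative
#' as its curvature penalty.
#'
#' @param gn Named numeric vector of GN scores ([compute_gn()]).
#' @param k Number of knots (default 6). Duplicate quantile knots are
#'   collapsed with a warning and `k` reduced; fewer than 3 distinct knots
#'   is an error.
#' @return A `spline_basis`: list with the mgcv smooth object, `knots`,
#'   `k`, model matrix `X` (rows aligned to `names(gn)`), penalty `S`, and
#'   the covariate `x = gn`.
#' @export
build_basis <- function(gn, k = 6) {
  x <- unname(gn)
  if (length(unique(x)) < 2) stop("GN scores are constant: degenerate covariate")
  kn <- unname(stats::quantile(x, probs = seq(0, 1, length.out = k), type = 7))
  kn_u <- unique(kn)
  if (length(kn_u) < length(kn)) {
    warning("collapsed ", length(kn) - length(kn_u),
            " duplicate quantile knot(s); k reduced to ", length(kn_u))
  }
  if (length(kn_u) < 3) stop("fewer than 3 distinct knots: need more spread in GN")
  if (length(unique(x)) < length(kn_u)) {
    stop("need at least k distinct GN values")
  }
  k <- length(kn_u)
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"),
                        data = data.frame(x = x),
                        knots = list(x = kn_u),
                        absorb.cons = FALSE)[[1L]]
  structure(list(smooth = sm, knots = kn_u, k = k,
                 X = sm$X, S = sm$S[[1L]], x = gn),
            class = "spline_basis")
}

#' Evaluate the spline basis at new covariate values
#' @keywords internal
basis_matrix <- function(basis, x) {
  mgcv::PredictMat(basis$smooth, data.frame(x = x))
}

#' Fit the monotone penalized spline linking GN score to selection
#'
#' Estimates the probability that a metabolite is reported as
#' interesting/differential as a monotone nondecreasing function of its GN
#' score, by penalized constrained least squares: minimize
#' \deqn{\|Y - X\beta\|^2 + \lambda \beta^T S \beta}
#' subject to linear inequality constraints that force the fitted curve to
#' be nondecreasing at every first difference of a fine evaluation grid
#' over the GN range. The quadratic program is solved with
#' [mgcv::pcls()]. Fitted probabilities are clamped into \[0, 1\] and the
#' combined global nonequivalence and bias score is `C = 1 - fitted`.
#'
#' @param basis A `spline_basis` built on `gn` via [build_basis()].
#' @param gn Named numeric GN-score vector (same table the basis was built
#'   on).
#' @param labels Named binary vector from [make_labels()].
#' @param lambda Either `"gcv"` (default: generalized cross-validation over
#'   a 40-point logarithmic grid, with effective degrees of freedom taken
#'   from the unconstrained penalized hat matrix) or a fixed nonnegative
#'   value.
#' @param grid_points Size of the monotonicity-constraint grid (>= 200).
#' @return A `bias_fit`: list with `beta`, `lambda`, `penalty`, `fitted`
#'   (named, clamped), `cgnb` (`1 - fitted`), `residuals`, `basis`, and
#'   `grid` (data.frame of the constraint grid and the unclamped curve).
#' @export
fit_monotone_spline <- function(basis, gn, labels, lambda = "gcv",
                                grid_points = 200) {
  stopifnot(inherits(basis, "spline_basis"))
  if (!identical(names(basis$x), names(gn))) {
    stop("basis was not built on this GN table")
  }
  y <- as.numeric(labels[names(gn)])
  if (anyNA(y)) stop("labels missing for some network metabolites")
  X <- basis$X
  S <- basis$S
  n <- nrow(X); k <- ncol(X)
  if (n < k) stop("fewer observations than spline coefficients")
  grid_points <- max(200L, as.integer(grid_points))
  grid <- seq(min(gn), max(gn), length.out = grid_points)
  Xg <- basis_matrix(basis, grid)
  Ain <- diff(diag(grid_points)) %*% Xg
  # strictly feasible start: knot values collinear in knot position give a
  # strictly increasing straight line under the natural-spline interpolant
  kn <- basis$knots
  p0 <- mean(y) + 1e-3 * (kn - mean(kn)) / diff(range(kn))
  solve_lam <- function(lam) {
    M <- list(y = y, w = rep(1, n), X = X, C = matrix(0, 0, 0),
              S = list(S), off = 0, sp = lam, p = p0,
              Ain = Ain, bin = rep(0, nrow(Ain)))
    mgcv::pcls(M)
  }
  if (identical(lambda, "gcv")) {
    XtX <- crossprod(X)
    scale <- sum(diag(XtX)) / max(sum(diag(S)), .Machine$double.eps)
    lams <- scale * 10^seq(-8, 5, length.out = 40)
    gcv <- vapply(lams, function(l) {
      b <- solve_lam(l)
      rss <- sum((y - X %*% b)^2)
      edf <- sum(diag(solve(XtX + l * S, XtX)))
      n * rss / (n - edf)^2
    }, 0)
    lambda <- lams[which.min(gcv)]
  } else {
    lambda <- as.numeric(lambda)
    if (is.na(lambda) || lambda < 0) stop("lambda must be 'gcv' or >= 0")
  }
  beta <- solve_lam(lambda)
  raw <- drop(X %*% beta)
  fitted <- pmin(pmax(raw, 0), 1)
  names(fitted) <- names(gn)
  structure(list(beta = beta, lambda = lambda, penalty = S,
                 fitted = fitted, cgnb = 1 - fitted,
                 residuals = y - fitted, basis = basis,
                 grid = data.frame(gn = grid,
                                   yhat = drop(Xg %*% beta))),
            class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat("bias_fit: monotone spline on", length(x$fitted), "metabolites,",
      "k =", x$basis$k, ", lambda =", format(x$lambda, digits = 4), "\n")
  invisible(x)
}

#' Combined global nonequivalence and bias (CGNB) scores
#'
#' `C = 1 - fitted` elementwise: a high CGNB marks a metabolite that is
#' both hard to detect in a metabolomic profile and hard to compensate for
#' in the network, i.e. a pathway-specific metabolite deserving more
#' attention in enrichment.
#'
#' @param fit A `bias_fit` from [fit_monotone_spline()].
#' @return Named numeric vector of CGNB scores in \[0, 1\].
#' @export
cgnb <- function(fit) {
  stopifnot(inherits(fit, "bias_fit"))
  fit$cgnb
}

#' Write the CGNB table
#'
#' @param fit A `bias_fit`.
#' @param path Output TSV (`metabolite_id`, `gn_score`, `fitted_prob`,
#'   `cgnb`).
#' @export
write_cgnb_table <- function(fit, path) {
  gn <- fit$basis$x
  df <- data.frame(metabolite_id = names(gn),
                   gn_score = formatC(unname(gn), digits = 10, format = "g"),
                   fitted_prob = sprintf("%.6f", unname(fit$fitted)),
                   cgnb = sprintf("%.6f", unname(fit$cgnb)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
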