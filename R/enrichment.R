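#' Relative pathway weights from CGNB scores
#'
#' For each retained pathway \eqn{P} the relative weight is
#' \deqn{W(P) = \frac{\mathrm{mean}_{j \in P}(1 - C_j)}
#'   {\frac{1}{K}\sum_k \mathrm{mean}_{r \in P_k}(1 - C_r)},}
#' the pathway's mean detectability relative to the across-pathway average,
#' so the mean of \eqn{W} over the \eqn{K} retained pathways is exactly 1.
#' Pathways dominated by high-CGNB (pathway-specific, hard-to-detect)
#' members receive \eqn{W < 1} and hence a small odds weight
#' \eqn{w_1 = W^6} in the enrichment test. Members without a CGNB score
#' use `impute_value`; per-pathway means and the across-pathway mean are
#' floored at 1e-6 for numerical safety.
#'
#' @param coll An annotated `pathway_collection`.
#' @param cgnb_scores Named numeric vector of CGNB scores (`C`).
#' @param impute_value Value of `1 - C` used for members without a CGNB
#'   score; default: mean of `1 - C` over all scored metabolites.
#' @return Named numeric vector of relative weights `W`, one per pathway.
#' @export
pathway_relative_weight <- function(coll, cgnb_scores,
                                    impute_value = NULL) {
  stopifnot(inherits(coll, "pathway_collection"))
  detect <- 1 - cgnb_scores
  if (is.null(impute_value)) impute_value <- mean(detect)
  if (is.na(impute_value)) stop("no CGNB scores to impute from")
  s <- vapply(names(coll$pathways), function(id) {
    m <- coll$pathways[[id]]
    if (!length(m)) stop("pathway ", id, " is empty after annotation")
    v <- detect[m]
    nmiss <- sum(is.na(v))
    if (nmiss) {
      mpinet_log("pathway ", id, ": imputed 1-C for ", nmiss, " member(s)",
                 level = "debug")
      v[is.na(v)] <- impute_value
    }
    max(mean(v), 1e-6)
  }, 0)
  denom <- max(mean(s), 1e-6)
  if (denom <= 1e-6 && all(s <= 1e-6)) {
    stop("all pathway detectability means vanish (all C = 1)")
  }
  s / denom
}

#' Wallenius noncentral hypergeometric probability mass function
#'
#' Probability of drawing exactly `x` pathway members when `n` items are
#' drawn without replacement from a population of `N` items of which `m1`
#' are pathway members with odds weight `w1` and `m2 = N - m1` are
#' non-members with odds weight `w2`. Each mass is evaluated through the
#' integral representation
#' \deqn{P(X = x) = \binom{m_1}{x}\binom{m_2}{n-x}
#'   \int_0^1 (1 - t^{w_1/d_x})^x (1 - t^{w_2/d_x})^{n-x} \, dt,}
#' with \eqn{d_x = w_1(m_1 - x) + w_2(m_2 - (n - x))}, computed after the
#' substitution \eqn{t = u^{d_x}} (which removes the boundary spike for
#' small \eqn{w/d_x}) by adaptive quadrature at relative tolerance 1e-10.
#'
#' @param n Number of draws (interesting metabolites).
#' @param m1 Number of pathway members in the population.
#' @param N Population (background) size.
#' @param w1,w2 Odds weights of members / non-members (both > 0).
#' @return Numeric vector of length `n + 1`: `P(X = x)` for `x = 0..n`.
#' @export
wallenius_pmf <- function(n, m1, N, w1, w2 = 1) {
  check_wallenius_args(0L, n, m1, N, w1, w2)
  m2 <- N - m1
  pmf <- numeric(n + 1)
  for (x in 0:n) {
    lch <- lchoose(m1, x) + lchoose(m2, n - x)
    if (lch == -Inf) next
    d <- w1 * (m1 - x) + w2 * (m2 - (n - x))
    if (d <= 0) {            # all items drawn: the single support point
      pmf[x + 1] <- exp(lch)
      next
    }
    f <- function(u) {
      out <- numeric(length(u))
      pos <- u > 0 & u < 1
      uu <- u[pos]
      out[pos] <- exp(lch + log(d) + (d - 1) * log(uu) +
                        x * log1p(-uu^w1) + (n - x) * log1p(-uu^w2))
      out
    }
    pmf[x + 1] <- stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                                   subdivisions = 500L)$value
  }
  pmf
}

#' Wallenius noncentral hypergeometric upper-tail p-value
#'
#' Significance of observing at least `g` pathway members among the `n`
#' interesting metabolites: `p = P(X >= g) = 1 - sum_{x < g} P(X = x)`.
#' With `w1 = w2` this reduces to the central hypergeometric test (ORA);
#' `w1 < 1` (pathway-specific pathways) makes a given overlap `g` more
#' surprising and hence more significant. The degenerate census case
#' `n = N` returns the exact limit directly.
#'
#' @param g Observed number of interesting metabolites in the pathway.
#' @inheritParams wallenius_pmf
#' @return Upper-tail p-value in \[0, 1\].
#' @export
wallenius_pvalue <- function(g, n, m1, N, w1, w2 = 1) {
  check_wallenius_args(g, n, m1, N, w1, w2)
  if (g == 0) return(1)
  if (n == N) return(1)      # g <= m1 guaranteed; X = m1 with certainty
  pmf <- wallenius_pmf(n, m1, N, w1, w2)
  min(1, max(0, 1 - sum(pmf[seq_len(g)])))
}

check_wallenius_args <- function(g, n, m1, N, w1, w2) {
  if (length(g) != 1 || is.na(g) || g < 0) stop("invalid g: ", g)
  if (length(n) != 1 || is.na(n) || n < 0) stop("invalid n: ", n)
  if (length(m1) != 1 || is.na(m1) || m1 < 0) stop("invalid m1: ", m1)
  if (length(N) != 1 || is.na(N) || N < 1) stop("invalid N: ", N)
  if (m1 > N) stop("invalid m1: exceeds N")
  if (n > N) stop("invalid n: exceeds N")
  if (g > min(n, m1)) stop("invalid g: exceeds min(n, m1)")
  if (!is.finite(w1) || w1 <= 0) stop("invalid w1: must be > 0")
  if (!is.finite(w2) || w2 <= 0) stop("invalid w2: must be > 0")
  invisible(NULL)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1 and aligned to the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the full network-based pathway identification pipeline
#'
#' End-to-end workflow: GCS walk scores on the weighted network, GN scores,
#' binary labels for the interesting metabolites, monotone spline fit of
#' selection probability versus GN, CGNB scores, background annotation of
#' the pathway collection, relative pathway weights, Wallenius upper-tail
#' p-values with odds weight `w1 = W^weight_exponent`, and
#' Benjamini-Hochberg FDR across the retained pathways.
#'
#' @param interesting Character vector of interesting metabolite IDs.
#' @param net A `metabolite_network`.
#' @param coll A `pathway_collection` (annotated or raw).
#' @param beta,lmax GCS walk attenuation and maximum walk length.
#' @param knots Number of spline knots.
#' @param weight_exponent Exponent turning the relative weight `W` into the
#'   odds weight `w1 = W^weight_exponent`; 0 reduces the pipeline to the
#'   plain hypergeometric ORA.
#' @param min_pathway_size Minimum background-annotated pathway size.
#' @param background Optional explicit background ID vector; default: all
#'   metabolites that appear in at least one pathway of the collection and
#'   carry a CGNB score.
#' @param lambda Smoothing selection for the spline fit (`"gcv"` or fixed).
#' @return A data.frame of per-pathway statistics, sorted by ascending
#'   p-value with ties broken by pathway id: `pathway_id`, `pathway_name`,
#'   `m1`, `g`, `relative_weight`, `w1`, `pvalue`, `fdr`,
#'   `interesting_members` (semicolon-joined, sorted).
#' @export
run_mpinet <- function(interesting, net, coll,
                       beta = 0.5, lmax = 6, knots = 6,
                       weight_exponent = 6, min_pathway_size = 3,
                       background = NULL, lambda = "gcv") {
  interesting <- unique(canonicalize_cid(interesting))
  gcs <- compute_gcs(net, beta = beta, lmax = lmax)
  gn <- compute_gn(gcs)
  y <- make_labels(net, interesting)
  basis <- build_basis(gn, k = knots)
  fit <- fit_monotone_spline(basis, gn, y, lambda = lambda)
  C <- cgnb(fit)
  if (is.null(background)) {
    background <- intersect(unique(unlist(coll$pathways)), names(C))
    if (!length(background)) stop("default background is empty: no pathway ",
                                  "member carries a CGNB score")
  } else {
    background <- unique(canonicalize_cid(background))
  }
  ann <- annotate(coll, background, min_size = min_pathway_size)
  N <- length(background)
  dropped <- sum(!interesting %in% background)
  if (dropped) {
    mpinet_log(dropped, " interesting metabolite(s) outside background dropped")
  }
  interesting <- intersect(interesting, background)
  n <- length(interesting)
  if (n < 1) stop("no interesting metabolites in the background")
  detect_bg <- 1 - C[names(C) %in% background]
  W <- pathway_relative_weight(ann, C, impute_value = mean(detect_bg))
  w1 <- W^weight_exponent
  ids <- names(ann$pathways)
  g <- vapply(ids, function(id) length(intersect(ann$pathways[[id]],
                                                 interesting)), 0L)
  mpinet_log("enrichment: N = ", N, ", n = ", n, ", K = ", ann$K)
  p <- vapply(ids, function(id) {
    wallenius_pvalue(g[[id]], n, ann$m1[[id]], N, w1[[id]], 1)
  }, 0)
  res <- data.frame(
    pathway_id = ids,
    pathway_name = unname(ann$names[ids]),
    m1 = unname(ann$m1[ids]),
    g = unname(g),
    relative_weight = unname(W),
    w1 = unname(w1),
    pvalue = unname(p),
    fdr = bh_fdr(unname(p)),
    interesting_members = vapply(ids, function(id) {
      paste(sort(intersect(ann$pathways[[id]], interesting)), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE)
  res <- res[order(res$pvalue, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write the enrichment result table
#'
#' Columns in fixed order; floating point values at 6 significant digits,
#' p-values and FDR in scientific notation below 1e-4.
#'
#' @param res Result data.frame from [run_mpinet()].
#' @param path Output TSV path.
#' @export
write_results <- function(res, path) {
  fmt_p <- function(p) ifelse(p < 1e-4, sprintf("%.6e", p),
                              formatC(p, digits = 6, format = "g"))
  out <- data.frame(
    pathway_id = res$pathway_id,
    pathway_name = res$pathway_name,
    m1 = res$m1,
    g = res$g,
    relative_weight = formatC(res$relative_weight, digits = 6, format = "g"),
    w1 = formatC(res$w1, digits = 6, format = "g"),
    pvalue = fmt_p(res$pvalue),
    fdr = fmt_p(res$fdr),
    interesting_members = res$interesting_members,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-pathway GN-score bias diagnostic
#'
#' Wilcoxon rank-sum test comparing the GN scores of a pathway's members
#' against those of the remaining network metabolites (the complement is
#' used so the two samples are independent; a pathway covering the whole
#' network returns p = 1 by the identical-distribution convention). Exact
#' enumeration is used for pathways with at most 10 scored members and no
#' ties, the tie-corrected normal approximation otherwise.
#'
#' @param coll A `pathway_collection`.
#' @param gn Named numeric GN-score vector.
#' @param sides `"two"` (default) or `"one"` (alternative: members have
#'   greater GN than the rest).
#' @return Named numeric vector of p-values (pathways with no scored
#'   member are skipped with a warning).
#' @export
pathway_gn_bias_test <- function(coll, gn, sides = c("two", "one")) {
  sides <- match.arg(sides)
  alt <- if (sides == "two") "two.sided" else "greater"
  out <- numeric(0)
  for (id in names(coll$pathways)) {
    x <- gn[names(gn) %in% coll$pathways[[id]]]
    if (!length(x)) {
      warning("pathway ", id, " has no member with a GN score; skipped")
      next
    }
    y <- gn[!names(gn) %in% coll$pathways[[id]]]
    if (!length(y)) {
      out[id] <- 1
      next
    }
    exact <- length(x) <= 10 && !anyDuplicated(c(x, y))
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alt, exact = exact,
                         correct = TRUE)$p.value)
    out[id] <- p
  }
  out
}

#' Pathway crosstalk edges from cross-set GCS
#'
#' For each unordered pathway pair, the mean GCS over all cross-set member
#' pairs (members absent from the network contribute nothing); an edge is
#' emitted when that mean exceeds the median of all off-diagonal GCS
#' entries.
#'
#' @param coll A `pathway_collection` with at least 2 pathways.
#' @param gcs A `gcs_matrix`.
#' @return data.frame `pathway_a`, `pathway_b`, `mean_gcs` for the emitted
#'   edges.
#' @export
pathway_crosstalk <- function(coll, gcs) {
  ids <- names(coll$pathways)
  if (length(ids) < 2) stop("need at least 2 pathways for crosstalk")
  if (!length(gcs$ids)) stop("empty GCS matrix")
  V <- gcs$values
  med <- stats::median(V[upper.tri(V)])
  idx <- lapply(coll$pathways, function(m) match(intersect(m, gcs$ids),
                                                 gcs$ids))
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      ia <- idx[[i]]; ib <- idx[[j]]
      if (!length(ia) || !length(ib)) next
      m <- mean(V[ia, ib, drop = FALSE])
      if (m > med) {
        rows[[length(rows) + 1L]] <- data.frame(
          pathway_a = ids[[i]], pathway_b = ids[[j]], mean_gcs = m,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(pathway_a = character(), pathway_b = character(),
                      mean_gcs = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Significance of the overlap between two pathway result lists
#'
#' Central hypergeometric upper tail: probability of an overlap at least
#' as large as observed when `|b|` pathways are drawn from a universe of
#' `universe` pathways containing `|a|` marked ones.
#'
#' @param list_a,list_b Character vectors of pathway IDs.
#' @param universe Total number of pathways eligible for both analyses.
#' @return Upper-tail p-value.
#' @export
overlap_pvalue <- function(list_a, list_b, universe) {
  a <- unique(list_a); b <- unique(list_b)
  if (length(a) > universe || length(b) > universe) {
    stop("list size exceeds universe")
  }
  ov <- length(intersect(a, b))
  stats::phyper(ov - 1, length(a), universe - length(a), length(b),
                lower.tail = FALSE)
}
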