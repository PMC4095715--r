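#' Differential metabolite selection by Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test per metabolite between two sample groups; exact
#' p-values when the combined group size is at most 20 and there are no
#' ties, the tie-corrected normal approximation otherwise. Metabolites
#' constant across all samples get p = 1 with a warning.
#'
#' @param mat Numeric matrix, metabolites (rows, named) x samples
#'   (columns, named).
#' @param groups Named character/factor vector over the sample columns with
#'   exactly two levels, each with at least 2 samples.
#' @param alpha Selection threshold on the raw p-value (default 0.1).
#' @return List with `selected` (character vector of metabolite IDs with
#'   p < alpha) and `table` (data.frame `metabolite_id`, `pvalue`).
#' @export
select_differential_wilcoxon <- function(mat, groups, alpha = 0.1) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("abundance matrix needs metabolite row names and sample col names")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate metabolite ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  groups <- groups[colnames(mat)]
  if (anyNA(groups)) stop("group label missing for some samples")
  lev <- unique(as.character(groups))
  if (length(lev) != 2) stop("need exactly two groups")
  g1 <- colnames(mat)[groups == lev[[1L]]]
  g2 <- colnames(mat)[groups == lev[[2L]]]
  if (length(g1) < 2 || length(g2) < 2) stop("need >= 2 samples per group")
  p <- vapply(rownames(mat), function(id) {
    x <- mat[id, g1]; y <- mat[id, g2]
    if (stats::var(c(x, y)) == 0) {
      warning("metabolite ", id, " constant across samples; p = 1")
      return(1)
    }
    exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact)$p.value)
  }, 0)
  list(selected = rownames(mat)[p < alpha],
       table = data.frame(metabolite_id = rownames(mat), pvalue = unname(p),
                          stringsAsFactors = FALSE))
}

#' Drug-sensitivity-related metabolite screen
#'
#' Pearson correlation between a drug's -log(GI50) sensitivity values and
#' each metabolite's abundance across shared samples (cell lines), with
#' Benjamini-Hochberg adjustment. Replicate sensitivity entries for the
#' same sample are averaged first. The default cutoff (adjusted p < 0.6)
#' is the deliberately permissive screen appropriate for feeding a
#' downstream pathway analysis, not a discovery threshold.
#'
#' @param gi50 Named numeric vector of -log(GI50) values; duplicated names
#'   are replicate measurements and are averaged.
#' @param mat Abundance matrix, metabolites x samples (both named).
#' @param fdr_cut Adjusted-p cutoff (default 0.6).
#' @return List with `selected` and `table` (`metabolite_id`, `r`,
#'   `pvalue`, `fdr`); zero-variance or insufficiently observed metabolites
#'   are skipped with a warning.
#' @export
drug_sensitivity_metabolites <- function(gi50, mat, fdr_cut = 0.6) {
  if (is.null(names(gi50))) stop("gi50 needs sample names")
  gi50 <- tapply(gi50, names(gi50), mean)  # average replicates
  shared <- intersect(names(gi50), colnames(mat))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  g <- gi50[shared]
  if (stats::var(g) == 0) stop("gi50 has zero variance over shared samples")
  rows <- lapply(rownames(mat), function(id) {
    x <- mat[id, shared]
    ok <- stats::complete.cases(x, g)
    if (sum(ok) < 3 || stats::var(x[ok]) == 0) {
      warning("metabolite ", id, " skipped (zero variance or < 3 complete pairs)")
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], g[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(metabolite_id = id, r = unname(ct$estimate),
               pvalue = ct$p.value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab) || !nrow(tab)) stop("no testable metabolites")
  tab$fdr <- bh_fdr(tab$pvalue)
  rownames(tab) <- NULL
  list(selected = tab$metabolite_id[tab$fdr < fdr_cut], table = tab)
}

#' Read an abundance matrix TSV
#'
#' First column = metabolite id, header row = sample ids.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_abundance <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Read sample group labels (TSV: sample_id, group)
#'
#' @param path TSV path.
#' @return Named character vector of group labels.
#' @export
read_groups <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), df[[1L]])
}
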