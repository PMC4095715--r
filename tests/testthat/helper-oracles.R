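# Independent oracles and fixture builders used across the suite.

# Exact Wallenius pmf by sequential-urn dynamic programming: draw n items
# one at a time without replacement; at each step the chance of drawing a
# type-1 item is w1*r1 / (w1*r1 + w2*r2) with r1, r2 the remaining counts.
# Independent of the package's integral-representation route.
urn_exact_pmf <- function(n, m1, N, w1, w2 = 1) {
  m2 <- N - m1
  # prob[x+1] = P(x type-1 drawn so far)
  prob <- c(1, rep(0, n))
  for (draw in seq_len(n)) {
    nxt <- rep(0, n + 1)
    for (x in 0:(draw - 1)) {
      if (prob[x + 1] == 0) next
      r1 <- m1 - x
      r2 <- m2 - (draw - 1 - x)
      tot <- w1 * r1 + w2 * r2
      if (tot <= 0) next
      if (r1 > 0) nxt[x + 2] <- nxt[x + 2] + prob[x + 1] * w1 * r1 / tot
      if (r2 > 0) nxt[x + 1] <- nxt[x + 1] + prob[x + 1] * w2 * r2 / tot
    }
    prob <- nxt
  }
  prob
}

urn_exact_tail <- function(g, n, m1, N, w1, w2 = 1) {
  if (g == 0) return(1)
  1 - sum(urn_exact_pmf(n, m1, N, w1, w2)[seq_len(g)])
}

# Monte Carlo urn draws, vectorized over replicates.
urn_mc_counts <- function(n, m1, N, w1, w2 = 1, reps = 1e5) {
  x <- integer(reps)          # type-1 drawn so far
  for (draw in seq_len(n)) {
    r1 <- m1 - x
    r2 <- (N - m1) - (draw - 1L - x)
    p1 <- w1 * r1 / (w1 * r1 + w2 * r2)
    x <- x + (runif(reps) < p1)
  }
  x
}

# Tiny deterministic networks -------------------------------------------

# path a-b (0.9), b-c (0.8); node ids 1,2,3
path3_network <- function() {
  build_network(data.frame(a = c("1", "2"), b = c("2", "3"),
                           score = c(900L, 800L), stringsAsFactors = FALSE))
}

random_network <- function(n_nodes, p = 0.5, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  build_network(data.frame(a = as.character(pairs[keep, 1]),
                           b = as.character(pairs[keep, 2]),
                           score = sample(1:1000, sum(keep), replace = TRUE),
                           stringsAsFactors = FALSE))
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

make_collection <- function(members, descs = NULL) {
  ids <- names(members)
  if (is.null(descs)) descs <- stats::setNames(paste("set", ids), ids)
  structure(list(pathways = members, names = descs,
                 m1 = stats::setNames(rep(NA_integer_, length(ids)), ids),
                 min_size = NA_integer_, K = length(ids)),
            class = "pathway_collection")
}
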