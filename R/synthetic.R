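#' Configuration for the synthetic benchmark generator
#'
#' Bundles every tunable of the seeded generator that emulates the
#' statistical structure the pathway-identification method assumes: a
#' weighted metabolite association network, pathway memberships stratified
#' into pathway-specific (low-GN) versus common (high-GN) metabolites, and
#' a detection/differential process whose selection probability increases
#' with network connectivity.
#'
#' @param seed Master integer seed; every stage draws from an independent
#'   substream derived from it, so one config + seed fixes all outputs.
#' @param n_nodes Number of network metabolites (>= 10).
#' @param edge_model `"scale-free"` (preferential attachment, connected by
#'   construction) or `"erdos-renyi"` (connectivity enforced by linking
#'   components).
#' @param edge_param Edges per new node (scale-free) or edge probability
#'   in (0, 1] (Erdős–Rényi).
#' @param n_pathways Number of pathways.
#' @param size_range Integer vector `c(min, max)` of pathway sizes.
#' @param specificity_mix Fraction of each pathway's members drawn from the
#'   low-GN (pathway-specific) stratum; the rest come from the high-GN
#'   (common) stratum.
#' @param bias_base,bias_strength Intercept and slope of the selection
#'   probability in the min-max-normalized GN score (the documented
#'   detection bias: well-connected metabolites are selected more often).
#' @param planted Character vector of pathway ids whose members' selection
#'   probability is multiplied by `planted_multiplier`.
#' @param planted_multiplier Enrichment multiplier inside planted pathways.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, n_nodes = 300,
                              edge_model = c("scale-free", "erdos-renyi"),
                              edge_param = 3, n_pathways = 12,
                              size_range = c(8, 15),
                              specificity_mix = 0.5,
                              bias_base = 0.1, bias_strength = 0.6,
                              planted = character(),
                              planted_multiplier = 1) {
  edge_model <- match.arg(edge_model)
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  if (n_pathways < 1) stop("n_pathways must be >= 1")
  if (edge_model == "erdos-renyi" && (edge_param <= 0 || edge_param > 1)) {
    stop("erdos-renyi edge_param must lie in (0, 1]")
  }
  if (edge_model == "scale-free" && edge_param < 1) {
    stop("scale-free edge_param must be >= 1")
  }
  if (length(size_range) != 2 || size_range[1] < 2 ||
      size_range[2] < size_range[1]) {
    stop("size_range must be c(min, max) with 2 <= min <= max")
  }
  if (specificity_mix < 0 || specificity_mix > 1) {
    stop("specificity_mix must lie in [0, 1]")
  }
  if (bias_base < 0 || bias_base > 1) stop("bias_base must lie in [0, 1]")
  if (planted_multiplier <= 0) stop("planted_multiplier must be > 0")
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 edge_model = edge_model, edge_param = edge_param,
                 n_pathways = as.integer(n_pathways),
                 size_range = as.integer(size_range),
                 specificity_mix = specificity_mix,
                 bias_base = bias_base, bias_strength = bias_strength,
                 planted = as.character(planted),
                 planted_multiplier = planted_multiplier),
            class = "simulation_config")
}

# independent substream seeds below 2^31, one per generator stage
substream_seed <- function(seed, stage) {
  offset <- c(network = 11L, pathways = 23L, interesting = 37L)[[stage]]
  (abs(as.integer(seed)) %% 20000003L) * 101L + offset
}

#' Simulate a weighted metabolite network
#'
#' Connected-by-construction weighted undirected graph; edge weights are
#' STITCH-style combined scores drawn uniformly from 150..999 and divided
#' by 1000. Deterministic under the config seed.
#'
#' @param cfg A `simulation_config`.
#' @return A `metabolite_network` with node IDs `"1".."n_nodes"`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(substream_seed(cfg$seed, "network"))
  n <- cfg$n_nodes
  if (cfg$edge_model == "scale-free") {
    gr <- igraph::sample_pa(n, m = cfg$edge_param, directed = FALSE)
  } else {
    gr <- igraph::sample_gnp(n, cfg$edge_param)
    comp <- igraph::components(gr)
    if (comp$no > 1) {  # chain one vertex of each component to the first
      reps <- vapply(seq_len(comp$no),
                     function(k) which(comp$membership == k)[1L], 0L)
      gr <- igraph::add_edges(gr, as.vector(rbind(reps[-1L], reps[1L])))
    }
  }
  gr <- igraph::simplify(gr)
  el <- igraph::as_edgelist(gr, names = FALSE)
  scores <- sample(150:999, nrow(el), replace = TRUE)
  edges <- data.frame(a = as.character(pmin(el[, 1], el[, 2])),
                      b = as.character(pmax(el[, 1], el[, 2])),
                      score = scores, stringsAsFactors = FALSE)
  build_network(edges)
}

#' Simulate a pathway collection with controllable specificity structure
#'
#' Network nodes are split at the median GN score into a low-GN
#' (pathway-specific) and a high-GN (common) stratum; each pathway draws
#' `round(size * specificity_mix)` members from the low stratum and the
#' rest from the high stratum.
#'
#' @param net A `metabolite_network` (typically from [simulate_network()]).
#' @param cfg A `simulation_config`.
#' @param gn Optional precomputed GN scores; computed with default GCS
#'   parameters otherwise.
#' @return A `pathway_collection` with ids `"pw1".."pwK"`.
#' @export
simulate_pathways <- function(net, cfg, gn = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(gn)) gn <- compute_gn(compute_gcs(net))
  set.seed(substream_seed(cfg$seed, "pathways"))
  med <- stats::median(gn)
  low <- names(gn)[gn <= med]
  high <- names(gn)[gn > med]
  members <- vector("list", cfg$n_pathways)
  for (i in seq_len(cfg$n_pathways)) {
    size <- sample(cfg$size_range[1]:cfg$size_range[2], 1L)
    n_low <- min(round(size * cfg$specificity_mix), length(low))
    n_high <- min(size - n_low, length(high))
    members[[i]] <- sort(c(sample(low, n_low), sample(high, n_high)))
  }
  ids <- paste0("pw", seq_len(cfg$n_pathways))
  names(members) <- ids
  structure(list(pathways = members,
                 names = stats::setNames(
                   paste0("synthetic pathway ", seq_along(ids)), ids),
                 m1 = stats::setNames(rep(NA_integer_, length(ids)), ids),
                 min_size = NA_integer_, K = length(ids)),
            class = "pathway_collection")
}

#' Simulate a biased interesting-metabolite set
#'
#' Each network metabolite is selected independently with probability
#' `clamp(bias_base + bias_strength * gn_norm, 0.01, 0.99)`, where
#' `gn_norm` is the min-max normalized GN score; the probability of
#' members of planted pathways is further multiplied by
#' `planted_multiplier` (and re-clamped). Reproduces the documented
#' detection bias: well-connected metabolites enter profiles more often.
#'
#' @param net A `metabolite_network`.
#' @param coll A `pathway_collection` (for the planted pathways).
#' @param cfg A `simulation_config`.
#' @param gn Optional precomputed GN scores.
#' @return Character vector of selected metabolite IDs (at least one: if
#'   the Bernoulli draws select none, the highest-probability node is
#'   returned).
#' @export
simulate_interesting <- function(net, coll, cfg, gn = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(gn)) gn <- compute_gn(compute_gcs(net))
  set.seed(substream_seed(cfg$seed, "interesting"))
  rng <- range(gn)
  gn_norm <- if (diff(rng) > 0) (gn - rng[1]) / diff(rng) else rep(0.5, length(gn))
  p <- pmin(pmax(cfg$bias_base + cfg$bias_strength * gn_norm, 0.01), 0.99)
  if (length(cfg$planted)) {
    in_planted <- names(gn) %in%
      unique(unlist(coll$pathways[intersect(cfg$planted,
                                            names(coll$pathways))]))
    p[in_planted] <- pmin(pmax(p[in_planted] * cfg$planted_multiplier,
                               0.01), 0.99)
  }
  sel <- names(gn)[stats::runif(length(gn)) < p]
  if (!length(sel)) sel <- names(gn)[which.max(p)]
  sel
}

#' Write a complete synthetic fixture directory
#'
#' Emits the same plain-text formats the pipeline reads: `network.tsv`,
#' `pathways.gmt`, `interesting.txt`, and `background.txt` (all network
#' nodes).
#'
#' @param dir Output directory (created if needed).
#' @param cfg A `simulation_config`.
#' @return Invisibly, a named list of the file paths plus the simulated
#'   objects.
#' @export
simulate_fixture <- function(dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- simulate_network(cfg)
  gn <- compute_gn(compute_gcs(net))
  coll <- simulate_pathways(net, cfg, gn = gn)
  interesting <- simulate_interesting(net, coll, cfg, gn = gn)
  paths <- list(network = file.path(dir, "network.tsv"),
                pathways = file.path(dir, "pathways.gmt"),
                interesting = file.path(dir, "interesting.txt"),
                background = file.path(dir, "background.txt"))
  write_network(net, paths$network)
  write_gmt(coll, paths$pathways)
  writeLines(interesting, paths$interesting)
  writeLines(net$nodes, paths$background)
  invisible(c(paths, list(net = net, coll = coll,
                          interesting_ids = interesting, gn = gn)))
}
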