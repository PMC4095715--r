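#' Canonicalize compound identifiers
#'
#' Converts PubChem compound identifiers to their canonical form: a bare
#' digit string with no prefix and no leading zeros. STITCH-style
#' stereospecific (`CIDs...`) and merged (`CIDm...`) forms are accepted and
#' collapse to the same canonical identifier.
#'
#' @param x Character vector of identifiers (`"CIDs00000123"`, `"CIDm123"`,
#'   `"123"`, ...).
#' @return Character vector of canonical digit strings.
#' @examples
#' canonicalize_cid(c("CIDs00000001", "CIDm042", "7"))
#' @export
canonicalize_cid <- function(x) {
  x <- as.character(x)
  out <- sub("^CID[sm]?", "", x)
  out <- sub("^0+", "", out)
  bad <- !grepl("^[0-9]+$", out) | out == "" | out == "0"
  if (any(bad)) {
    stop("invalid compound identifier(s): ",
         paste(utils::head(x[bad], 5L), collapse = ", "))
  }
  out
}

#' Read a STITCH-dialect chemical-chemical link file
#'
#' Parses a whitespace- or tab-separated file with at least three columns
#' (chemical A, chemical B, integer combined score on the 0-1000 scale).
#' A single header line is auto-detected and skipped. Identifiers are
#' canonicalized, records below `min_score` and self links are dropped, and
#' for duplicate unordered pairs the maximum score is kept.
#'
#' @param path Path to the link file.
#' @param min_score Minimum combined score to retain (default 0: no cutoff).
#' @return A data.frame with columns `a`, `b` (canonical IDs, `a < b` in the
#'   canonical string order) and integer `score`.
#' @export
read_stitch_links <- function(path, min_score = 0) {
  if (!file.exists(path)) stop("cannot read link file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  start <- 1L
  if (length(lines) >= 1L) {
    f <- strsplit(trimws(lines[[1L]]), "[\t ]+")[[1L]]
    if (length(f) >= 3L && is.na(suppressWarnings(as.numeric(f[[3L]])))) {
      start <- 2L  # header line
    }
  }
  if (start > length(lines)) {
    warning("no data lines in ", path)
    return(data.frame(a = character(), b = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  body <- lines[start:length(lines)]
  fields <- strsplit(trimws(body), "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", which(nf < 3L)[1L] + start - 1L,
         ": expected at least 3 columns")
  }
  a_raw <- vapply(fields, `[[`, "", 1L)
  b_raw <- vapply(fields, `[[`, "", 2L)
  sc_raw <- vapply(fields, `[[`, "", 3L)
  sc <- suppressWarnings(as.numeric(sc_raw))
  bad <- is.na(sc) | sc != round(sc)
  if (any(bad)) {
    stop("line ", which(bad)[1L] + start - 1L,
         ": non-integer combined score '", sc_raw[which(bad)[1L]], "'")
  }
  oob <- sc <= 0 | sc > 1000
  if (any(oob)) {
    stop("line ", which(oob)[1L] + start - 1L,
         ": combined score ", sc[which(oob)[1L]], " outside (0, 1000]")
  }
  a <- canonicalize_cid(a_raw)
  b <- canonicalize_cid(b_raw)
  keep <- sc >= min_score
  self <- a == b
  if (any(self)) {
    mpinet_log("dropped ", sum(self), " self link(s)")
  }
  keep <- keep & !self
  a <- a[keep]; b <- b[keep]; sc <- as.integer(sc[keep])
  if (!length(a)) {
    return(data.frame(a = character(), b = character(),
                      score = integer(), stringsAsFactors = FALSE))
  }
  swap <- a > b  # order endpoints so duplicates collide
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  best <- tapply(sc, key, max)
  first <- !duplicated(key)
  out <- data.frame(a = a[first], b = b[first],
                    score = as.integer(best[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Restrict edge records to a background metabolite set
#'
#' Keeps exactly those records whose both endpoints belong to the background
#' (e.g. the union of human metabolites across curated databases).
#'
#' @param edges Edge data.frame as returned by [read_stitch_links()].
#' @param background Character vector of background metabolite IDs
#'   (canonicalized internally).
#' @return The filtered edge data.frame, input order preserved.
#' @export
restrict_to_background <- function(edges, background) {
  if (!length(background)) stop("background set is empty")
  bg <- unique(canonicalize_cid(background))
  keep <- edges$a %in% bg & edges$b %in% bg
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  mpinet_log("background restriction kept ", nrow(out), " of ",
             nrow(edges), " edges")
  out
}

#' Build the global edge-weighted metabolite network
#'
#' Nodes are the union of edge endpoints; the edge weight is the combined
#' score divided by 1000, so all weights lie in (0, 1].
#'
#' @param edges Deduplicated edge data.frame ([read_stitch_links()] output).
#' @return A `metabolite_network` object: list with `nodes` (sorted
#'   character vector) and `edges` (data.frame `a`, `b`, `weight`).
#' @export
build_network <- function(edges) {
  if (!nrow(edges)) stop("cannot build a network from zero edges")
  if (any(edges$a == edges$b)) stop("self links present in edge input")
  nodes <- sort(unique(c(edges$a, edges$b)))
  net <- structure(
    list(nodes = nodes,
         edges = data.frame(a = edges$a, b = edges$b,
                            weight = edges$score / 1000,
                            stringsAsFactors = FALSE)),
    class = "metabolite_network")
  mpinet_log("network: ", length(nodes), " nodes, ", nrow(edges), " edges")
  net
}

#' @export
print.metabolite_network <- function(x, ...) {
  cat("metabolite_network:", length(x$nodes), "nodes,",
      nrow(x$edges), "weighted edges\n")
  invisible(x)
}

#' Weighted adjacency matrix of a metabolite network
#'
#' @param net A `metabolite_network`.
#' @return Symmetric base matrix with dimnames = node IDs.
#' @keywords internal
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  ia <- match(net$edges$a, net$nodes)
  ib <- match(net$edges$b, net$nodes)
  A[cbind(ia, ib)] <- net$edges$weight
  A[cbind(ib, ia)] <- net$edges$weight
  A
}

#' Serialize / deserialize a metabolite network
#'
#' Writes a 3-column TSV (`node_a`, `node_b`, `weight` with 6 decimal
#' places). The write-read round trip is lossless for networks whose
#' weights are multiples of 0.001, as produced by [build_network()].
#'
#' @param net A `metabolite_network`.
#' @param path Output file path.
#' @export
write_network <- function(net, path) {
  df <- data.frame(node_a = net$edges$a, node_b = net$edges$b,
                   weight = sprintf("%.6f", net$edges$weight),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @return `read_network()` returns a `metabolite_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"))
  w <- suppressWarnings(as.numeric(df[[3L]]))
  if (anyNA(w) || any(w <= 0) || any(w > 1)) {
    stop("malformed weight column in ", path, ": weights must lie in (0, 1]")
  }
  a <- canonicalize_cid(df[[1L]])
  b <- canonicalize_cid(df[[2L]])
  structure(
    list(nodes = sort(unique(c(a, b))),
         edges = data.frame(a = a, b = b, weight = w,
                            stringsAsFactors = FALSE)),
    class = "metabolite_network")
}

#' Read a one-ID-per-line metabolite list
#'
#' @param path Text file, one compound identifier per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return Character vector of canonical IDs.
#' @export
read_metabolite_list <- function(path) {
  if (!file.exists(path)) stop("cannot read metabolite list: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(canonicalize_cid(x))
}

# package-level logging: levels quiet < info < debug
mpinet_log <- function(..., level = "info") {
  opt <- getOption("mpinet.log_level", "info")
  rank <- c(quiet = 0L, info = 1L, debug = 2L)
  if (rank[[level]] <= rank[[opt]] && rank[[opt]] > 0L) {
    message("[mpinet] ", ...)
  }
  invisible(NULL)
}
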