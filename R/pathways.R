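#' Read a pathway collection from a GMT file
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `id`, `description`, then member metabolite IDs. Members are
#' canonicalized and deduplicated within each line.
#'
#' @param path GMT file path.
#' @return A `pathway_collection`: list with `pathways` (named list of
#'   member character vectors, in file order), `names` (named descriptions),
#'   `m1` (background-annotated sizes, `NA` until [annotate()]),
#'   `min_size`, and `K`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("GMT line ", which(nf < 3L)[1L], ": fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ", ids[duplicated(ids)][1L])
  }
  members <- lapply(fields, function(f) unique(canonicalize_cid(f[-(1:2)])))
  names(members) <- ids
  descs <- vapply(fields, `[[`, "", 2L)
  names(descs) <- ids
  structure(list(pathways = members, names = descs,
                 m1 = stats::setNames(rep(NA_integer_, length(ids)), ids),
                 min_size = NA_integer_, K = length(ids)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection: K =", x$K, "pathways")
  if (!is.na(x$min_size)) cat(" (annotated, min_size =", x$min_size, ")")
  cat("\n")
  invisible(x)
}

#' Annotate a pathway collection against a background set
#'
#' Intersects every pathway's members with the background metabolite
#' universe, records the background-annotated size `m1`, and drops
#' pathways with fewer than `min_size` annotated members. Idempotent.
#'
#' @param coll A `pathway_collection`.
#' @param background Character vector of background metabolite IDs.
#' @param min_size Minimum background-annotated size to retain (default 3).
#' @return The annotated, filtered `pathway_collection`.
#' @export
annotate <- function(coll, background, min_size = 3) {
  stopifnot(inherits(coll, "pathway_collection"))
  if (!length(background)) stop("background set is empty")
  bg <- unique(canonicalize_cid(background))
  members <- lapply(coll$pathways, function(m) m[m %in% bg])
  m1 <- lengths(members)
  keep <- m1 >= min_size
  if (!any(keep)) stop("all pathways dropped by annotation (min_size = ",
                       min_size, ")")
  if (any(!keep)) {
    mpinet_log("dropped ", sum(!keep), " pathway(s) below min_size ", min_size)
  }
  structure(list(pathways = members[keep],
                 names = coll$names[keep],
                 m1 = m1[keep],
                 min_size = as.integer(min_size),
                 K = sum(keep)),
            class = "pathway_collection")
}

#' Write a pathway collection as GMT
#'
#' @param coll A `pathway_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(names(coll$pathways), function(id) {
    paste(c(id, coll$names[[id]], coll$pathways[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
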