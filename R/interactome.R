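#' Signed, directed protein-interaction network
#'
#' An `interactome` is the substrate every propagation run works on: a set of
#' proteins (case-sensitive gene symbols) plus directed edges carrying a sign,
#' `+1` for activation and `-1` for inhibition. Signal flows along edge
#' direction, so `A -> B` means A's activity influences B.
#'
#' @param edges a data frame with columns `from`, `to` and `sign` (one of
#'   `+1`/`-1`, `"+"`/`"-"`, `"activation"`/`"inhibition"`,
#'   `"activates"`/`"inhibits"`); an optional `annotation` column carries free
#'   text provenance.
#' @param proteins optional character vector of protein identifiers; defaults
#'   to the union of edge endpoints. Isolated proteins may be listed here.
#'
#' @return an object of class `interactome` with elements `proteins`
#'   (character) and `edges` (data frame with `from`, `to`, `sign`,
#'   `annotation`).
#' @export
#' @examples
#' net <- interactome(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                               sign = c(1, -1)))
#' net
interactome <- function(edges, proteins = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to", "sign") %in% names(edges)))
    stop("edges must have columns 'from', 'to' and 'sign'")
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), annotation = character(),
                        stringsAsFactors = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- normalize_sign(edges$sign)
  if (is.null(edges$annotation)) edges$annotation <- rep("", nrow(edges))
  if (is.null(proteins)) proteins <- union(edges$from, edges$to)
  proteins <- as.character(proteins)
  obj <- structure(list(proteins = sort(unique(proteins)), edges = edges),
                   class = "interactome")
  validate_interactome(obj)
}

#' Normalize edge-sign encodings to the internal -1/+1 convention
#'
#' Accepted encodings reflect the common SIF/edge-list dialects:
#' numeric `+1`/`-1`, `"+"`/`"-"`, and the words
#' `"activation"`/`"activates"` and `"inhibition"`/`"inhibits"`.
#'
#' @param x a vector of sign tokens.
#' @return an integer vector of `+1`/`-1`.
#' @export
normalize_sign <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("1", "+1", "+", "activation", "activates", "activate")] <- 1L
  out[tok %in% c("-1", "-", "inhibition", "inhibits", "inhibit")] <- -1L
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop("malformed sign token(s): ", paste(sQuote(bad), collapse = ", "))
  }
  out
}

validate_interactome <- function(net) {
  e <- net$edges
  missing <- setdiff(union(e$from, e$to), net$proteins)
  if (length(missing))
    stop("edge endpoint(s) not in protein set: ", paste(missing, collapse = ", "))
  self <- e$from == e$to
  if (any(self))
    stop("self-edge(s) rejected: ", paste(unique(e$from[self]), collapse = ", "))
  key <- paste(e$from, e$to, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    conflict <- vapply(unique(dup), function(k) {
      length(unique(e$sign[key == k])) > 1
    }, logical(1))
    if (any(conflict))
      stop("duplicate edge(s) with conflicting signs: ",
           paste(gsub("\r", " -> ", names(conflict)[conflict]), collapse = ", "))
    stop("duplicate edge(s): ",
         paste(gsub("\r", " -> ", unique(dup)), collapse = ", "))
  }
  net
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome:", length(x$proteins), "proteins,",
      nrow(x$edges), "signed directed edges\n")
  cat("  activating:", sum(x$edges$sign == 1),
      " inhibiting:", sum(x$edges$sign == -1), "\n")
  invisible(x)
}

#' Convert an interactome to an igraph graph
#'
#' The returned graph is directed, with a `sign` edge attribute; isolated
#' proteins are kept as vertices.
#'
#' @param net an [interactome()].
#' @return an `igraph` object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "sign")],
    directed = TRUE,
    vertices = data.frame(name = net$proteins)
  )
}

#' Read a signed network from TSV, SIF or GraphML
#'
#' Three on-disk dialects are supported:
#' \describe{
#'   \item{tsv}{three tab-separated columns `source<TAB>sign<TAB>target`.}
#'   \item{sif}{`source<TAB>relation<TAB>target` with relation
#'     `activates`/`inhibits`.}
#'   \item{graphml}{GraphML with a `sign` edge attribute (read via igraph).}
#' }
#' Malformed rows abort the load with the offending line number; self-edges
#' and conflicting duplicate edges are rejected.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; defaults to the file
#'   extension.
#' @return an [interactome()].
#' @export
read_interactome <- function(path, format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("tsv", "sif", "graphml")) ext else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    if (nrow(el) == 0) stop("no edges in ", path)
    if (is.null(el$sign)) stop("GraphML file has no 'sign' edge attribute")
    return(interactome(data.frame(from = el$from, to = el$to, sign = el$sign),
                       proteins = igraph::V(g)$name))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  if (length(lines) == 0) stop("no edges in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed row(s) at line ", paste(bad, collapse = ", "),
         " of ", path, " (expected 3 tab-separated fields)")
  m <- do.call(rbind, lapply(parts, function(p) p[1:3]))
  sign <- tryCatch(normalize_sign(m[, 2]), error = function(e) e)
  if (inherits(sign, "error")) {
    ok <- !vapply(m[, 2], function(s)
      inherits(tryCatch(normalize_sign(s), error = function(e) e), "error"),
      logical(1))
    stop("malformed sign token at line ", paste(which(!ok), collapse = ", "),
         " of ", path)
  }
  interactome(data.frame(from = m[, 1], to = m[, 3], sign = sign))
}

#' Write a signed network to TSV, SIF or GraphML
#'
#' Inverse of [read_interactome()]: `save` then `load` is the identity on the
#' protein set, edge set and signs for all three formats.
#'
#' @param net an [interactome()].
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; defaults to the file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path,
                              format = c("auto", "tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "interactome"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("tsv", "sif", "graphml")) ext else "tsv"
  }
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    rel <- if (format == "sif") {
      ifelse(net$edges$sign > 0, "activates", "inhibits")
    } else {
      sprintf("%+d", net$edges$sign)
    }
    writeLines(paste(net$edges$from, rel, net$edges$to, sep = "\t"), path)
  }
  invisible(path)
}
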