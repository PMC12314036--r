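#' Build a mechanism-of-action model
#'
#' A MoA model simulates the drug: every drug target is clamped at `-1`
#' (an inhibitor suppresses all the proteins it binds), the flagged
#' triggering off-targets being the stimulus of interest while the remaining
#' targets are kept in an inhibited state to reproduce the drug context.
#' The clamp is propagated through every ensemble solution and per-protein
#' activities are summarized as the ensemble mean.
#'
#' @param net an [interactome()].
#' @param ensemble a `solution_ensemble`.
#' @param drug a [drug_profile()].
#' @param flagged character vector of flagged trigger proteins; must be a
#'   subset of the drug's targets.
#' @param effs the [effector_set()] of the process being modelled.
#' @return an object of class `moa_model`: `drug`, `process`, `clamp`
#'   (named vector), `flagged`, `activity` (proteins x solutions matrix),
#'   `mean_activity` (named vector), `effectors`, `tau_act`.
#' @export
build_moa <- function(net, ensemble, drug, flagged, effs) {
  stopifnot(inherits(drug, "drug_profile"), inherits(effs, "effector_set"),
            inherits(ensemble, "solution_ensemble"))
  bad <- setdiff(flagged, drug$targets$protein)
  if (length(bad))
    stop("flagged protein(s) not drug targets: ", paste(bad, collapse = ", "))
  clamp <- stats::setNames(rep(-1, nrow(drug$targets)), drug$targets$protein)
  act <- vapply(ensemble$solutions,
                function(s) propagate(net, s$params, clamp),
                numeric(length(net$proteins)))
  act <- matrix(act, nrow = length(net$proteins),
                dimnames = list(net$proteins, NULL))
  structure(list(drug = drug$name, process = effs$process_name,
                 clamp = clamp, flagged = flagged,
                 activity = act, mean_activity = rowMeans(act),
                 effectors = effs,
                 tau_act = ensemble$solutions[[1]]$params$tau_act),
            class = "moa_model")
}

#' @export
print.moa_model <- function(x, ...) {
  cat("moa_model: drug '", x$drug, "' -> process '", x$process, "'\n",
      sep = "")
  cat("  stimulus:", paste(x$flagged, collapse = ", "), "\n")
  cat("  ", sum(abs(x$mean_activity) >= x$tau_act),
      "proteins above the activity threshold\n")
  invisible(x)
}

#' Extract the most frequent sign-consistent pathways of a MoA model
#'
#' Enumerates simple directed paths of length at most `max_len` from each
#' flagged stimulus protein to each process effector. A path is active in a
#' solution when every protein on it has activity magnitude at least
#' `tau_act` and every step is sign-consistent (the child's activity sign
#' equals the edge sign times the parent's). A path's support is the
#' fraction of ensemble solutions in which it is active; paths with support
#' at least `min_support` are returned, sorted by decreasing support, ties
#' broken by shorter length then lexicographic node order.
#'
#' @param net an [interactome()].
#' @param ensemble the `solution_ensemble` used to build `moa`.
#' @param moa a [build_moa()] result.
#' @param max_len maximum number of steps per path (default 4).
#' @param min_support minimum ensemble support (default 0.5).
#' @return data frame of class `pathway_records` with columns `path`
#'   (proteins joined by `"->"`), `length`, `support`, `edge_signs`
#'   (`+`/`-` per step).
#' @export
extract_pathways <- function(net, ensemble, moa, max_len = 4,
                             min_support = 0.5) {
  stopifnot(inherits(moa, "moa_model"), max_len >= 1)
  g <- as_igraph(net)
  esign_key <- stats::setNames(net$edges$sign,
                               paste(net$edges$from, net$edges$to, sep = "\r"))
  targets <- intersect(moa$effectors$effectors$protein, net$proteins)
  paths <- list()
  for (s in moa$flagged) {
    for (e in setdiff(targets, s)) {
      sp <- igraph::all_simple_paths(g, from = s, to = e, mode = "out",
                                     cutoff = max_len)
      paths <- c(paths, lapply(sp, function(v) igraph::V(g)$name[v]))
    }
  }
  if (length(paths) == 0) return(empty_pathways())
  paths <- unique(paths)

  n_sol <- length(ensemble$solutions)
  recs <- lapply(paths, function(nodes) {
    steps <- cbind(nodes[-length(nodes)], nodes[-1])
    es <- esign_key[paste(steps[, 1], steps[, 2], sep = "\r")]
    active <- vapply(seq_len(n_sol), function(i) {
      y <- moa$activity[nodes, i]
      tau <- ensemble$solutions[[i]]$params$tau_act
      all(abs(y) >= tau) &&
        all(sign(y[-1]) == es * sign(y[-length(y)]))
    }, logical(1))
    data.frame(path = paste(nodes, collapse = "->"),
               length = length(nodes) - 1L,
               support = mean(active),
               edge_signs = paste(ifelse(es > 0, "+", "-"), collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[out$support >= min_support & out$support > 0, , drop = FALSE]
  out <- out[order(-out$support, out$length, out$path), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pathway_records", "data.frame")
  out
}

empty_pathways <- function() {
  structure(data.frame(path = character(), length = integer(),
                       support = numeric(), edge_signs = character(),
                       stringsAsFactors = FALSE),
            class = c("pathway_records", "data.frame"))
}

#' Agreement of MoA models with literature-described drug responses
#'
#' Among the literature proteins that are present with predicted activity
#' (mean activity magnitude at least `tau_act`) in at least one of the
#' models, computes the percentage whose predicted activity sign matches the
#' literature direction. With `consistency = "all"` (default) a protein
#' counts as matching only when it matches in every model where it is
#' present; `"any"` requires a match in at least one such model. Proteins
#' clamped as stimulus are excluded — their sign is imposed, not predicted.
#'
#' @param models list of [build_moa()] results (at least one).
#' @param lit a [literature_set()].
#' @param consistency `"all"` or `"any"`.
#' @return percentage in `[0, 100]`, with attributes `n_present` and
#'   `n_matching`. When no literature protein is present in any model the
#'   agreement is undefined and `NA` is returned (with `n_present = 0`),
#'   never 0.
#' @export
literature_agreement <- function(models, lit, consistency = c("all", "any")) {
  consistency <- match.arg(consistency)
  stopifnot(length(models) >= 1, inherits(lit, "literature_set"))
  clamped <- unique(unlist(lapply(models, function(m) names(m$clamp))))
  entries <- lit$entries[!lit$entries$protein %in% clamped, , drop = FALSE]
  per_protein <- vapply(seq_len(nrow(entries)), function(i) {
    p <- entries$protein[i]
    dir <- entries$direction[i]
    present <- vapply(models, function(m)
      p %in% names(m$mean_activity) &&
        abs(m$mean_activity[[p]]) >= m$tau_act, logical(1))
    if (!any(present)) return(NA)
    match <- vapply(models[present], function(m)
      sign(m$mean_activity[[p]]) == dir, logical(1))
    if (consistency == "all") all(match) else any(match)
  }, logical(1))
  n_present <- sum(!is.na(per_protein))
  if (n_present == 0) {
    out <- NA_real_
    attr(out, "n_present") <- 0L
    attr(out, "n_matching") <- 0L
    return(out)
  }
  n_match <- sum(per_protein, na.rm = TRUE)
  out <- 100 * n_match / n_present
  attr(out, "n_present") <- n_present
  attr(out, "n_matching") <- n_match
  out
}

#' Export a MoA model and its pathways as Graphviz DOT
#'
#' Emits a deterministic DOT digraph: nodes are filled by predicted activity
#' sign (activated, inhibited, or below threshold), stimulus nodes are
#' boxed, effector nodes double-circled; activating steps are drawn as solid
#' `vee` arrows and inhibiting steps as `tee` arrows. With an empty pathway
#' list only the stimulus and effector nodes are emitted.
#'
#' @param moa a [build_moa()] result.
#' @param pathways an [extract_pathways()] result (possibly empty).
#' @return a single DOT string.
#' @export
export_dot <- function(moa, pathways = empty_pathways()) {
  stopifnot(inherits(moa, "moa_model"))
  eff <- moa$effectors$effectors$protein
  path_nodes <- unique(unlist(strsplit(pathways$path, "->", fixed = TRUE)))
  nodes <- sort(unique(c(moa$flagged, eff, path_nodes)))
  node_lines <- vapply(nodes, function(p) {
    a <- if (p %in% names(moa$mean_activity)) moa$mean_activity[[p]] else 0
    fill <- if (abs(a) < moa$tau_act) "gray90"
      else if (a > 0) "tomato" else "lightblue"
    shape <- if (p %in% moa$flagged) "box"
      else if (p %in% eff) "doublecircle" else "ellipse"
    sprintf("  \"%s\" [shape=%s, style=filled, fillcolor=%s];",
            p, shape, fill)
  }, character(1))
  edges <- character(0)
  if (nrow(pathways) > 0) {
    for (i in seq_len(nrow(pathways))) {
      nd <- strsplit(pathways$path[i], "->", fixed = TRUE)[[1]]
      sg <- strsplit(pathways$edge_signs[i], "")[[1]]
      edges <- c(edges, sprintf(
        "  \"%s\" -> \"%s\" [arrowhead=%s];",
        nd[-length(nd)], nd[-1], ifelse(sg == "+", "vee", "tee")))
    }
    edges <- sort(unique(edges))
  }
  paste(c(sprintf("digraph \"%s: %s\" {", moa$drug, moa$process),
          "  rankdir=LR;", node_lines, edges, "}"),
        collapse = "\n")
}

#' Write MoA summary and pathway tables
#'
#' @param moa a [build_moa()] result.
#' @param pathways an [extract_pathways()] result.
#' @param summary_path,pathway_path,dot_path output paths (`NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_moa <- function(moa, pathways, summary_path = NULL,
                      pathway_path = NULL, dot_path = NULL) {
  written <- list()
  if (!is.null(summary_path)) {
    n_present <- rowSums(abs(moa$activity) >= moa$tau_act)
    utils::write.table(
      data.frame(protein = names(moa$mean_activity),
                 mean_activity = moa$mean_activity,
                 n_solutions_present = n_present),
      summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written$summary <- summary_path
  }
  if (!is.null(pathway_path)) {
    utils::write.table(as.data.frame(pathways), pathway_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written$pathways <- pathway_path
  }
  if (!is.null(dot_path)) {
    writeLines(export_dot(moa, pathways), dot_path)
    written$dot <- dot_path
  }
  invisible(written)
}
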