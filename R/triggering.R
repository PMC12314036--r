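#' Shortest directed distances from a protein to process effectors
#'
#' Distance is the number of interactions on the shortest directed path
#' following edge direction (signal flows downstream from the stimulated
#' protein): directly related proteins are at distance 1, proteins related
#' through one intermediate at distance 2, and so on. Unreachable effectors
#' are omitted; an effector equal to the source gets distance 0 (it is
#' excluded from the distance-1..3 scoring tiers).
#'
#' @param net an [interactome()].
#' @param source protein identifier present in `net`.
#' @param effs an [effector_set()].
#' @param mode `"out"` follows edge direction (default); `"all"` is an
#'   undirected fallback.
#' @return named numeric vector of distances, one entry per reachable
#'   effector.
#' @export
effector_distances <- function(net, source, effs, mode = c("out", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(effs, "effector_set"))
  if (!source %in% net$proteins)
    stop("unknown source protein: ", source)
  g <- as_igraph(net)
  targets <- intersect(effs$effectors$protein, net$proteins)
  if (length(targets) == 0) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(g, v = source, to = targets, mode = mode,
                         weights = NA)
  out <- stats::setNames(as.numeric(d[1, ]), colnames(d))
  out[is.finite(out)]
}

#' Raw distance-weighted triggering score
#'
#' Scores one protein's capacity to evoke a pathophysiological process when
#' clamped inhibited (`-1`) or activated (`+1`). Per ensemble solution the
#' clamp is propagated and every effector at directed distance 1, 2 or 3
#' whose resulting activity carries the effector's expected sign with
#' magnitude at least `tau_act` contributes its proximity weight
#' (`weights[d]`, closer effectors weighing more). The score is the mean of
#' these per-solution sums over the universe of solutions.
#'
#' @param net an [interactome()].
#' @param ensemble a `solution_ensemble`.
#' @param source the protein under evaluation.
#' @param mode `"inhibited"` clamps the source at `-1`, `"activated"` at
#'   `+1`.
#' @param effs an [effector_set()].
#' @param weights proximity weights for distances 1..3 (default
#'   `c(1, 1/2, 1/3)`).
#' @param distance_mode `"out"` (directed, default) or `"all"` (undirected
#'   fallback) for the distance computation.
#' @return a non-negative number.
#' @export
raw_triggering_score <- function(net, ensemble, source,
                                 mode = c("inhibited", "activated"), effs,
                                 weights = c(1, 1 / 2, 1 / 3),
                                 distance_mode = "out") {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "solution_ensemble"), length(weights) == 3)
  if (nrow(effs$effectors) == 0) stop("empty effector set")
  clamp <- stats::setNames(if (mode == "inhibited") -1 else 1, source)
  d <- effector_distances(net, source, effs, mode = distance_mode)
  d <- d[d >= 1 & d <= 3]
  if (length(d) == 0) return(0)
  vsign <- stats::setNames(effs$effectors$sign, effs$effectors$protein)
  per_sol <- vapply(ensemble$solutions, function(s) {
    y <- propagate(net, s$params, clamp)
    hit <- sign(y[names(d)]) == vsign[names(d)] &
      abs(y[names(d)]) >= s$params$tau_act
    sum(weights[d[hit]])
  }, numeric(1))
  mean(per_sol)
}

#' Full triggering table for a set of proteins and processes
#'
#' Computes, for every (protein, process) pair, the raw inhibited and
#' activated scores, their per-process normalized versions, the difference
#' `score(inhibited) - score(activated)` and the trigger flag
#' (difference strictly greater than `threshold`). The difference isolates
#' proteins whose *inhibition*, rather than overall modulation, evokes the
#' process — the relevant direction for an inhibitor's off-targets.
#'
#' @param net an [interactome()].
#' @param ensemble a `solution_ensemble`.
#' @param proteins character vector of proteins to evaluate (typically a
#'   drug's targets and off-targets).
#' @param processes a named list of [effector_set()]s.
#' @param threshold trigger classification threshold on the normalized
#'   difference (default 0.2).
#' @param weights,distance_mode see [raw_triggering_score()].
#' @return a data frame of class `triggering_table` with columns `protein`,
#'   `process`, `raw_inhibited`, `raw_activated`, `score_inhibited`,
#'   `score_activated`, `difference`, `triggered`.
#' @export
triggering_table <- function(net, ensemble, proteins, processes,
                             threshold = 0.2, weights = c(1, 1 / 2, 1 / 3),
                             distance_mode = "out") {
  stopifnot(is.list(processes), length(processes) >= 1,
            !is.null(names(processes)))
  rows <- list()
  for (pn in names(processes)) {
    effs <- processes[[pn]]
    for (p in proteins) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = p, process = pn,
        raw_inhibited = raw_triggering_score(net, ensemble, p, "inhibited",
                                             effs, weights, distance_mode),
        raw_activated = raw_triggering_score(net, ensemble, p, "activated",
                                             effs, weights, distance_mode),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- normalize_scores(tab)
  tab$difference <- tab$score_inhibited - tab$score_activated
  tab$triggered <- tab$difference > threshold
  class(tab) <- c("triggering_table", "data.frame")
  attr(tab, "threshold") <- threshold
  tab
}

#' Normalize raw triggering scores by the per-process maximum
#'
#' Within each process, both the inhibited and activated raw scores are
#' divided by the maximum raw score observed across all evaluated proteins
#' and both modes, so normalized scores lie in `[0, 1]` and the best-scoring
#' cell of each process is exactly 1. A process whose scores are all zero
#' passes through unchanged.
#'
#' @param tab data frame with columns `protein`, `process`, `raw_inhibited`,
#'   `raw_activated`.
#' @return the table with `score_inhibited` and `score_activated` columns
#'   added (or refreshed).
#' @export
normalize_scores <- function(tab) {
  stopifnot(all(c("process", "raw_inhibited", "raw_activated") %in% names(tab)))
  tab$score_inhibited <- tab$raw_inhibited
  tab$score_activated <- tab$raw_activated
  for (pn in unique(tab$process)) {
    i <- tab$process == pn
    mx <- max(tab$raw_inhibited[i], tab$raw_activated[i])
    if (mx > 0) {
      tab$score_inhibited[i] <- tab$raw_inhibited[i] / mx
      tab$score_activated[i] <- tab$raw_activated[i] / mx
    }
  }
  tab
}

#' Classify triggering proteins
#'
#' Flags exactly the (protein, process) cells whose score difference
#' `score(inhibited) - score(activated)` is strictly greater than
#' `threshold`. Works on any table with `protein`, `process` and
#' `difference` columns, so externally reported difference matrices can be
#' classified directly.
#'
#' @param tab a [triggering_table()] or any data frame with columns
#'   `protein`, `process`, `difference`.
#' @param threshold classification threshold (default 0.2).
#' @return data frame with columns `protein` and `process`, one row per
#'   flagged cell, ordered as in the input.
#' @export
classify_triggers <- function(tab, threshold = 0.2) {
  stopifnot(all(c("protein", "process", "difference") %in% names(tab)))
  out <- tab[tab$difference > threshold, c("protein", "process")]
  rownames(out) <- NULL
  out
}

#' Write a triggering table to TSV
#'
#' One row per (protein, process) with raw and normalized scores, the
#' difference, and the trigger flag; a `drug` tag column (e.g. `I`, `A`,
#' `I/A`) can be supplied to mirror the usual reporting layout.
#'
#' @param tab a [triggering_table()].
#' @param path output path.
#' @param drug_tags optional named character vector protein -> tag.
#' @return `path`, invisibly.
#' @export
write_triggering_table <- function(tab, path, drug_tags = NULL) {
  out <- as.data.frame(tab)
  if (!is.null(drug_tags)) out$drug <- unname(drug_tags[out$protein])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
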