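#' tSignal of an activity vector against a process definition
#'
#' The tSignal summarizes how a stimulus's propagated activity aligns with a
#' process definition:
#' \deqn{tSignal = -\frac{1}{n}\sum_{i=1}^{n} v_i y_i}
#' where the sum runs over the n process effectors, `v_i` is the activity
#' sign expected for effector i when the process is active, and `y_i` the
#' predicted activity reaching it. The leading minus sign means full
#' concordance (`y = v`) gives -1; the negated quantity
#' ([induction_signal()]) therefore reads as "signal over the process" and
#' is positive when the stimulus drives the process. Both scales are
#' reported downstream. Effectors missing from `y` are treated as activity
#' 0 and noted via a message.
#'
#' @param y named numeric activity vector (see [propagate()]).
#' @param effs a non-empty [effector_set()].
#' @return a number in `[-1, 1]`.
#' @export
#' @examples
#' effs <- effector_set("proc", data.frame(protein = c("A", "B"),
#'                                         sign = c(1, -1)))
#' tsignal(c(A = 0.6, B = 0.2), effs)  # -0.2
tsignal <- function(y, effs) {
  stopifnot(inherits(effs, "effector_set"))
  e <- effs$effectors
  if (nrow(e) == 0) stop("empty effector set")
  yi <- y[e$protein]
  if (anyNA(yi)) {
    message("tsignal: ", sum(is.na(yi)),
            " effector(s) missing from the activity vector, treated as 0")
    yi[is.na(yi)] <- 0
  }
  -mean(e$sign * yi)
}

#' Induction signal (negated tSignal)
#'
#' @inheritParams tsignal
#' @return `-tsignal(y, effs)`: positive when the stimulus drives the
#'   process.
#' @export
induction_signal <- function(y, effs) -tsignal(y, effs)

#' Cotreatment interference on a process (Diff Effect)
#'
#' For every ensemble solution, computes the tSignal of the drug alone
#' (its targets clamped per their actions: inhibit `-1`, activate `+1`) and
#' of the drug plus cotreatment (both clamp sets combined), against one
#' process definition. The reported Diff Effect is the change in induction
#' signal, `(-tSignal combined) - (-tSignal alone)`: negative when the
#' cotreatment reduces the drug's signal over the process, positive when it
#' increases it. Raw tSignal samples on both arms are kept for the
#' statistical layer.
#'
#' @param net an [interactome()].
#' @param ensemble a `solution_ensemble`.
#' @param drug the base [drug_profile()] (e.g. the BTK inhibitor).
#' @param cotx the cotreatment-class [drug_profile()]; an empty target set
#'   yields differences exactly 0.
#' @param effs an [effector_set()].
#' @return an object of class `interference_result` (pre-statistics): list
#'   with `cotx`, `process`, per-solution `tsignal_alone`,
#'   `tsignal_combined`, `diff` (induction scale) and `mean_diff`.
#' @export
diff_effect <- function(net, ensemble, drug, cotx, effs) {
  stopifnot(inherits(ensemble, "solution_ensemble"))
  for (obj in list(drug, cotx)) {
    missing <- validate_against_network(obj, net)
    if (length(missing))
      stop("profile '", obj$name, "' protein(s) not in network: ",
           paste(missing, collapse = ", "))
  }
  base <- profile_clamps(drug)
  extra <- profile_clamps(cotx)
  shared <- intersect(names(base), names(extra))
  conflict <- shared[base[shared] != extra[shared]]
  if (length(conflict))
    stop("conflicting clamp direction for protein(s): ",
         paste(conflict, collapse = ", "))
  combined <- c(base, extra[setdiff(names(extra), names(base))])
  ts_alone <- vapply(ensemble$solutions, function(s)
    tsignal(propagate(net, s$params, base), effs), numeric(1))
  ts_comb <- vapply(ensemble$solutions, function(s)
    tsignal(propagate(net, s$params, combined), effs), numeric(1))
  diff <- ts_alone - ts_comb  # induction scale: -(ts_comb) - -(ts_alone)
  structure(list(cotx = cotx$name, process = effs$process_name,
                 tsignal_alone = ts_alone, tsignal_combined = ts_comb,
                 diff = diff, mean_diff = mean(diff)),
            class = "interference_result")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper over the standard Mann-Whitney/Wilcoxon rank-sum test:
#' exact enumeration when both samples have at most 20 values and no ties,
#' normal approximation with tie and continuity correction otherwise. Two
#' identical constant samples carry no evidence and return p = 1.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  exact <- length(a) <= 20 && length(b) <= 20 && !anyDuplicated(pooled)
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (via [stats::p.adjust()]): monotone,
#' capped at 1, invariant under input reordering.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Screen cotreatment classes for interference with drug-evoked processes
#'
#' Runs [diff_effect()] for every (cotreatment class, process) pair, tests
#' each pair's combined-vs-alone tSignal samples with the Wilcoxon rank-sum
#' test (or the per-solution differences against zero with
#' `paired = TRUE`), applies Benjamini-Hochberg correction across the whole
#' screen, and flags interference when `q <= alpha` and
#' `|mean Diff Effect| > diff_threshold`.
#'
#' @param net an [interactome()].
#' @param ensemble a `solution_ensemble`.
#' @param drug the base [drug_profile()].
#' @param cotx_classes named list of cotreatment [drug_profile()]s (>= 1).
#' @param processes named list of [effector_set()]s.
#' @param alpha FDR level (default 0.05).
#' @param diff_threshold minimum absolute Diff Effect (default 0.05).
#' @param paired use a signed-rank test of per-solution differences against
#'   zero instead of the two-sample rank-sum (default `FALSE`).
#' @return data frame of class `interference_screen` with one row per
#'   (class, process): mean tSignals on both arms, `diff_effect`, `p`, `q`,
#'   `flag`; sorted by `q` then decreasing `|diff_effect|`.
#' @export
interference_screen <- function(net, ensemble, drug, cotx_classes, processes,
                                alpha = 0.05, diff_threshold = 0.05,
                                paired = FALSE) {
  stopifnot(length(cotx_classes) >= 1, length(processes) >= 1,
            !is.null(names(processes)))
  if (is.null(names(cotx_classes)))
    names(cotx_classes) <- vapply(cotx_classes, `[[`, character(1), "name")
  rows <- list()
  for (cn in names(cotx_classes)) {
    for (pn in names(processes)) {
      r <- diff_effect(net, ensemble, drug, cotx_classes[[cn]],
                       processes[[pn]])
      p <- if (paired) {
        if (all(r$diff == 0)) 1 else suppressWarnings(
          stats::wilcox.test(r$diff, alternative = "two.sided",
                             exact = length(r$diff) <= 20 &&
                               !anyDuplicated(abs(r$diff)))$p.value)
      } else {
        rank_sum_test(r$tsignal_combined, r$tsignal_alone)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug$name, cotreatment = cn, process = pn,
        mean_tsignal_alone = mean(r$tsignal_alone),
        mean_tsignal_combined = mean(r$tsignal_combined),
        diff_effect = r$mean_diff, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$flag <- out$q <= alpha & abs(out$diff_effect) > diff_threshold
  out <- out[order(out$q, -abs(out$diff_effect)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interference_screen", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "diff_threshold") <- diff_threshold
  out
}
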