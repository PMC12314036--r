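#' Bundled BTK-inhibitor triggering-difference matrices
#'
#' Curated `score(inhibited) - score(activated)` difference matrices for the
#' targets and off-targets of ibrutinib and acalabrutinib, against the
#' pathophysiological processes of atrial fibrillation and of hypertension,
#' as reported in a published in-silico triggering analysis of the two
#' inhibitors. Bundled as a worked example for the classification rule:
#' feeding either matrix to [classify_triggers()] at the standard 0.2
#' threshold reproduces the reported trigger calls.
#'
#' @param condition `"af"` (atrial fibrillation, five processes) or
#'   `"hypertension"` (four processes).
#' @return a long-format data frame with columns `protein`, `process`,
#'   `difference` and `drug` (`I` ibrutinib, `A` acalabrutinib, `I/A`
#'   both), suitable for [classify_triggers()].
#' @export
#' @examples
#' classify_triggers(btki_difference_table("af"), threshold = 0.2)
btki_difference_table <- function(condition = c("af", "hypertension")) {
  condition <- match.arg(condition)
  path <- system.file("extdata",
                      paste0(condition, "_triggering_differences.tsv"),
                      package = "triggernet", mustWork = TRUE)
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  procs <- setdiff(names(wide), c("protein", "drug"))
  long <- do.call(rbind, lapply(procs, function(pn)
    data.frame(protein = wide$protein, process = pn,
               difference = wide[[pn]], drug = wide$drug,
               stringsAsFactors = FALSE)))
  long <- long[order(match(long$protein, wide$protein),
                     match(long$process, procs)), , drop = FALSE]
  rownames(long) <- NULL
  long
}
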