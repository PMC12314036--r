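#' Drug target profile
#'
#' A drug (or drug class) is modelled by the set of proteins it binds, the
#' direction of the pharmacological action on each (`inhibit` or `activate`),
#' an optional binding potency (IC50, nM), and a role tag separating the
#' intended primary target(s) from off-targets. Off-target selection in the
#' upstream curation typically keeps proteins bound with IC50 < 500 nM or
#' reported in regulatory documents without a published IC50; see
#' [filter_offtargets()].
#'
#' @param name drug or drug-class name.
#' @param targets data frame with columns `protein`, `action` (`"inhibit"` or
#'   `"activate"`); optional columns `ic50_nM` (positive or `NA`), `role`
#'   (`"primary_target"` or `"off_target"`, default `"off_target"`) and
#'   `regulatory` (logical: sourced from a regulatory document with no IC50).
#' @return an object of class `drug_profile`.
#' @export
drug_profile <- function(name, targets) {
  stopifnot(is.character(name), length(name) == 1, is.data.frame(targets))
  if (nrow(targets) > 0 && !all(c("protein", "action") %in% names(targets)))
    stop("targets must have columns 'protein' and 'action'")
  t <- targets
  t$protein <- as.character(t$protein)
  t$action <- as.character(t$action)
  if (!all(t$action %in% c("inhibit", "activate")))
    stop("action must be 'inhibit' or 'activate'")
  if (is.null(t$ic50_nM)) t$ic50_nM <- rep(NA_real_, nrow(t))
  if (is.null(t$role)) t$role <- rep("off_target", nrow(t))
  if (is.null(t$regulatory)) t$regulatory <- rep(FALSE, nrow(t))
  if (!all(t$role %in% c("primary_target", "off_target")))
    stop("role must be 'primary_target' or 'off_target'")
  if (any(!is.na(t$ic50_nM) & t$ic50_nM <= 0))
    stop("ic50_nM must be positive")
  if (anyDuplicated(t$protein))
    stop("duplicate target protein(s) in profile '", name, "': ",
         paste(unique(t$protein[duplicated(t$protein)]), collapse = ", "))
  structure(list(name = name,
                 targets = t[, c("protein", "action", "ic50_nM", "role",
                                 "regulatory")]),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat("drug_profile '", x$name, "': ", nrow(x$targets), " targets (",
      sum(x$targets$role == "primary_target"), " primary)\n", sep = "")
  invisible(x)
}

#' Pathophysiological-process effector set
#'
#' A pathophysiological process (e.g. "structural remodeling & atrial
#' fibrosis" within atrial fibrillation) is defined molecularly as the set of
#' its protein effectors, each with the activity sign expected when the
#' process is active: `+1` if the protein drives the process when active,
#' `-1` if loss of activity does.
#'
#' @param process_name name of the process.
#' @param effectors data frame with columns `protein` and `sign` (`+1`/`-1`).
#' @return an object of class `effector_set`.
#' @export
effector_set <- function(process_name, effectors) {
  stopifnot(is.character(process_name), length(process_name) == 1,
            is.data.frame(effectors), nrow(effectors) >= 1)
  e <- effectors
  e$protein <- as.character(e$protein)
  e$sign <- normalize_sign(e$sign)
  if (anyDuplicated(e$protein))
    stop("duplicate effector protein(s) in process '", process_name, "'")
  structure(list(process_name = process_name,
                 effectors = e[, c("protein", "sign")]),
            class = "effector_set")
}

#' @export
print.effector_set <- function(x, ...) {
  cat("effector_set '", x$process_name, "': ", nrow(x$effectors),
      " effectors\n", sep = "")
  invisible(x)
}

#' Literature-described drug response set
#'
#' Proteins reported in the literature to be modulated downstream of a drug
#' (up- or down-regulated), without being direct targets. Used only for
#' post-hoc agreement scoring of mechanism-of-action models
#' ([literature_agreement()]), never for training.
#'
#' @param drug drug name.
#' @param entries data frame with columns `protein` and `direction`
#'   (`+1` up, `-1` down).
#' @return an object of class `literature_set`.
#' @export
literature_set <- function(drug, entries) {
  stopifnot(is.character(drug), length(drug) == 1, is.data.frame(entries))
  e <- entries
  e$protein <- as.character(e$protein)
  e$direction <- normalize_sign(e$direction)
  if (anyDuplicated(e$protein))
    stop("duplicate protein(s) in literature set for '", drug, "'")
  structure(list(drug = drug, entries = e[, c("protein", "direction")]),
            class = "literature_set")
}

#' Stimulus-response truth table
#'
#' The training data for the propagation model: each constraint clamps a
#' stimulus (one or more proteins at `+1`/`-1`) and requires a response
#' protein to end up with a given activity sign. Model accuracy is the
#' fraction of constraints satisfied ([model_accuracy()]).
#'
#' @param constraints a list; each element has `stimulus` (named numeric
#'   vector of `+1`/`-1` clamp values, names are proteins), `response`
#'   (protein) and `sign` (`+1`/`-1`).
#' @return an object of class `truth_table`.
#' @export
truth_table <- function(constraints) {
  stopifnot(is.list(constraints), length(constraints) >= 1)
  constraints <- lapply(constraints, function(k) {
    stopifnot(!is.null(k$stimulus), !is.null(k$response), !is.null(k$sign))
    stim <- k$stimulus
    if (is.null(names(stim)) || any(!nzchar(names(stim))))
      stop("constraint stimulus must be a named vector of clamp values")
    if (!all(stim %in% c(-1, 1)))
      stop("clamp values must be +1 or -1")
    list(stimulus = stim, response = as.character(k$response),
         sign = as.integer(k$sign))
  })
  structure(list(constraints = constraints), class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", length(x$constraints), "stimulus-response constraints\n")
  invisible(x)
}

#' Filter a target profile by binding potency
#'
#' Retains targets bound with IC50 strictly below `threshold_nM`, plus
#' targets with no recorded IC50 that are flagged as sourced from a
#' regulatory document (an EPAR-style report): curation keeps a protein on
#' either criterion. The operation is idempotent and monotone in the
#' threshold, and preserves the original target ordering.
#'
#' @param profile a [drug_profile()].
#' @param threshold_nM positive potency cut-off in nM (default 500).
#' @return a filtered [drug_profile()]; possibly with zero targets.
#' @export
#' @examples
#' p <- drug_profile("drugX", data.frame(
#'   protein = c("A", "B", "C"), action = "inhibit",
#'   ic50_nM = c(100, 800, NA), regulatory = c(FALSE, FALSE, TRUE)))
#' filter_offtargets(p)$targets$protein  # "A" and "C"
filter_offtargets <- function(profile, threshold_nM = 500) {
  stopifnot(inherits(profile, "drug_profile"), threshold_nM > 0)
  t <- profile$targets
  keep <- (!is.na(t$ic50_nM) & t$ic50_nM < threshold_nM) |
    (is.na(t$ic50_nM) & t$regulatory)
  out <- profile
  out$targets <- t[keep, , drop = FALSE]
  rownames(out$targets) <- NULL
  out
}

#' Check that an object's proteins are present in a network
#'
#' @param obj a [drug_profile()], [effector_set()], [literature_set()] or
#'   [truth_table()].
#' @param net an [interactome()].
#' @return character vector of identifiers absent from the network (empty
#'   when fully mapped).
#' @export
validate_against_network <- function(obj, net) {
  stopifnot(inherits(net, "interactome"))
  prot <- if (inherits(obj, "drug_profile")) {
    obj$targets$protein
  } else if (inherits(obj, "effector_set")) {
    obj$effectors$protein
  } else if (inherits(obj, "literature_set")) {
    obj$entries$protein
  } else if (inherits(obj, "truth_table")) {
    unique(unlist(lapply(obj$constraints,
                         function(k) c(names(k$stimulus), k$response))))
  } else stop("unsupported object of class ", paste(class(obj), collapse = "/"))
  setdiff(unique(prot), net$proteins)
}

# ---- JSON serialization -----------------------------------------------------

SCHEMA_VERSION <- "1.0"

#' Write a domain object to JSON
#'
#' Drug profiles, effector sets, literature sets and truth tables share a
#' JSON envelope with an explicit `schema` version and a `type` tag, so files
#' are self-describing.
#'
#' @param obj the object to serialize.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_json <- function(obj, path) {
  type <- intersect(class(obj), c("drug_profile", "effector_set",
                                  "literature_set", "truth_table"))
  if (length(type) == 0) stop("unsupported object")
  payload <- unclass(obj)
  if (type == "truth_table") {
    payload$constraints <- lapply(payload$constraints, function(k)
      list(stimulus = as.list(k$stimulus), response = k$response,
           sign = k$sign))
  }
  jsonlite::write_json(list(schema = SCHEMA_VERSION, type = type,
                            data = payload),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a domain object from JSON
#'
#' @param path a file written by [write_profile_json()].
#' @return the deserialized object.
#' @export
read_profile_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  if (is.null(raw$type)) stop("not a recognized profile JSON: ", path)
  d <- raw$data
  if (raw$type == "truth_table") {
    # stimuli have heterogeneous keys, so they must not be column-simplified
    d <- jsonlite::read_json(path, simplifyVector = FALSE)$data
    return(truth_table(lapply(d$constraints, function(k)
      list(stimulus = unlist(k$stimulus), response = k$response,
           sign = k$sign))))
  }
  switch(raw$type,
    drug_profile = drug_profile(d$name, as.data.frame(d$targets)),
    effector_set = effector_set(d$process_name, as.data.frame(d$effectors)),
    literature_set = literature_set(d$drug, as.data.frame(d$entries)),
    stop("unknown profile type: ", raw$type))
}
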