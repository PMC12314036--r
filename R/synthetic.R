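#' Specification of a synthetic benchmark with planted ground truth
#'
#' The generator emulates the structures the real analysis consumes: a
#' scale-free signed interactome, pathophysiological processes defined by
#' effector sets reachable from drug targets within three steps, two
#' inhibitor profiles with shared and drug-A-specific off-targets (the
#' two-inhibitor asymmetry), antagonist and null cotreatment classes, and a
#' stimulus-response truth table recorded from a planted parameterization —
#' so a fully compliant solution is guaranteed to exist and every designated
#' inducer satisfies the triggering decision rule under the planted model.
#'
#' @param n_proteins total number of proteins (default 200).
#' @param attachment preferential-attachment power for the scale-free
#'   backbone (default 1).
#' @param p_inhibit probability that an edge is inhibiting (default 0.3).
#' @param n_processes number of pathophysiological processes (default 3).
#' @param effectors_per_process effectors per process (default 6; at least
#'   `2 * inducers_per_process`).
#' @param n_shared_offtargets off-targets shared by both drugs (default 2).
#' @param n_specific_offtargets off-targets specific to drug A (default 4).
#' @param inducers_per_process designated inducer off-targets per process
#'   (default 2).
#' @param n_constraints total truth-table constraints (default 30; must be
#'   at least the number of planted path-pinning constraints).
#' @param seed integer seed.
#' @return a list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_proteins = 200, attachment = 1, p_inhibit = 0.3,
                           n_processes = 3, effectors_per_process = 6,
                           n_shared_offtargets = 2, n_specific_offtargets = 4,
                           inducers_per_process = 2, n_constraints = 30,
                           seed = 1) {
  spec <- list(n_proteins = n_proteins, attachment = attachment,
               p_inhibit = p_inhibit, n_processes = n_processes,
               effectors_per_process = effectors_per_process,
               n_shared_offtargets = n_shared_offtargets,
               n_specific_offtargets = n_specific_offtargets,
               inducers_per_process = inducers_per_process,
               n_constraints = n_constraints, seed = as.integer(seed))
  counts <- spec[c("n_proteins", "n_processes", "effectors_per_process",
                   "n_shared_offtargets", "n_specific_offtargets",
                   "inducers_per_process", "n_constraints")]
  if (any(unlist(counts) < 1)) stop("all counts must be >= 1")
  if (p_inhibit < 0 || p_inhibit > 1) stop("p_inhibit must be in [0, 1]")
  if (effectors_per_process < 2 * inducers_per_process)
    stop("spec infeasible: need effectors_per_process >= 2 * ",
         "inducers_per_process")
  n_special <- n_processes * effectors_per_process +          # effectors
    n_processes * inducers_per_process +                      # relays
    n_processes                                               # antagonists
  n_targets <- 1 + n_shared_offtargets + n_specific_offtargets
  if (n_proteins - n_special < 4 * n_targets)
    stop("spec infeasible: too few proteins for ", n_special,
         " planted nodes plus a backbone holding ", n_targets, " targets")
  structure(spec, class = "benchmark_spec")
}

#' Generate a synthetic benchmark with planted ground truth
#'
#' Deterministic given `spec$seed`. The construction:
#' \enumerate{
#'   \item A scale-free backbone (preferential attachment, random edge
#'     orientation, inhibiting signs with probability `p_inhibit`).
#'   \item Drug targets placed on backbone nodes pairwise at directed
#'     distance at least 3 (both directions), so no target sits inside
#'     another target's 3-step triggering horizon.
#'   \item For each process, `inducers_per_process` off-targets are
#'     designated inducers; each gets two dedicated effectors, one at
#'     distance 1 and one at distance 2 through a dedicated relay, with
#'     expected signs chosen so that clamping the inducer at -1 yields the
#'     expected effector sign. Non-inducer targets have no directed path of
#'     length <= 3 to any effector, so the planted triggering classification
#'     is exact by construction.
#'   \item One antagonist cotreatment class per process: a fresh protein
#'     wired into the planted effectors with signs that push them against
#'     their expected direction when the antagonist is inhibited.
#'   \item A planted parameterization (magnitude 0.95 on planted edges,
#'     uniform `[0.5, 1]` elsewhere); the truth table records its
#'     propagation outcomes — pinning every planted inducer and antagonist
#'     path, plus random stimulus-response constraints up to
#'     `n_constraints` — so a 100\%-compliant solution exists.
#' }
#'
#' @param spec a [benchmark_spec()].
#' @return a list of class `benchmark`: `network`, `processes` (named list
#'   of [effector_set()]), `drugs` (`drugA` superset profile, `drugB`),
#'   `cotreatments` (antagonist classes plus a null class), `truth`
#'   ([truth_table()]) and `planted` (ground truth: `params`, `inducers`
#'   data frame, `antagonists`, `spec`).
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "benchmark_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  n_eff <- spec$n_processes * spec$effectors_per_process
  n_rel <- spec$n_processes * spec$inducers_per_process
  n_core <- spec$n_proteins - n_eff - n_rel - spec$n_processes
  core <- sprintf("P%04d", seq_len(n_core))

  # scale-free backbone, randomly oriented, signed
  g0 <- igraph::sample_pa(n_core, power = spec$attachment, m = 2,
                          directed = FALSE)
  el <- igraph::as_edgelist(g0, names = FALSE)
  flip <- stats::runif(nrow(el)) < 0.5
  el[flip, ] <- el[flip, 2:1]
  edges <- data.frame(
    from = core[el[, 1]], to = core[el[, 2]],
    sign = ifelse(stats::runif(nrow(el)) < spec$p_inhibit, -1L, 1L),
    annotation = "backbone", stringsAsFactors = FALSE)
  edges <- edges[edges$from != edges$to, ]

  # place targets pairwise >= 3 apart (directed, both ways)
  n_targets <- 1 + spec$n_shared_offtargets + spec$n_specific_offtargets
  gc <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE,
                                      vertices = data.frame(name = core))
  cand <- sample(core)
  targets <- character(0)
  for (v in cand) {
    if (length(targets) == n_targets) break
    if (length(targets) == 0) {
      targets <- v
      next
    }
    d_out <- igraph::distances(gc, v = v, to = targets, mode = "out",
                               weights = NA)
    d_in <- igraph::distances(gc, v = v, to = targets, mode = "in",
                              weights = NA)
    if (all(pmin(d_out, d_in) >= 3)) targets <- c(targets, v)
  }
  if (length(targets) < n_targets)
    stop("spec infeasible: could not place ", n_targets,
         " targets pairwise at directed distance >= 3; ",
         "use a larger network")
  primary <- targets[1]
  shared <- targets[1 + seq_len(spec$n_shared_offtargets)]
  specific <- targets[1 + spec$n_shared_offtargets +
                        seq_len(spec$n_specific_offtargets)]
  offtargets <- c(shared, specific)

  # designated inducers and planted effector wiring
  proc_names <- sprintf("process_%d", seq_len(spec$n_processes))
  eff_names <- rel_names <- ant_names <- character(0)
  processes <- list()
  inducer_rows <- list()
  planted_edges <- list()
  planted_mag <- 0.95
  for (ip in seq_len(spec$n_processes)) {
    pn <- proc_names[ip]
    inducers <- sample(offtargets, spec$inducers_per_process)
    effs <- sprintf("EFF_%02d_%02d", ip, seq_len(spec$effectors_per_process))
    rels <- sprintf("REL_%02d_%02d", ip, seq_len(spec$inducers_per_process))
    ant <- sprintf("ANT_%02d", ip)
    eff_names <- c(eff_names, effs)
    rel_names <- c(rel_names, rels)
    ant_names <- c(ant_names, ant)
    vsign <- integer(spec$effectors_per_process)
    used <- 0L
    for (ii in seq_along(inducers)) {
      ind <- inducers[ii]
      e1 <- effs[used + 1L]
      e2 <- effs[used + 2L]
      used <- used + 2L
      s1 <- sample(c(-1L, 1L), 1)                       # inducer -> e1
      s2a <- sample(c(-1L, 1L), 1)                      # inducer -> relay
      s2b <- sample(c(-1L, 1L), 1)                      # relay -> e2
      # clamping the inducer at -1 propagates sign -s along a path whose
      # edge-sign product is s; the expected sign is defined accordingly
      vsign[used - 1L] <- -s1
      vsign[used] <- -(s2a * s2b)
      planted_edges[[length(planted_edges) + 1L]] <- data.frame(
        from = c(ind, ind, rels[ii]), to = c(e1, rels[ii], e2),
        sign = c(s1, s2a, s2b), annotation = "planted",
        stringsAsFactors = FALSE)
      inducer_rows[[length(inducer_rows) + 1L]] <- data.frame(
        protein = ind, process = pn, effector_1 = e1, effector_2 = e2,
        stringsAsFactors = FALSE)
    }
    planted_eff <- effs[seq_len(used)]
    # antagonist: inhibiting-clamped, it pushes planted effectors to -v
    planted_edges[[length(planted_edges) + 1L]] <- data.frame(
      from = ant, to = planted_eff, sign = vsign[seq_len(used)],
      annotation = "antagonist", stringsAsFactors = FALSE)
    # spare effectors hang off backbone nodes outside every target's
    # 3-step horizon (or stay isolated if none exists)
    spare <- if (used < length(effs)) effs[(used + 1L):length(effs)] else
      character(0)
    if (length(spare)) {
      d_from_targets <- igraph::distances(gc, v = targets, to = core,
                                          mode = "out", weights = NA)
      far <- core[apply(d_from_targets, 2, min) >= 3]
      far <- setdiff(far, targets)
      if (length(far)) {
        src <- sample(far, length(spare), replace = TRUE)
        sg <- sample(c(-1L, 1L), length(spare), replace = TRUE)
        planted_edges[[length(planted_edges) + 1L]] <- data.frame(
          from = src, to = spare, sign = sg, annotation = "spare",
          stringsAsFactors = FALSE)
        vsign[effs %in% spare] <- sample(c(-1L, 1L), length(spare),
                                         replace = TRUE)
      } else {
        vsign[effs %in% spare] <- 1L
      }
    }
    processes[[pn]] <- effector_set(pn, data.frame(protein = effs,
                                                   sign = vsign))
  }

  all_proteins <- c(core, eff_names, rel_names, ant_names)
  edges <- rbind(edges, do.call(rbind, planted_edges))
  net <- interactome(edges, proteins = all_proteins)
  inducers <- do.call(rbind, inducer_rows)

  # drug profiles: drug A carries the shared plus A-specific off-targets,
  # drug B only the shared ones (superset/subset asymmetry)
  mk_targets <- function(prot) {
    data.frame(protein = prot, action = "inhibit",
               ic50_nM = c(1, round(stats::runif(length(prot) - 1, 5, 450))),
               role = c("primary_target", rep("off_target", length(prot) - 1)),
               regulatory = FALSE, stringsAsFactors = FALSE)
  }
  drugA <- drug_profile("drugA", mk_targets(c(primary, shared, specific)))
  drugB <- drug_profile("drugB", mk_targets(c(primary, shared)))

  # planted parameterization
  mag <- stats::runif(nrow(net$edges), 0.5, 1)
  mag[net$edges$annotation %in% c("planted", "antagonist")] <- planted_mag
  params <- model_params(net, mag * net$edges$sign, n_steps = 5,
                         tau_act = 0.05)
  W <- weight_matrix(net, params)

  # truth table: pin every planted inducer and antagonist path, then add
  # random stimulus-response constraints recorded from the planted model
  constraints <- list()
  for (i in seq_len(nrow(inducers))) {
    pn <- inducers$process[i]
    vs <- stats::setNames(processes[[pn]]$effectors$sign,
                          processes[[pn]]$effectors$protein)
    for (e in c(inducers$effector_1[i], inducers$effector_2[i])) {
      constraints[[length(constraints) + 1L]] <- list(
        stimulus = stats::setNames(-1, inducers$protein[i]),
        response = e, sign = vs[[e]])
    }
  }
  for (ip in seq_len(spec$n_processes)) {
    pn <- proc_names[ip]
    vs <- stats::setNames(processes[[pn]]$effectors$sign,
                          processes[[pn]]$effectors$protein)
    pinned <- unique(c(inducers$effector_1[inducers$process == pn],
                       inducers$effector_2[inducers$process == pn]))
    for (e in pinned[seq_len(min(2, length(pinned)))]) {
      constraints[[length(constraints) + 1L]] <- list(
        stimulus = stats::setNames(-1, ant_names[ip]),
        response = e, sign = -vs[[e]])
    }
  }
  n_planted <- length(constraints)
  if (spec$n_constraints < n_planted)
    stop("spec infeasible: n_constraints must be >= ", n_planted,
         " planted constraints")
  tries <- 0
  while (length(constraints) < spec$n_constraints && tries < 1000) {
    tries <- tries + 1
    stim_p <- sample(core, 1)
    stim_v <- sample(c(-1, 1), 1)
    y <- propagate_batch(W, list(stats::setNames(stim_v, stim_p)), 5)[, 1]
    names(y) <- net$proteins
    eligible <- setdiff(names(y)[abs(y) >= 0.1], stim_p)
    eligible <- intersect(eligible, core)
    if (length(eligible) == 0) next
    resp <- sample(eligible, 1)
    constraints[[length(constraints) + 1L]] <- list(
      stimulus = stats::setNames(stim_v, stim_p),
      response = resp, sign = as.integer(sign(y[[resp]])))
  }
  truth <- truth_table(constraints)

  antagonists <- stats::setNames(lapply(seq_len(spec$n_processes), function(ip)
    drug_profile(paste0("antagonist_", proc_names[ip]), data.frame(
      protein = ant_names[ip], action = "inhibit", ic50_nM = 50,
      role = "off_target", regulatory = FALSE))),
    paste0("antagonist_", proc_names))
  null_class <- generate_null_cotreatment(net, processes,
                                          seed = spec$seed + 10000L)

  structure(list(
    network = net, processes = processes,
    drugs = list(drugA = drugA, drugB = drugB),
    cotreatments = c(antagonists, list(null_class = null_class)),
    truth = truth,
    planted = list(params = params, inducers = inducers,
                   antagonists = names(antagonists), spec = spec)),
    class = "benchmark")
}

#' Draw a null cotreatment class
#'
#' Targets are chosen among proteins with no directed path to any process
#' effector, so clamping them cannot move any effector's activity: the Diff
#' Effect of the class is exactly 0 per solution under any parameters.
#'
#' @param net an [interactome()].
#' @param processes named list of [effector_set()]s whose effectors must be
#'   unreachable.
#' @param seed integer seed.
#' @param n_targets number of targets to draw (default 2).
#' @return a [drug_profile()] named `"null_class"`.
#' @export
generate_null_cotreatment <- function(net, processes, seed, n_targets = 2) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  g <- as_igraph(net)
  eff <- unique(unlist(lapply(processes, function(e) e$effectors$protein)))
  eff <- intersect(eff, net$proteins)
  upstream <- unique(unlist(lapply(eff, function(e)
    names(igraph::subcomponent(g, e, mode = "in")))))
  cand <- setdiff(net$proteins, upstream)
  if (length(cand) == 0)
    stop("no protein lacks a directed path to the effectors; ",
         "use a larger network")
  prot <- sample(cand, min(n_targets, length(cand)))
  drug_profile("null_class", data.frame(
    protein = prot, action = "inhibit", ic50_nM = 50,
    role = "off_target", regulatory = FALSE))
}

#' Write every benchmark artifact to a directory
#'
#' Networks go out as TSV, profiles/effector sets/truth table as JSON, and
#' a `benchmark.json` manifest records the spec, seed and planted truth.
#'
#' @param bench a [generate_benchmark()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactome(bench$network, file.path(dir, "network.tsv"), "tsv")
  for (pn in names(bench$processes))
    write_profile_json(bench$processes[[pn]],
                       file.path(dir, paste0(pn, ".json")))
  for (dn in names(bench$drugs))
    write_profile_json(bench$drugs[[dn]], file.path(dir, paste0(dn, ".json")))
  for (cn in names(bench$cotreatments))
    write_profile_json(bench$cotreatments[[cn]],
                       file.path(dir, paste0("cotx_", cn, ".json")))
  write_profile_json(bench$truth, file.path(dir, "truth.json"))
  jsonlite::write_json(list(
    schema = SCHEMA_VERSION,
    spec = unclass(bench$planted$spec),
    inducers = bench$planted$inducers,
    antagonists = bench$planted$antagonists),
    file.path(dir, "benchmark.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
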