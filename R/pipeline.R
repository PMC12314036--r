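#' Configuration for a full analysis run
#'
#' Collects all input paths, thresholds and seeds for
#' [run_full_analysis()]. The configuration is serialized into the output
#' directory for provenance, so every number in a report bundle can be
#' traced to the settings that produced it.
#'
#' @param network path to the interactome (TSV/SIF/GraphML).
#' @param drug path to the drug-profile JSON.
#' @param processes named character vector of effector-set JSON paths.
#' @param truth path to the truth-table JSON.
#' @param cotreatments named character vector of cotreatment-class JSON
#'   paths (may be empty).
#' @param literature optional path to a literature response-set JSON.
#' @param out_dir output directory.
#' @param trigger_threshold triggering classification threshold (default
#'   0.2).
#' @param tau_act activity threshold (default 0.05).
#' @param n_steps propagation steps (default 5).
#' @param n_solutions ensemble size (default 10).
#' @param acceptance_threshold minimum training compliance for ensemble
#'   membership (default 0.9).
#' @param min_support,max_len pathway extraction settings (defaults 0.5, 4).
#' @param alpha,diff_threshold interference screen settings (defaults 0.05,
#'   0.05).
#' @param ic50_threshold off-target potency cut-off in nM (default 500).
#' @param seed base seed for training (default 1).
#' @param sa simulated-annealing settings ([sa_control()]).
#' @return a list of class `run_config`.
#' @export
run_config <- function(network, drug, processes, truth,
                       cotreatments = character(0), literature = NULL,
                       out_dir = "triggernet_run",
                       trigger_threshold = 0.2, tau_act = 0.05, n_steps = 5,
                       n_solutions = 10, acceptance_threshold = 0.9,
                       min_support = 0.5, max_len = 4, alpha = 0.05,
                       diff_threshold = 0.05, ic50_threshold = 500,
                       seed = 1, sa = sa_control()) {
  cfg <- list(network = network, drug = drug, processes = processes,
              truth = truth, cotreatments = cotreatments,
              literature = literature, out_dir = out_dir,
              trigger_threshold = trigger_threshold, tau_act = tau_act,
              n_steps = n_steps, n_solutions = n_solutions,
              acceptance_threshold = acceptance_threshold,
              min_support = min_support, max_len = max_len, alpha = alpha,
              diff_threshold = diff_threshold,
              ic50_threshold = ic50_threshold, seed = as.integer(seed),
              sa = sa)
  thr <- c(cfg$trigger_threshold, cfg$tau_act, cfg$min_support, cfg$alpha,
           cfg$diff_threshold, cfg$ic50_threshold)
  if (any(thr <= 0)) stop("thresholds must be positive")
  paths <- c(network, drug, processes, truth, cotreatments, literature)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (is.null(names(processes)) || any(!nzchar(names(processes))))
    stop("processes must be a named vector of paths")
  structure(cfg, class = "run_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load and filter inputs, train the solution
#' ensemble, compute the triggering table and classification, build MoA
#' models with pathway extraction and DOT export for every (process,
#' flagged set), run the cotreatment interference screen, and score
#' literature agreement if a response set is supplied — writing every table
#' plus a machine-readable run manifest under `config$out_dir`. Idempotent
#' given identical config and seeds; a stage failure aborts with the stage
#' name while earlier outputs are preserved.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`ensemble`,
#'   `triggering`, `flagged`, `moa`, `interference`, `agreement`) and
#'   `out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- run_stage("load", {
    net <- read_interactome(config$network)
    drug <- filter_offtargets(read_profile_json(config$drug),
                              config$ic50_threshold)
    processes <- lapply(config$processes, read_profile_json)
    truth <- read_profile_json(config$truth)
    cotx <- lapply(config$cotreatments, read_profile_json)
    lit <- if (!is.null(config$literature))
      read_profile_json(config$literature) else NULL
    for (obj in c(list(drug, truth), processes)) {
      miss <- validate_against_network(obj, net)
      if (length(miss))
        stop("protein(s) not in network: ", paste(miss, collapse = ", "))
    }
    list(net = net, drug = drug, processes = processes, truth = truth,
         cotx = cotx, lit = lit)
  })

  ensemble <- run_stage("train", {
    ens <- sample_ensemble(inputs$net, inputs$truth,
                           n_solutions = config$n_solutions,
                           acceptance_threshold = config$acceptance_threshold,
                           base_seed = config$seed,
                           n_steps = config$n_steps,
                           tau_act = config$tau_act, control = config$sa)
    write_ensemble(ens, inputs$net, file.path(config$out_dir, "ensemble"))
    ens
  })

  trig <- run_stage("trigger", {
    tab <- triggering_table(inputs$net, ensemble,
                            proteins = inputs$drug$targets$protein,
                            processes = inputs$processes,
                            threshold = config$trigger_threshold)
    write_triggering_table(tab, file.path(config$out_dir, "triggering.tsv"))
    tab
  })
  flagged <- classify_triggers(trig, config$trigger_threshold)

  moas <- run_stage("moa", {
    out <- list()
    for (pn in unique(flagged$process)) {
      fl <- flagged$protein[flagged$process == pn]
      m <- build_moa(inputs$net, ensemble, inputs$drug, fl,
                     inputs$processes[[pn]])
      pw <- extract_pathways(inputs$net, ensemble, m,
                             max_len = config$max_len,
                             min_support = config$min_support)
      write_moa(m, pw,
                summary_path = file.path(config$out_dir,
                                         paste0("moa_", pn, ".tsv")),
                pathway_path = file.path(config$out_dir,
                                         paste0("pathways_", pn, ".tsv")),
                dot_path = file.path(config$out_dir,
                                     paste0("moa_", pn, ".dot")))
      out[[pn]] <- list(model = m, pathways = pw)
    }
    out
  })

  interference <- NULL
  if (length(inputs$cotx)) {
    interference <- run_stage("interfere", {
      scr <- interference_screen(inputs$net, ensemble, inputs$drug,
                                 inputs$cotx, inputs$processes,
                                 alpha = config$alpha,
                                 diff_threshold = config$diff_threshold)
      utils::write.table(as.data.frame(scr),
                         file.path(config$out_dir, "interference.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      scr
    })
  }

  agreement <- NULL
  if (!is.null(inputs$lit) && length(moas)) {
    agreement <- run_stage("agreement", {
      literature_agreement(lapply(moas, `[[`, "model"), inputs$lit)
    })
  }

  run_stage("manifest", {
    jsonlite::write_json(list(
      schema = SCHEMA_VERSION,
      config = lapply(unclass(config), function(x)
        if (inherits(x, "sa_control")) unclass(x) else x),
      ensemble_accuracies = ensemble$all_accuracies,
      n_flagged = nrow(flagged),
      agreement = if (is.null(agreement)) NULL else as.numeric(agreement)),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  })

  invisible(list(ensemble = ensemble, triggering = trig, flagged = flagged,
                 moa = moas, interference = interference,
                 agreement = agreement, out_dir = config$out_dir))
}
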