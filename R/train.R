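#' Simulated-annealing control settings
#'
#' The training optimizer is a simulated-annealing search over edge-weight
#' magnitudes (signs stay pinned to the curated edge signs). Each proposal
#' perturbs one randomly chosen edge magnitude; moves are accepted by the
#' Metropolis rule under a geometrically cooled temperature. The objective is
#' the constraint-satisfaction fraction plus a small bounded margin bonus
#' (strictly smaller than the value of one constraint) that smooths the
#' otherwise step-like accuracy landscape.
#'
#' @param n_proposals number of annealing proposals per solution (default
#'   4000, roughly ten per edge at the reference benchmark size; the
#'   accuracy plateau is not reached with substantially fewer).
#' @param t_start,t_end initial and final temperature of the geometric
#'   cooling schedule. The objective moves in steps of one constraint
#'   (`1/n_constraints`), so `t_start` is kept well below that step: early
#'   exploration then comes from the margin term rather than from accepting
#'   constraint losses.
#' @param step_sd standard deviation of the Gaussian magnitude perturbation.
#' @param min_weight smallest allowed weight magnitude; keeping it positive
#'   avoids silently deleting curated edges during the search.
#' @return a list of class `sa_control`.
#' @export
sa_control <- function(n_proposals = 4000, t_start = 0.02, t_end = 1e-3,
                       step_sd = 0.4, min_weight = 0.01) {
  stopifnot(n_proposals >= 1, t_start > t_end, t_end > 0,
            step_sd > 0, min_weight >= 0, min_weight < 1)
  structure(list(n_proposals = as.integer(n_proposals), t_start = t_start,
                 t_end = t_end, step_sd = step_sd, min_weight = min_weight),
            class = "sa_control")
}

# Objective = accuracy + bounded margin bonus. The bonus rewards pushing
# responses towards (and past) the activity threshold but is capped at
# 0.5 / n_constraints so it can never trade away a satisfied constraint.
sa_objective <- function(W, truth, n_steps, tau_act) {
  m <- constraint_margins(W, truth, n_steps)
  acc <- mean(m >= tau_act)
  bonus <- mean(pmax(pmin(m / (4 * tau_act), 1), -1)) * 0.5 / length(m)
  list(score = acc + bonus, accuracy = acc)
}

#' Train one propagation-model solution
#'
#' Runs a seeded simulated-annealing search maximizing training-set
#' compliance ([model_accuracy()]) over the sign-constrained edge weights.
#' Deterministic given `seed`; low accuracy is a result, not an error.
#' Initial weight magnitudes are drawn uniformly from `[0.1, 1]` so the
#' search never starts at the all-zero fixed point.
#'
#' @param net an [interactome()].
#' @param truth a non-empty [truth_table()].
#' @param seed integer seed.
#' @param n_steps,tau_act propagation settings (see [model_params()]).
#' @param control an [sa_control()].
#' @return a list with `params` (a [model_params()]), `accuracy` and `seed`.
#' @export
train_solution <- function(net, truth, seed, n_steps = 5, tau_act = 0.05,
                           control = sa_control()) {
  stopifnot(inherits(net, "interactome"), inherits(truth, "truth_table"))
  if (length(truth$constraints) == 0) stop("empty truth table")
  missing <- validate_against_network(truth, net)
  if (length(missing))
    stop("truth-table protein(s) not in network: ",
         paste(missing, collapse = ", "))
  n_edges <- nrow(net$edges)
  old <- local_seed(seed)
  on.exit(restore_seed(old))

  esign <- net$edges$sign
  mag <- stats::runif(n_edges, 0.1, 1)
  params <- model_params(net, mag * esign, n_steps, tau_act)
  W <- weight_matrix(net, params)
  eidx <- cbind(match(net$edges$from, net$proteins),
                match(net$edges$to, net$proteins))

  cur <- sa_objective(W, truth, n_steps, tau_act)
  best_mag <- mag
  best <- cur
  cool <- (control$t_end / control$t_start)^(1 / max(1, control$n_proposals - 1))
  temp <- control$t_start
  for (it in seq_len(control$n_proposals)) {
    e <- sample.int(n_edges, 1)
    new_m <- reflect_into(mag[e] + stats::rnorm(1, 0, control$step_sd),
                          control$min_weight, 1)
    old_m <- mag[e]
    mag[e] <- new_m
    W[eidx[e, , drop = FALSE]] <- new_m * esign[e]
    prop <- sa_objective(W, truth, n_steps, tau_act)
    if (prop$score >= cur$score ||
        stats::runif(1) < exp((prop$score - cur$score) / temp)) {
      cur <- prop
      if (cur$score > best$score) {
        best <- cur
        best_mag <- mag
      }
    } else {
      mag[e] <- old_m
      W[eidx[e, , drop = FALSE]] <- old_m * esign[e]
    }
    temp <- temp * cool
  }
  list(params = model_params(net, best_mag * esign, n_steps, tau_act),
       accuracy = best$accuracy, seed = seed)
}

# Reflect a proposal back into [lo, hi].
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  x <- (x - lo) %% (2 * span)
  lo + ifelse(x > span, 2 * span - x, x)
}

#' Sample a "universe of solutions" ensemble
#'
#' Trains `n_solutions` independent solutions with seeds
#' `base_seed, base_seed + 1, ...` and retains those whose training-set
#' compliance reaches `acceptance_threshold`. All per-seed accuracies are
#' recorded whether or not the solution is retained. Retained solutions are
#' weighted uniformly in all downstream ensemble summaries.
#'
#' @param net an [interactome()].
#' @param truth a [truth_table()].
#' @param n_solutions number of independent training runs (>= 1).
#' @param acceptance_threshold minimum accuracy for ensemble membership
#'   (default 0.9, in line with typical training compliance around 93%).
#' @param base_seed integer; solution i uses seed `base_seed + i - 1`.
#' @param n_steps,tau_act,control forwarded to [train_solution()].
#' @return an object of class `solution_ensemble`: list with `solutions`
#'   (each `params`/`accuracy`/`seed`), `acceptance_threshold` and
#'   `all_accuracies`.
#' @export
sample_ensemble <- function(net, truth, n_solutions = 10,
                            acceptance_threshold = 0.9, base_seed = 1,
                            n_steps = 5, tau_act = 0.05,
                            control = sa_control()) {
  stopifnot(n_solutions >= 1)
  sols <- lapply(seq_len(n_solutions) - 1L, function(i)
    train_solution(net, truth, seed = base_seed + i, n_steps = n_steps,
                   tau_act = tau_act, control = control))
  acc <- vapply(sols, `[[`, numeric(1), "accuracy")
  keep <- acc >= acceptance_threshold
  if (!any(keep))
    stop("ensemble empty: no solution reached acceptance threshold ",
         acceptance_threshold, " (best accuracy ", max(acc), ")")
  structure(list(solutions = sols[keep],
                 acceptance_threshold = acceptance_threshold,
                 all_accuracies = acc),
            class = "solution_ensemble")
}

#' Build an ensemble from explicit parameterizations
#'
#' Wraps already-available parameterizations (e.g. a planted ground-truth
#' model, or hand-built fixtures) in the ensemble container used by the
#' triggering, MoA and cotreatment layers.
#'
#' @param params_list list of [model_params()].
#' @param accuracies optional per-solution accuracies (default 1).
#' @return a `solution_ensemble`.
#' @export
as_ensemble <- function(params_list, accuracies = NULL) {
  if (inherits(params_list, "model_params")) params_list <- list(params_list)
  if (is.null(accuracies)) accuracies <- rep(1, length(params_list))
  sols <- Map(function(p, a) list(params = p, accuracy = a, seed = NA_integer_),
              params_list, accuracies)
  structure(list(solutions = sols, acceptance_threshold = 0,
                 all_accuracies = accuracies),
            class = "solution_ensemble")
}

#' @export
print.solution_ensemble <- function(x, ...) {
  acc <- vapply(x$solutions, `[[`, numeric(1), "accuracy")
  cat("solution_ensemble:", length(x$solutions), "retained solutions",
      sprintf("(mean accuracy %.3f, threshold %.2f)\n",
              mean(acc), x$acceptance_threshold))
  invisible(x)
}

#' Serialize an ensemble to a directory
#'
#' Writes `ensemble.json` (settings, seeds, accuracies) plus one
#' `solution_<i>.tsv` weight table (`from`, `to`, `weight`) per retained
#' solution.
#'
#' @param ensemble a `solution_ensemble`.
#' @param net the [interactome()] the ensemble was trained on.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- list(
    schema = SCHEMA_VERSION,
    acceptance_threshold = ensemble$acceptance_threshold,
    all_accuracies = ensemble$all_accuracies,
    solutions = lapply(seq_along(ensemble$solutions), function(i) {
      s <- ensemble$solutions[[i]]
      list(file = sprintf("solution_%03d.tsv", i), seed = s$seed,
           accuracy = s$accuracy, n_steps = s$params$n_steps,
           tau_act = s$params$tau_act)
    }))
  jsonlite::write_json(hdr, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (i in seq_along(ensemble$solutions)) {
    s <- ensemble$solutions[[i]]
    utils::write.table(
      data.frame(from = net$edges$from, to = net$edges$to,
                 weight = sprintf("%.17g", s$params$weights)),
      file.path(dir, sprintf("solution_%03d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Load an ensemble written by [write_ensemble()]
#'
#' @param dir the directory.
#' @param net the companion [interactome()]; edge order is realigned by
#'   (from, to) key so the reload is bit-exact regardless of row order.
#' @return a `solution_ensemble`.
#' @export
read_ensemble <- function(dir, net) {
  hdr <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  key <- paste(net$edges$from, net$edges$to, sep = "\r")
  sols <- lapply(hdr$solutions, function(h) {
    w <- utils::read.table(file.path(dir, h$file), sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric"))
    ord <- match(key, paste(w$from, w$to, sep = "\r"))
    if (anyNA(ord)) stop("weight table does not match the network edge set")
    list(params = model_params(net, w$weight[ord], h$n_steps, h$tau_act),
         accuracy = h$accuracy,
         seed = if (is.null(h$seed)) NA_integer_ else h$seed)
  })
  structure(list(solutions = sols,
                 acceptance_threshold = hdr$acceptance_threshold,
                 all_accuracies = unlist(hdr$all_accuracies)),
            class = "solution_ensemble")
}
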