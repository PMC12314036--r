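# Shared fixtures and independent brute-force oracles. The oracles use plain
# loops and exhaustive path enumeration only -- no code path shared with the
# implementations they check.

chain_net <- function() {
  interactome(data.frame(from = c("A", "B"), to = c("B", "C"),
                         sign = c(1, -1)))
}

# Random signed directed graph (no self-edges, unique pairs).
random_net <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  prot <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = prot, to = prot, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  if (nrow(pairs) == 0) pairs <- data.frame(from = prot[1], to = prot[2])
  pairs$sign <- sample(c(-1L, 1L), nrow(pairs), replace = TRUE)
  interactome(pairs, proteins = prot)
}

random_params <- function(net, seed, n_steps = 3, tau_act = 0.05) {
  set.seed(seed)
  mag <- runif(nrow(net$edges), 0.1, 1)
  model_params(net, mag * net$edges$sign, n_steps = n_steps,
               tau_act = tau_act)
}

random_ensemble <- function(net, seeds, ...) {
  as_ensemble(lapply(seeds, function(s) random_params(net, s, ...)))
}

# --- brute-force propagation: explicit loops over steps and edges ----------
bf_propagate <- function(net, params, stimulus = numeric()) {
  y <- stats::setNames(rep(0, length(net$proteins)), net$proteins)
  y[names(stimulus)] <- stimulus
  for (t in seq_len(params$n_steps)) {
    acc <- stats::setNames(rep(0, length(net$proteins)), net$proteins)
    for (i in seq_len(nrow(net$edges))) {
      acc[[net$edges$to[i]]] <- acc[[net$edges$to[i]]] +
        params$weights[i] * y[[net$edges$from[i]]]
    }
    y2 <- tanh(acc)
    y2[names(stimulus)] <- stimulus
    y <- y2
  }
  y
}

# --- exhaustive simple-path enumeration ------------------------------------
bf_simple_paths <- function(net, from, to, max_len) {
  adj <- split(net$edges$to, net$edges$from)
  out <- list()
  walk <- function(path) {
    tip <- path[length(path)]
    if (tip == to && length(path) > 1) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= max_len) return(invisible())
    for (nxt in adj[[tip]]) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  walk(from)
  out
}

bf_distance <- function(net, from, to, max_len = length(net$proteins)) {
  if (from == to) return(0)
  paths <- bf_simple_paths(net, from, to, max_len)
  if (length(paths) == 0) return(Inf)
  min(lengths(paths)) - 1
}

bf_edge_sign <- function(net, from, to) {
  net$edges$sign[net$edges$from == from & net$edges$to == to][1]
}

# --- brute-force triggering score -------------------------------------------
bf_raw_score <- function(net, ensemble, source, mode, effs,
                         weights = c(1, 1 / 2, 1 / 3)) {
  clamp <- stats::setNames(if (mode == "inhibited") -1 else 1, source)
  per_sol <- sapply(ensemble$solutions, function(s) {
    y <- bf_propagate(net, s$params, clamp)
    total <- 0
    for (i in seq_len(nrow(effs$effectors))) {
      e <- effs$effectors$protein[i]
      v <- effs$effectors$sign[i]
      d <- bf_distance(net, source, e)
      if (d >= 1 && d <= 3 &&
          sign(y[[e]]) == v && abs(y[[e]]) >= s$params$tau_act)
        total <- total + weights[d]
    }
    total
  })
  mean(per_sol)
}

# --- brute-force pathway supports -------------------------------------------
bf_pathway_records <- function(net, ensemble, clamp, stimuli, effectors,
                               max_len, min_support) {
  paths <- list()
  for (s in stimuli) {
    for (e in setdiff(effectors, s)) {
      paths <- c(paths, bf_simple_paths(net, s, e, max_len))
    }
  }
  paths <- unique(paths)
  recs <- lapply(paths, function(nodes) {
    active <- sapply(ensemble$solutions, function(sol) {
      y <- bf_propagate(net, sol$params, clamp)
      ok <- all(abs(y[nodes]) >= sol$params$tau_act)
      for (i in seq_len(length(nodes) - 1)) {
        es <- bf_edge_sign(net, nodes[i], nodes[i + 1])
        if (sign(y[[nodes[i + 1]]]) != es * sign(y[[nodes[i]]])) ok <- FALSE
      }
      ok
    })
    data.frame(path = paste(nodes, collapse = "->"), support = mean(active),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) return(data.frame(path = character(), support = numeric()))
  out[out$support >= min_support & out$support > 0, , drop = FALSE]
}

# Small solvable benchmark used across tests (fast to train).
small_bench <- function(seed = 5) {
  generate_benchmark(benchmark_spec(
    n_proteins = 60, n_processes = 1, effectors_per_process = 4,
    n_shared_offtargets = 1, n_specific_offtargets = 2,
    inducers_per_process = 2, n_constraints = 10, seed = seed))
}
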