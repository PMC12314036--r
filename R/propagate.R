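#' Propagation model parameters
#'
#' The propagation model treats the interactome like a multilayer
#' perceptron unrolled over the network itself: proteins are the units,
#' signed edges the connections. Each edge carries a real weight in
#' `[-1, 1]` whose sign must match the curated edge sign (an inhibiting edge
#' can only transmit inhibition). Propagation runs `n_steps` synchronous
#' update rounds; a protein counts as stimulated when its final activity
#' magnitude reaches `tau_act`.
#'
#' @param net an [interactome()].
#' @param weights numeric vector, one weight per row of `net$edges`, each with
#'   the edge's sign (zero allowed) and magnitude at most 1.
#' @param n_steps number of synchronous propagation steps (default 5; a
#'   small step count, of the order of the network diameter, is enough for a
#'   signal to cross the distances that matter here).
#' @param tau_act activity threshold in `(0, 1)` above which a protein counts
#'   as stimulated (default 0.05).
#' @return an object of class `model_params`.
#' @export
model_params <- function(net, weights, n_steps = 5, tau_act = 0.05) {
  stopifnot(inherits(net, "interactome"),
            length(weights) == nrow(net$edges),
            n_steps >= 1, tau_act > 0, tau_act < 1)
  if (any(abs(weights) > 1)) stop("weight magnitudes must be <= 1")
  nz <- weights != 0
  if (any(sign(weights[nz]) != net$edges$sign[nz]))
    stop("nonzero weight signs must match edge signs")
  structure(list(weights = as.numeric(weights),
                 n_steps = as.integer(n_steps),
                 tau_act = tau_act),
            class = "model_params")
}

# Dense weight matrix W[i, j] = weight of edge i -> j (0 if absent).
weight_matrix <- function(net, params) {
  n <- length(net$proteins)
  W <- matrix(0, n, n, dimnames = list(net$proteins, net$proteins))
  W[cbind(match(net$edges$from, net$proteins),
          match(net$edges$to, net$proteins))] <- params$weights
  W
}

#' Propagate a stimulus over the network
#'
#' Starting from activity 0 everywhere except the clamped stimulus proteins,
#' runs `n_steps` synchronous rounds in which every non-clamped protein's
#' activity becomes `tanh(sum of incoming weight x source activity)`.
#' The squashing keeps all activities in `(-1, 1)`, is odd
#' (`tanh(-x) = -tanh(x)`, so negating every clamp negates every activity)
#' and maps 0 to 0, so an empty stimulus yields the all-zero vector.
#' Clamped proteins hold their clamp value exactly throughout.
#'
#' @param net an [interactome()].
#' @param params a [model_params()].
#' @param stimulus named numeric vector of clamp values (`+1`/`-1`), names
#'   are proteins; may be empty.
#' @return named numeric vector of activities in `[-1, 1]`, one per protein.
#' @export
#' @examples
#' net <- interactome(data.frame(from = "A", to = "B", sign = 1))
#' p <- model_params(net, weights = 1, n_steps = 1)
#' propagate(net, p, c(A = 1))["B"]  # tanh(1)
propagate <- function(net, params, stimulus = numeric()) {
  stopifnot(inherits(params, "model_params"))
  unknown <- setdiff(names(stimulus), net$proteins)
  if (length(unknown))
    stop("unknown stimulus protein(s): ", paste(unknown, collapse = ", "))
  W <- weight_matrix(net, params)
  y <- propagate_batch(W, list(stimulus), params$n_steps)[, 1]
  names(y) <- net$proteins
  y
}

# Batched propagation: one column per stimulus. W is the dense weight matrix
# with rownames giving protein order. Returns an n x k activity matrix.
propagate_batch <- function(W, stimuli, n_steps) {
  n <- nrow(W)
  k <- length(stimuli)
  Y <- matrix(0, n, k)
  prot <- rownames(W)
  idx <- integer(0)
  val <- numeric(0)
  for (j in seq_len(k)) {
    s <- stimuli[[j]]
    if (length(s)) {
      i <- match(names(s), prot)
      idx <- c(idx, (j - 1L) * n + i)
      val <- c(val, as.numeric(s))
    }
  }
  Y[idx] <- val
  for (t in seq_len(n_steps)) {
    Y <- tanh(crossprod(W, Y))
    Y[idx] <- val
  }
  Y
}

#' Training-set compliance of a parameterization
#'
#' The fraction of truth-table constraints a model satisfies: a constraint
#' holds when, after clamping its stimulus and propagating, the response
#' protein's activity has the required sign with magnitude at least
#' `tau_act`.
#'
#' @param net an [interactome()].
#' @param params a [model_params()].
#' @param truth a [truth_table()] validated against `net`.
#' @return fraction in `[0, 1]`.
#' @export
model_accuracy <- function(net, params, truth) {
  stopifnot(inherits(truth, "truth_table"))
  if (length(truth$constraints) == 0) stop("empty truth table")
  missing <- validate_against_network(truth, net)
  if (length(missing))
    stop("truth-table protein(s) not in network: ",
         paste(missing, collapse = ", "))
  W <- weight_matrix(net, params)
  mean(constraint_margins(W, truth, params$n_steps) >= params$tau_act)
}

# Signed response margins: required_sign * activity(response) per constraint.
# A constraint is satisfied when its margin >= tau_act.
constraint_margins <- function(W, truth, n_steps) {
  ks <- truth$constraints
  Y <- propagate_batch(W, lapply(ks, `[[`, "stimulus"), n_steps)
  resp <- match(vapply(ks, `[[`, character(1), "response"), rownames(W))
  req <- vapply(ks, `[[`, numeric(1), "sign")
  req * Y[cbind(resp, seq_along(ks))]
}
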