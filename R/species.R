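#' Behavioral movement states
#'
#' A behavioral state bundles the three parameters that govern movement
#' while the simulated animal is in that state:
#'
#' * `concentration` — turning-angle concentration of the wrapped-normal
#'   turning kernel, parameterized as the mean resultant length
#'   \eqn{\rho = e^{-\sigma^2/2}} in \[0, 1\]: 0 gives a uniform kernel
#'   (plain random walk), values near 1 give nearly straight paths
#'   (correlated random walk).
#' * `step_length` — the fixed maximum displacement per simulation step, in
#'   map units.  The realized step may be shorter where the landscape
#'   resists movement; a state with step length 0 is a Resting state.
#' * `perceptual_range` — the radius (map units) up to which the animal
#'   perceives the surrounding landscape when choosing its heading.
#'
#' `state_rw()` builds a plain random-walk state (concentration 0),
#' `state_crw()` a correlated random-walk state, and `state_resting()` a
#' stationary state (step length 0; the walker's heading memory is carried
#' unchanged through rest, so a correlated walker resumes its previous
#' direction when it starts moving again).
#'
#' @param step_length non-negative maximum step length in map units.
#' @param perceptual_range positive perception radius in map units.
#' @param concentration turning-angle concentration in \[0, 1\].
#' @param label optional state label.
#' @return a `movement_state` object.
#' @examples
#' state_crw(0.95, 10, 500)      # strongly directional walker
#' state_rw(10, 200)             # uniform-heading walker
#' state_resting(200)            # stationary state
#' @export
state_rw <- function(step_length, perceptual_range, label = "RW") {
  movement_state(0, step_length, perceptual_range, label)
}

#' @rdname state_rw
#' @export
state_crw <- function(concentration, step_length, perceptual_range,
                      label = "CRW") {
  movement_state(concentration, step_length, perceptual_range, label)
}

#' @rdname state_rw
#' @export
state_resting <- function(perceptual_range = 1, label = "Resting") {
  movement_state(0, 0, perceptual_range, label)
}

#' @rdname state_rw
#' @export
movement_state <- function(concentration, step_length, perceptual_range,
                           label = "state") {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      concentration < 0 || concentration > 1)
    stop("'concentration' must be a single value in [0, 1]")
  if (!is.numeric(step_length) || length(step_length) != 1 || step_length < 0)
    stop("'step_length' must be a single non-negative number")
  if (!is.numeric(perceptual_range) || length(perceptual_range) != 1 ||
      perceptual_range <= 0)
    stop("'perceptual_range' must be a single positive number")
  structure(
    list(concentration = as.numeric(concentration),
         step_length = as.numeric(step_length),
         perceptual_range = as.numeric(perceptual_range),
         label = as.character(label)),
    class = "movement_state"
  )
}

#' @export
print.movement_state <- function(x, ...) {
  cat(sprintf("<movement_state '%s'> concentration %g, step length %g, perceptual range %g\n",
              x$label, x$concentration, x$step_length, x$perceptual_range))
  invisible(x)
}

#' State transition matrix
#'
#' Builds the row-stochastic matrix of per-step probabilities of switching
#' between behavioral states.  Only the off-diagonal switching
#' probabilities are supplied; each diagonal entry (the probability of
#' remaining in the state) is filled so the row sums to 1.  Dwell time in a
#' state with total exit probability `p` is geometric with mean `1/p`
#' steps.
#'
#' @param probs for two states, a length-2 vector
#'   `c(p12, p21)`; generally, an `S x S` matrix whose off-diagonal entries
#'   are the switching probabilities (the diagonal is ignored and
#'   recomputed).
#' @return an `S x S` transition matrix with rows summing to 1.
#' @examples
#' transition_matrix(c(0.01, 0.01))    # symmetric two-state switching
#' transition_matrix(c(0.01, 0.002))   # slow return to state 1
#' @export
transition_matrix <- function(probs) {
  if (is.matrix(probs)) {
    m <- probs
    if (nrow(m) != ncol(m)) stop("transition matrix must be square")
  } else if (length(probs) == 1) {
    m <- matrix(probs, 1, 1)
  } else if (length(probs) == 2) {
    m <- matrix(c(0, probs[2], probs[1], 0), 2, 2)
  } else {
    stop("'probs' must be a square matrix, or a vector of length 1 or 2")
  }
  storage.mode(m) <- "double"
  diag(m) <- 0
  if (any(m < 0)) stop("switching probabilities must be non-negative")
  off <- rowSums(m)
  if (any(off > 1 + 1e-12))
    stop("off-diagonal switching probabilities in some row sum to more than 1")
  diag(m) <- 1 - off
  m
}

#' Species: states plus switching machinery
#'
#' A species is an ordered set of behavioral states together with the
#' Markov transition matrix that switches between them, one draw per
#' simulation step.
#'
#' @param states a single `movement_state` or a list of them.
#' @param transitions transition matrix with one row/column per state
#'   (see [transition_matrix()]); defaults to the identity for a
#'   single-state species.
#' @param name species name.
#' @return a `species` object.
#' @examples
#' levy <- species(
#'   list(state_rw(10, 200), state_crw(0.95, 10, 200)),
#'   transition_matrix(c(0.01, 0.01)),
#'   name = "levy-like walker"
#' )
#' @export
species <- function(states, transitions = NULL, name = "species") {
  if (inherits(states, "movement_state")) states <- list(states)
  if (!length(states) || !all(vapply(states, inherits, TRUE, "movement_state")))
    stop("'states' must be one or more movement_state objects")
  S <- length(states)
  if (is.null(transitions)) transitions <- diag(S)
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == S))
    stop(sprintf("transition matrix is %dx%d but species has %d state(s)",
                 nrow(transitions), ncol(transitions), S))
  if (any(transitions < 0) || any(transitions > 1) ||
      any(abs(rowSums(transitions) - 1) > 1e-12))
    stop("transition matrix rows must be probabilities summing to 1")
  structure(list(states = states, transitions = transitions,
                 name = as.character(name)),
            class = "species")
}

#' @export
print.species <- function(x, ...) {
  cat(sprintf("<species '%s'> %d state(s)\n", x$name, length(x$states)))
  for (s in x$states)
    cat(sprintf("  %-10s concentration %g, step length %g, perceptual range %g\n",
                s$label, s$concentration, s$step_length, s$perceptual_range))
  if (length(x$states) > 1) {
    cat("  transition matrix:\n")
    m <- format(x$transitions, digits = 4)
    for (i in seq_len(nrow(m))) cat("   ", m[i, ], "\n")
  }
  invisible(x)
}

n_states <- function(sp) length(sp$states)

state_field <- function(sp, field) {
  vapply(sp$states, `[[`, numeric(1), field)
}

#' Draw the next behavioral state
#'
#' One step of the state-switching Markov chain: draws the next state from
#' the categorical distribution given by row `current` of the transition
#' matrix, using R's global random number stream.
#'
#' @param current current state index (1-based).
#' @param transitions transition matrix.
#' @return the next state index.
#' @export
draw_next_state <- function(current, transitions) {
  if (current < 1 || current > nrow(transitions))
    stop("'current' is not a valid state index")
  row <- transitions[current, ]
  findInterval(stats::runif(1), cumsum(row), left.open = TRUE) + 1L
}

# Vectorized simulation of the switching chain: one draw per step.
simulate_state_chain <- function(transitions, n_steps, start_state = 1L) {
  S <- nrow(transitions)
  s <- integer(n_steps)
  if (S == 1) {
    s[] <- 1L
    return(s)
  }
  cum <- t(apply(transitions, 1, cumsum))
  u <- stats::runif(n_steps)
  cur <- as.integer(start_state)
  for (t in seq_len(n_steps)) {
    row <- cum[cur, ]
    cur <- 1L
    while (u[t] > row[cur]) cur <- cur + 1L
    s[t] <- cur
  }
  s
}

#' Write or read a species configuration file
#'
#' Serializes a species to a small YAML file (states with their parameters,
#' plus the transition matrix as rows), the format consumed by the
#' command-line interface.
#'
#' @param sp a `species`.
#' @param path file path.
#' @return `read_species()` returns a `species`; `write_species()` returns
#'   `path` invisibly.
#' @export
write_species <- function(sp, path) {
  obj <- list(
    name = sp$name,
    states = lapply(sp$states, function(s) list(
      label = s$label, concentration = s$concentration,
      step_length = s$step_length, perceptual_range = s$perceptual_range
    )),
    transitions = lapply(seq_len(nrow(sp$transitions)),
                         function(i) as.numeric(sp$transitions[i, ]))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_species
#' @export
read_species <- function(path) {
  obj <- yaml::read_yaml(path)
  states <- lapply(obj$states, function(s)
    movement_state(s$concentration, s$step_length, s$perceptual_range,
                   s$label %||% "state"))
  tm <- do.call(rbind, lapply(obj$transitions, as.numeric))
  species(states, tm, name = obj$name %||% "species")
}
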