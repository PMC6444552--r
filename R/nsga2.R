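#' Fast nondominated sorting
#'
#' Partitions a set of objective vectors (rows; all objectives minimized)
#' into Pareto fronts: front 1 is the nondominated set, front 2 the set
#' nondominated once front 1 is removed, and so on.
#'
#' @param objectives numeric matrix, one row per candidate, one column per
#'   objective.
#' @return integer vector of front indices (1 = best).
#' @export
nondominated_rank <- function(objectives) {
  n <- nrow(objectives)
  rank <- integer(n)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    oi <- objectives[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      oj <- objectives[j, ]
      if (all(oi <= oj) && any(oi < oj)) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (all(oj <= oi) && any(oj < oi)) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  front <- which(dom_count == 0L)
  f <- 1L
  while (length(front)) {
    rank[front] <- f
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    f <- f + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' For each candidate of one front, the sum over objectives of the
#' normalized gap between its neighbors when the front is sorted by that
#' objective.  Boundary candidates (per-objective extremes) get `Inf`, so
#' truncation of an oversized front always keeps the extreme points — this
#' is what makes the per-objective minimum monotone across generations.
#' When an objective has zero range over the front it contributes nothing.
#'
#' @param objectives numeric matrix of the front members' objectives.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(objectives))) {
    o <- objectives[, m]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0)
      d[ord[2:(n - 1)]] <- d[ord[2:(n - 1)]] +
        (o[ord[3:n]] - o[ord[1:(n - 2)]]) / rng
  }
  d
}

# Binary tournament on (rank, crowding): lower rank wins; ties broken by
# larger crowding distance, then by the first contestant.
tournament_pick <- function(rank, crowd) {
  n <- length(rank)
  i <- sample.int(n, 1L); j <- sample.int(n, 1L)
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowd[j] > crowd[i]) j else i
}

# Simulated binary crossover (SBX), per-variable, bound-clipped.
sbx_crossover <- function(p1, p2, lower, upper, eta, p_cx = 0.9) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) > p_cx) return(list(c1, c2))
  for (v in seq_along(p1)) {
    if (stats::runif(1) > 0.5 || abs(p1[v] - p2[v]) < 1e-14) next
    u <- stats::runif(1)
    beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
            else (1 / (2 * (1 - u)))^(1 / (eta + 1))
    c1[v] <- 0.5 * ((1 + beta) * p1[v] + (1 - beta) * p2[v])
    c2[v] <- 0.5 * ((1 - beta) * p1[v] + (1 + beta) * p2[v])
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# Polynomial mutation, per-variable probability p_mut, bound-clipped.
poly_mutation <- function(x, lower, upper, eta, p_mut) {
  for (v in seq_along(x)) {
    if (stats::runif(1) > p_mut) next
    u <- stats::runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
    x[v] <- x[v] + delta * (upper[v] - lower[v])
  }
  pmin(pmax(x, lower), upper)
}

#' NSGA-II multi-objective minimizer
#'
#' An elitist multi-objective genetic algorithm: fast nondominated sorting,
#' crowding-distance diversity preservation, binary tournament selection on
#' (rank, crowding), simulated binary crossover, polynomial mutation, and
#' (mu + lambda) survivor selection over the union of parents and
#' offspring.  Parents keep their cached objective values (no
#' re-evaluation), so with a deterministic or frozen-noise objective the
#' per-generation minimum of every objective is non-increasing.
#'
#' @param fn objective function: takes a parameter vector, returns a
#'   numeric vector of objectives to minimize (length >= 1).
#' @param lower,upper numeric bounds per decision variable.
#' @param pop_size even population size >= 4.
#' @param generations number of generations.
#' @param eta_crossover,eta_mutation SBX and polynomial-mutation
#'   distribution indices (defaults 15 and 20).
#' @param p_crossover per-pair crossover probability (default 0.9).
#' @param p_mutation per-variable mutation probability; default
#'   `1 / n_variables`.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `nsga2_trace`: list with `front` (one data
#'   frame of nondominated parameters + objectives per generation),
#'   `population` and `objectives` (final generation), `bounds`.
#' @examples
#' res <- nsga2(function(x) c(x^2, (x - 2)^2),
#'              lower = -10, upper = 10,
#'              pop_size = 40, generations = 50, seed = 1)
#' @export
nsga2 <- function(fn, lower, upper, pop_size = 100, generations = 50,
                  eta_crossover = 15, eta_mutation = 20, p_crossover = 0.9,
                  p_mutation = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(upper < lower))
    stop("'lower' and 'upper' must be conformable bounds")
  nv <- length(lower)
  if (pop_size < 4 || pop_size %% 2 != 0)
    stop("'pop_size' must be even and >= 4")
  if (is.null(p_mutation)) p_mutation <- 1 / nv

  # row-wise evaluation; apply() returns a bare vector for one objective
  eval_rows <- function(P) {
    o <- apply(P, 1, function(x) as.numeric(fn(x)))
    o <- if (is.matrix(o)) t(o) else matrix(o, ncol = 1)
    o[!is.finite(o)] <- .Machine$double.xmax
    o
  }

  pop <- matrix(stats::runif(pop_size * nv, rep(lower, each = pop_size),
                             rep(upper, each = pop_size)),
                nrow = pop_size)
  obj <- eval_rows(pop)

  front_trace <- vector("list", generations)
  rank <- nondominated_rank(obj)
  crowd <- crowding_by_front(obj, rank)

  for (g in seq_len(generations)) {
    # variation
    children <- matrix(0, pop_size, nv)
    i <- 1L
    while (i < pop_size) {
      a <- tournament_pick(rank, crowd)
      b <- tournament_pick(rank, crowd)
      kids <- sbx_crossover(pop[a, ], pop[b, ], lower, upper,
                            eta_crossover, p_crossover)
      children[i, ] <- poly_mutation(kids[[1]], lower, upper,
                                     eta_mutation, p_mutation)
      children[i + 1L, ] <- poly_mutation(kids[[2]], lower, upper,
                                          eta_mutation, p_mutation)
      i <- i + 2L
    }
    cobj <- eval_rows(children)

    # (mu + lambda) elitist survivor selection
    upop <- rbind(pop, children)
    uobj <- rbind(obj, cobj)
    urank <- nondominated_rank(uobj)
    keep <- integer(0)
    f <- 1L
    while (length(keep) < pop_size) {
      members <- which(urank == f)
      if (length(keep) + length(members) <= pop_size) {
        keep <- c(keep, members)
      } else {
        cd <- crowding_distance(uobj[members, , drop = FALSE])
        members <- members[order(cd, decreasing = TRUE)]
        keep <- c(keep, members[seq_len(pop_size - length(keep))])
      }
      f <- f + 1L
    }
    pop <- upop[keep, , drop = FALSE]
    obj <- uobj[keep, , drop = FALSE]
    rank <- nondominated_rank(obj)
    crowd <- crowding_by_front(obj, rank)

    fr <- which(rank == 1L)
    front_trace[[g]] <- data.frame(
      generation = g,
      pop[fr, , drop = FALSE],
      obj[fr, , drop = FALSE]
    )
    names(front_trace[[g]]) <- c("generation",
                                 paste0("par", seq_len(nv)),
                                 paste0("obj", seq_len(ncol(obj))))
  }

  structure(
    list(front = front_trace, population = pop, objectives = obj,
         bounds = cbind(lower = lower, upper = upper)),
    class = "nsga2_trace"
  )
}

crowding_by_front <- function(obj, rank) {
  crowd <- numeric(nrow(obj))
  for (f in unique(rank)) {
    idx <- which(rank == f)
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  crowd
}

#' Flatten an optimization trace to one data frame
#'
#' Stacks the per-generation nondominated fronts into a single data frame
#' (columns `generation`, decision variables, objectives) — the data behind
#' a generation plot, and the CSV the command-line interface exports.
#'
#' @param trace an `nsga2_trace`.
#' @return data frame.
#' @export
trace_as_df <- function(trace) {
  do.call(rbind, trace$front)
}

#' @export
print.nsga2_trace <- function(x, ...) {
  g <- length(x$front)
  fr <- x$front[[g]]
  cat(sprintf("<nsga2_trace> %d generation(s); final front: %d candidate(s)\n",
              g, nrow(fr)))
  obj_cols <- grep("^obj", names(fr))
  cat("  final per-objective minima:",
      paste(signif(vapply(fr[obj_cols], min, numeric(1)), 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' Dominated hypervolume of a two-objective front
#'
#' Area dominated by a set of two-objective points, relative to a reference
#' point that every point must dominate.  Used to judge front quality on
#' test problems.
#'
#' @param objectives matrix of points (rows; 2 columns, minimized).
#' @param ref numeric `c(r1, r2)` reference point.
#' @return non-negative scalar.
#' @export
hypervolume_2d <- function(objectives, ref) {
  stopifnot(ncol(objectives) == 2)
  keep <- objectives[, 1] <= ref[1] & objectives[, 2] <= ref[2]
  objectives <- objectives[keep, , drop = FALSE]
  if (!nrow(objectives)) return(0)
  rank <- nondominated_rank(objectives)
  pts <- objectives[rank == 1L, , drop = FALSE]
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  hv <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(pts))) {
    hv <- hv + (ref[1] - pts[i, 1]) * (y_prev - pts[i, 2])
    y_prev <- pts[i, 2]
  }
  hv
}
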