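#' @importFrom rlang .data
NULL

pathway_states <- c("S", "I", "P")

# Default initial condition: freshly damaged DNA, all mass in the substrate.
state_damaged <- c(S = 1, I = 0, P = 0)

#' @noRd
validate_state <- function(initial, tol = 1e-9) {
  x <- unlist(initial)
  if (is.null(names(x)) && length(x) == 3) names(x) <- pathway_states
  if (!all(pathway_states %in% names(x))) {
    stop("a state distribution needs named entries S, I, P", call. = FALSE)
  }
  x <- x[pathway_states]
  if (anyNA(x) || any(x < -tol) || any(x > 1 + tol)) {
    stop("state probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop("state probabilities must sum to 1", call. = FALSE)
  }
  pmin(pmax(x, 0), 1)
}

#' Transition-rate matrix (generator) of the pathway model
#'
#' Builds the 3x3 generator `Q` of the continuous-time Markov chain over states
#' `(S, I, P)`. Convention: **columns index the source state**, so the dynamics
#' are `dx/dt = Q x` with `x` a probability column vector and every column of
#' `Q` sums to zero. `Q[j, i]` is the rate of the `i -> j` transition.
#'
#' @param rates A [rate_set()] (or anything [as_rate_set()] accepts).
#' @return A 3x3 numeric matrix with dimnames `(S, I, P)`.
#' @examples
#' pathway_generator(rate_set(1, 0.1, 1, 0.1, 0.1))
#' @export
pathway_generator <- function(rates) {
  r <- as_rate_set(rates)
  q <- matrix(0, 3, 3, dimnames = list(pathway_states, pathway_states))
  q["I", "S"] <- r[["k1"]]
  q["P", "S"] <- r[["k3"]]
  q["S", "I"] <- r[["k_m1"]]
  q["P", "I"] <- r[["k2"]]
  q["I", "P"] <- r[["k_m2"]]
  diag(q) <- -colSums(q)
  q
}

#' Exact time course of the pathway model
#'
#' Solves `dx/dt = Q x` exactly through the matrix exponential,
#' `x(t) = expm(Q t) x(0)`, at the requested times.
#'
#' @inheritParams pathway_generator
#' @param times Non-negative, strictly increasing times.
#' @param initial Initial distribution over `(S, I, P)`; defaults to all mass in
#'   the damage substrate `S`.
#' @return A tibble of class `pathway_timecourse` with columns
#'   `time, S, I, P`; each row is a probability distribution.
#' @examples
#' simulate_pathway(rate_set(1, 0.1, 1, 0.1, 0.1), times = c(0, 1, 10, 100))
#' @export
simulate_pathway <- function(rates, times, initial = state_damaged) {
  r <- as_rate_set(rates)
  x0 <- validate_state(initial)
  if (length(times) == 0 || anyNA(times) || any(times < 0)) {
    stop("times must be non-negative numbers", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  q <- pathway_generator(r)
  states <- vapply(
    times, function(t) propagate_state(q, x0, t),
    c(S = 0, I = 0, P = 0)
  )
  out <- tibble::tibble(
    time = as.numeric(times),
    S = unname(states["S", ]),
    I = unname(states["I", ]),
    P = unname(states["P", ])
  )
  class(out) <- c("pathway_timecourse", class(out))
  out
}

# x(t) = expm(Q t) x0, renormalized against expm round-off (column sums of the
# propagator are 1 up to ~1e-14).
propagate_state <- function(q, x0, t) {
  if (t == 0) {
    return(x0)
  }
  pt <- as.matrix(Matrix::expm(q * t))
  x <- as.numeric(pt %*% x0)
  x <- pmin(pmax(x, 0), 1)
  stats::setNames(x / sum(x), pathway_states)
}

#' Long-time (limiting) state distribution
#'
#' Computes the `t -> Inf` limit of [simulate_pathway()] analytically. For an
#' irreducible chain this is the unique stationary distribution (independent of
#' `initial`, obtained from the null space of the generator). Knockouts make the
#' chain reducible: absorbing states / closed classes arise (the kinetic traps),
#' and the limit is then the mixture of the closed-class stationary
#' distributions weighted by the absorption probabilities from `initial`.
#'
#' @inheritParams simulate_pathway
#' @return Named numeric vector `c(S = , I = , P = )` summing to 1.
#' @examples
#' limiting_state(rate_set(1, 0.1, 1, 0.1, 0.1))
#' # bpSL double knockout: S is absorbing
#' limiting_state(rate_set(0, 0.1, 1, 0.1, 0))
#' @export
limiting_state <- function(rates, initial = state_damaged) {
  r <- as_rate_set(rates)
  x0 <- validate_state(initial)
  q <- pathway_generator(r)

  cls <- closed_classes(q)
  limit <- numeric(3)
  names(limit) <- pathway_states

  # Stationary distribution within each closed class (conditional dynamics
  # restricted to the class are themselves a conservative generator).
  class_stationary <- lapply(cls$closed, function(members) {
    stationary_on(q, members)
  })

  transient <- setdiff(seq_len(3), unlist(cls$closed))
  # Mass ending up in each closed class: initial mass already there plus
  # absorption probabilities from transient states.
  mass <- vapply(seq_along(cls$closed), function(ci) {
    members <- cls$closed[[ci]]
    m <- sum(x0[members])
    if (length(transient) > 0) {
      h <- hitting_probabilities(q, transient, members, unlist(cls$closed))
      m <- m + sum(x0[transient] * h)
    }
    m
  }, numeric(1))

  for (ci in seq_along(cls$closed)) {
    limit[cls$closed[[ci]]] <- limit[cls$closed[[ci]]] + mass[ci] * class_stationary[[ci]]
  }

  # Residual check: the limit must be stationary for the full generator.
  if (max(abs(q %*% limit)) > 1e-10 * max(1, max(abs(q)))) {
    stop("internal error: limiting distribution failed the stationarity residual check")
  }
  limit / sum(limit)
}

# Closed communicating classes of the 3-state chain (states with no path out).
closed_classes <- function(q) {
  adj <- q > 0
  diag(adj) <- TRUE
  reach <- adj
  for (i in 1:2) reach <- (reach %*% reach) > 0 # transitive closure, n = 3
  # note: reach[j, i] means i -> ... -> j under the column-source convention
  reaches <- t(reach) # reaches[i, j]: j reachable from i
  comm <- reaches & t(reaches)
  seen <- rep(FALSE, 3)
  classes <- list()
  for (i in 1:3) {
    if (seen[i]) next
    members <- which(comm[i, ])
    seen[members] <- TRUE
    classes <- c(classes, list(members))
  }
  closed <- Filter(function(members) {
    all(which(reaches[members[1], ]) %in% members)
  }, classes)
  list(classes = classes, closed = closed)
}

# Stationary distribution of the chain restricted to a closed class.
stationary_on <- function(q, members) {
  if (length(members) == 1) {
    return(1)
  }
  qc <- q[members, members, drop = FALSE]
  a <- rbind(qc, rep(1, length(members)))
  b <- c(rep(0, length(members)), 1)
  pi_c <- as.numeric(qr.solve(a, b))
  if (max(abs(qc %*% pi_c)) > 1e-10 * max(1, max(abs(qc)))) {
    stop("internal error: stationary solve residual too large")
  }
  pmax(pi_c, 0) / sum(pmax(pi_c, 0))
}

# Probability of being absorbed into `target` (one closed class) from each
# transient state, given all closed states in `absorbing`.
hitting_probabilities <- function(q, transient, target, absorbing) {
  h_abs <- as.numeric(absorbing %in% target)
  if (length(transient) == 0) {
    return(numeric(0))
  }
  # For transient i: sum_j q(i->j) h_j = 0 with h fixed on absorbing states,
  # i.e. (row = equation for i): Q^T restricted.
  qt <- t(q) # qt[i, j] = rate i -> j (plus diagonal)
  a <- qt[transient, transient, drop = FALSE]
  b <- -as.numeric(qt[transient, absorbing, drop = FALSE] %*% h_abs)
  as.numeric(solve(a, b))
}

#' Time until the repaired probability reaches a threshold
#'
#' Smallest time `t` with `P(t) >= threshold`, starting from `initial`, located
#' by geometric bracketing followed by bisection on the exact (matrix
#' exponential) solution. Returns `Inf` when the limiting repaired probability
#' is below the threshold.
#'
#' @inheritParams simulate_pathway
#' @param threshold Repair probability threshold in (0, 1); default 0.5.
#' @param rel_tol Relative tolerance on the located time.
#' @return A single time, or `Inf`.
#' @examples
#' time_to_repair(rate_set(0, 0, 0, 0, 0.1)) # log(2) / 0.1
#' @export
time_to_repair <- function(rates, threshold = 0.5, initial = state_damaged,
                           rel_tol = 1e-6) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
    threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single probability in (0, 1)", call. = FALSE)
  }
  r <- as_rate_set(rates)
  x0 <- validate_state(initial)
  if (x0[["P"]] >= threshold) {
    return(0)
  }
  if (limiting_state(r, x0)[["P"]] < threshold) {
    return(Inf)
  }
  q <- pathway_generator(r)
  p_at <- function(t) propagate_state(q, x0, t)[["P"]]

  t_hi <- 1 / max(unclass(r))
  n_doublings <- 0
  while (p_at(t_hi) < threshold) {
    t_hi <- 2 * t_hi
    n_doublings <- n_doublings + 1
    if (n_doublings > 200) {
      return(Inf) # limit == threshold approached from below
    }
  }
  t_lo <- 0
  while ((t_hi - t_lo) > rel_tol * t_hi) {
    mid <- (t_lo + t_hi) / 2
    if (p_at(mid) >= threshold) t_hi <- mid else t_lo <- mid
  }
  t_hi
}

#' First-passage probability of repair through the compensatory route
#'
#' Probability that, starting from the damage substrate `S`, the first entry
#' into the repaired state `P` uses the direct compensatory edge `S -> P`
#' rather than the main route through the intermediate. By first-step analysis
#' the closed form is `q = a / (1 - b c)` with `a = k3/(k1+k3)`,
#' `b = k1/(k1+k3)` and `c = k_m1/(k2+k_m1)`.
#'
#' @inheritParams pathway_generator
#' @return A probability in (0, 1].
#' @examples
#' compensatory_route_prob(rate_set(1, 0.1, 1, 0.1, 0.1))
#' @export
compensatory_route_prob <- function(rates) {
  r <- as_rate_set(rates)
  k1 <- r[["k1"]]
  k_m1 <- r[["k_m1"]]
  k2 <- r[["k2"]]
  k3 <- r[["k3"]]
  if (k1 + k3 == 0) {
    stop("route undefined: P is unreachable from S (k1 + k3 = 0)", call. = FALSE)
  }
  if (k3 == 0 && k2 == 0) {
    stop("route undefined: P is unreachable from S (k3 = 0 and k2 = 0)", call. = FALSE)
  }
  a <- k3 / (k1 + k3)
  b <- k1 / (k1 + k3)
  cc <- if (k2 + k_m1 == 0) 0 else k_m1 / (k2 + k_m1)
  a / (1 - b * cc)
}
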