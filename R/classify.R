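#' Pathway fate labels
#'
#' The five qualitative outcomes used throughout the package:
#' `REPAIRED_MAIN` (repaired, predominantly through the main route),
#' `COMPENSATED` (repaired, predominantly through the compensatory route),
#' `DD` (death by accumulated DNA damage: long-time `S` probability above the
#' threshold), `DT` (death by toxic intermediate: long-time `I` probability
#' above the threshold) and `DEAD_MIXED` (not repaired, but neither single dead
#' state exceeds the threshold).
#'
#' @format Character vector of the five labels.
#' @export
fate_levels <- c("REPAIRED_MAIN", "COMPENSATED", "DD", "DT", "DEAD_MIXED")

#' Control parameters of the fate classification
#'
#' The long-time classification is governed by three rate ratios:
#' `r1 = k1 / k_m1` and `r2 = k2 / k_m2` (forward over backward, per step) and
#' `rb = k_m1 / k_m2` (the ratio of the two backward rates, which separates the
#' robust from the fragile normal regime). Ratios with a zero denominator and a
#' positive numerator are `Inf`; `0/0` ratios are returned as `NaN` (undefined).
#'
#' These formulas are a documented reconstruction: they are the unique
#' forward/backward-per-step plus backward/backward choices consistent with the
#' degenerate phase-diagram slices (the `k_m1 = 0` slice varies only `r2`, so
#' `r2` cannot contain `k_m1`; the `k1 = 0` slice replaces `r1`, so `r1` must
#' contain `k1`).
#'
#' @inheritParams pathway_generator
#' @return A one-row tibble with columns `r1`, `r2`, `rb`.
#' @examples
#' control_parameters(rate_set(1, 0.1, 1, 0.001, 0.1))
#' @export
control_parameters <- function(rates) {
  r <- as_rate_set(rates)
  ratio <- function(num, den) {
    if (den == 0) {
      if (num == 0) NaN else Inf
    } else {
      num / den
    }
  }
  tibble::tibble(
    r1 = ratio(r[["k1"]], r[["k_m1"]]),
    r2 = ratio(r[["k2"]], r[["k_m2"]]),
    rb = ratio(r[["k_m1"]], r[["k_m2"]])
  )
}

#' Classify the long-time fate of a genotype
#'
#' Computes the limiting distribution from freshly damaged DNA (`S = 1`) and
#' applies the fate rules: repaired if the long-time `P` probability strictly
#' exceeds `threshold` (then `COMPENSATED` when the first passage into `P` runs
#' through the compensatory edge with probability > 0.5, otherwise
#' `REPAIRED_MAIN`); otherwise `DD` / `DT` if the long-time `S` / `I`
#' probability strictly exceeds `threshold`; `DEAD_MIXED` otherwise.
#' Probabilities exactly equal to the threshold are not above it.
#'
#' @inheritParams simulate_pathway
#' @param threshold Fate threshold, default 0.5 (the ">50%" rule).
#' @return A single string among [fate_levels].
#' @examples
#' classify_fate(rate_set(0, 0.1, 1, 0.1, 0)) # bpSL double knockout -> "DD"
#' classify_fate(rate_set(1, 0, 0, 0.1, 0.1)) # wrpSL double knockout -> "DT"
#' @export
classify_fate <- function(rates, threshold = 0.5, initial = state_damaged) {
  r <- as_rate_set(rates)
  d <- limiting_state(r, initial)
  if (d[["P"]] > threshold) {
    route <- tryCatch(compensatory_route_prob(r), error = function(e) NA_real_)
    if (!is.na(route) && route > 0.5) "COMPENSATED" else "REPAIRED_MAIN"
  } else if (d[["S"]] > threshold) {
    "DD"
  } else if (d[["I"]] > threshold) {
    "DT"
  } else {
    "DEAD_MIXED"
  }
}

#' Single-knockout robustness of a viable genotype
#'
#' A viable (repaired) rate set is "normal robust" (`NR`) when every one of the
#' five single knockouts (each rate set to zero in turn) still leads to a
#' repaired fate, and "normal fragile" (`NF`) when at least one single knockout
#' is lethal.
#'
#' @inheritParams classify_fate
#' @return A list of class `baseline_class` with elements `label` (`"NR"` or
#'   `"NF"`) and `knockouts`, a five-row tibble (`enzyme`, `rate`, `fate`,
#'   `viable`) giving the per-knockout fate table.
#' @examples
#' classify_baseline(rate_set(1, 0.1, 1, 0.001, 0.1))$label # "NR"
#' classify_baseline(rate_set(1, 0.1, 1, 0.1, 0.1))$label # "NF"
#' @export
classify_baseline <- function(rates, threshold = 0.5) {
  r <- as_rate_set(rates)
  base_fate <- classify_fate(r, threshold)
  if (!base_fate %in% c("REPAIRED_MAIN", "COMPENSATED")) {
    stop("baseline not viable: unperturbed fate is ", base_fate, call. = FALSE)
  }
  ko <- purrr::map_chr(rate_names, function(k) {
    r2 <- unclass(r)
    r2[[k]] <- 0
    if (all(r2 == 0)) {
      return("DD") # nothing moves; damage persists
    }
    classify_fate(as_rate_set(r2), threshold)
  })
  tab <- tibble::tibble(
    enzyme = enzyme_names,
    rate = rate_names,
    fate = ko,
    viable = ko %in% c("REPAIRED_MAIN", "COMPENSATED")
  )
  structure(
    list(label = if (all(tab$viable)) "NR" else "NF", knockouts = tab),
    class = "baseline_class"
  )
}

#' @export
print.baseline_class <- function(x, ...) {
  cat("<baseline_class>", x$label, "\n")
  print(x$knockouts, ...)
  invisible(x)
}

#' Phase-diagram color of a state distribution
#'
#' The coloring rule used in the phase diagrams: `RED` when the repaired
#' probability `P` strictly exceeds 0.5; otherwise `GREEN` when the
#' intermediate-trapping probability `I` exceeds the unrepaired-substrate
#' probability `S`, and `BLUE` in the opposite case.
#'
#' @param S,I,P Numeric vectors forming valid distributions row-wise (recycled
#'   to a common length).
#' @return Character vector of `"RED"`, `"GREEN"`, `"BLUE"`.
#' @examples
#' phase_color(0.1, 0.1, 0.8)
#' phase_color(c(0.2, 0.5), c(0.5, 0.2), c(0.3, 0.3))
#' @export
phase_color <- function(S, I, P) {
  n <- max(length(S), length(I), length(P))
  S <- rep_len(S, n)
  I <- rep_len(I, n)
  P <- rep_len(P, n)
  if (any(abs(S + I + P - 1) > 1e-9) || any(c(S, I, P) < -1e-12)) {
    stop("phase_color expects valid probability distributions", call. = FALSE)
  }
  ifelse(P > 0.5, "RED", ifelse(I > S, "GREEN", "BLUE"))
}

#' Full classification of one genotype
#'
#' Bundles the limiting distribution, control parameters, compensatory-route
#' probability, fate and (for viable genotypes) the single-knockout robustness
#' label into one object with [generics::tidy()] and [generics::glance()]
#' methods.
#'
#' @inheritParams classify_fate
#' @return An object of class `pathway_class`.
#' @examples
#' cls <- classify_pathway(rate_set(1, 0.1, 1, 0.1, 0.1))
#' glance(cls)
#' tidy(cls)
#' @export
classify_pathway <- function(rates, threshold = 0.5) {
  r <- as_rate_set(rates)
  d <- limiting_state(r)
  fate <- classify_fate(r, threshold)
  route <- tryCatch(compensatory_route_prob(r), error = function(e) NA_real_)
  baseline <- if (fate %in% c("REPAIRED_MAIN", "COMPENSATED")) {
    classify_baseline(r, threshold)
  } else {
    NULL
  }
  structure(
    list(
      rates = r, limiting = d, control = control_parameters(r),
      route_prob = route, fate = fate, threshold = threshold,
      baseline = baseline
    ),
    class = "pathway_class"
  )
}

#' @export
print.pathway_class <- function(x, ...) {
  cat("<pathway_class> fate:", x$fate)
  if (!is.null(x$baseline)) cat("  baseline:", x$baseline$label)
  cat("\n  limiting state: S =", signif(x$limiting[["S"]], 4),
      " I =", signif(x$limiting[["I"]], 4),
      " P =", signif(x$limiting[["P"]], 4), "\n")
  invisible(x)
}

#' @describeIn classify_pathway One row per model state with its limiting
#'   probability.
#' @param x A `pathway_class` object.
#' @param ... Unused.
#' @export
tidy.pathway_class <- function(x, ...) {
  tibble::tibble(
    state = pathway_states,
    description = c("damage substrate", "toxic intermediate", "repaired product"),
    limiting_probability = as.numeric(x$limiting)
  )
}

#' @describeIn classify_pathway One-row summary: fate, baseline label, control
#'   parameters, route probability and limiting probabilities.
#' @export
glance.pathway_class <- function(x, ...) {
  tibble::tibble(
    fate = x$fate,
    baseline = if (is.null(x$baseline)) NA_character_ else x$baseline$label,
    r1 = x$control$r1, r2 = x$control$r2, rb = x$control$rb,
    route_prob = x$route_prob,
    S = x$limiting[["S"]], I = x$limiting[["I"]], P = x$limiting[["P"]],
    threshold = x$threshold
  )
}
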