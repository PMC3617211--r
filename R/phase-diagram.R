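#' Log-spaced grid helper
#'
#' @param from,to Positive endpoints.
#' @param n Number of points.
#' @return Numeric vector of `n` log-spaced values.
#' @export
log_seq <- function(from = 1e-2, to = 1e2, n = 41) {
  stopifnot(from > 0, to > from, n >= 1)
  exp(seq(log(from), log(to), length.out = n))
}

#' Specify a phase-diagram grid
#'
#' A phase diagram sweeps the control-parameter plane `r2 x r1`
#' (`r1 = k1/k_m1`, `r2 = k2/k_m2`) at fixed anchor rates, and classifies every
#' cell's long-time state by color (see [phase_color()]). Three slice modes are
#' supported:
#'
#' * `"FULL"` — both ratios swept; `k1 = r1 * k_m1`, `k2 = r2 * k_m2`.
#' * `"K1_ZERO"` — the upstream-block slice (`k1 = 0`). `r1` is undefined
#'   there, so the first axis instead sweeps the reconstruction parameter
#'   `k3 / k_m1` (the compensatory rate is swept in place of `k1`); the `k3`
#'   anchor is ignored.
#' * `"KM1_ZERO"` — the irreversible-first-step slice (`k_m1 = 0`). Only `r2`
#'   is swept; `k1` is taken from the anchor and the first axis collapses to a
#'   single `Inf` placeholder.
#'
#' The backward-rate regime is set through the anchors: `rb = k_m1 / k_m2`.
#'
#' @param r1_values,r2_values Positive grid values for the two axes (defaults:
#'   41 log-spaced points over `[1e-2, 1e2]`).
#' @param anchors Named vector of fixed rates `c(k1=, k_m1=, k_m2=, k3=)`; the
#'   `k1` anchor is used only by `"KM1_ZERO"`.
#' @param slice One of `"FULL"`, `"K1_ZERO"`, `"KM1_ZERO"`.
#' @return An object of class `phase_grid`.
#' @examples
#' phase_grid(anchors = c(k1 = 1, k_m1 = 0.1, k_m2 = 0.001, k3 = 0.1))
#' @export
phase_grid <- function(r1_values = log_seq(),
                       r2_values = log_seq(),
                       anchors = c(k1 = 1, k_m1 = 0.1, k_m2 = 0.1, k3 = 0.1),
                       slice = c("FULL", "K1_ZERO", "KM1_ZERO")) {
  slice <- match.arg(slice)
  full <- c(k1 = 1, k_m1 = 0.1, k_m2 = 0.1, k3 = 0.1)
  if (is.null(names(anchors)) || !all(names(anchors) %in% names(full))) {
    stop("anchors must be named among k1, k_m1, k_m2, k3", call. = FALSE)
  }
  full[names(anchors)] <- anchors
  anchors <- full
  if (any(anchors < 0) || anyNA(anchors)) {
    stop("anchor rates must be non-negative", call. = FALSE)
  }
  if (length(r1_values) == 0 || length(r2_values) == 0) {
    stop("empty grid", call. = FALSE)
  }
  if (any(r1_values <= 0) || any(r2_values <= 0)) {
    stop("grid values must be positive", call. = FALSE)
  }
  if (slice %in% c("FULL", "K1_ZERO") && anchors[["k_m1"]] == 0) {
    stop("slice ", slice, " needs a positive k_m1 anchor", call. = FALSE)
  }
  if (anchors[["k_m2"]] == 0) {
    stop("r2 is undefined with a zero k_m2 anchor", call. = FALSE)
  }
  if (slice == "KM1_ZERO") {
    if (anchors[["k1"]] == 0) {
      stop("KM1_ZERO slice needs a positive k1 anchor", call. = FALSE)
    }
    r1_values <- Inf # axis collapses: r1 = k1/0
  }
  structure(
    list(
      r1_values = as.numeric(r1_values), r2_values = as.numeric(r2_values),
      anchors = anchors, slice = slice
    ),
    class = "phase_grid"
  )
}

#' Rate set at one grid point
#'
#' Inverts the control-parameter map for the given slice mode (see
#' [phase_grid()] for the slice definitions).
#'
#' @param spec A [phase_grid()].
#' @param r1 First-axis value (`r1`, or `k3/k_m1` for `"K1_ZERO"`; ignored for
#'   `"KM1_ZERO"`).
#' @param r2 Second-axis value (`r2 = k2/k_m2`).
#' @return A `rate_set`.
#' @export
rates_from_grid_point <- function(spec, r1, r2) {
  stopifnot(inherits(spec, "phase_grid"))
  a <- spec$anchors
  k2 <- r2 * a[["k_m2"]]
  switch(spec$slice,
    FULL = rate_set(r1 * a[["k_m1"]], a[["k_m1"]], k2, a[["k_m2"]], a[["k3"]]),
    K1_ZERO = rate_set(0, a[["k_m1"]], k2, a[["k_m2"]], r1 * a[["k_m1"]]),
    KM1_ZERO = rate_set(a[["k1"]], 0, k2, a[["k_m2"]], a[["k3"]])
  )
}

#' Compute a phase diagram
#'
#' Classifies every grid cell by its limiting distribution from freshly damaged
#' DNA (`S = 1`) and the red/green/blue rule of [phase_color()]. Deterministic.
#'
#' @inheritParams rates_from_grid_point
#' @param initial Initial distribution (default all mass in `S`), so reducible
#'   (knockout) cells have a well-defined limit.
#' @return An object of class `phase_diagram`: list with the `spec` and a
#'   long-format tibble `cells` (`r1`, `r2`, `S`, `I`, `P`, `color`), ordered by
#'   `r1` then `r2`.
#' @examples
#' pd <- compute_phase_diagram(phase_grid(log_seq(n = 5), log_seq(n = 5)))
#' head(pd$cells)
#' @export
compute_phase_diagram <- function(spec, initial = state_damaged) {
  stopifnot(inherits(spec, "phase_grid"))
  grid <- tidyr::expand_grid(r1 = spec$r1_values, r2 = spec$r2_values)
  states <- purrr::map2(grid$r1, grid$r2, function(a1, a2) {
    limiting_state(rates_from_grid_point(spec, a1, a2), initial)
  })
  cells <- dplyr::mutate(grid,
    S = purrr::map_dbl(states, "S"),
    I = purrr::map_dbl(states, "I"),
    P = purrr::map_dbl(states, "P"),
    color = phase_color(.data$S, .data$I, .data$P)
  )
  structure(list(spec = spec, cells = cells), class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(
    "<phase_diagram>", x$spec$slice, "slice,",
    length(x$spec$r1_values), "x", length(x$spec$r2_values), "grid, rb =",
    signif(x$spec$anchors[["k_m1"]] / x$spec$anchors[["k_m2"]], 4), "\n"
  )
  print(dplyr::count(x$cells, .data$color), ...)
  invisible(x)
}

#' @describeIn compute_phase_diagram Long-format tibble of the cells, including
#'   the anchors and slice as columns.
#' @param x A `phase_diagram`.
#' @param ... Unused.
#' @export
tidy.phase_diagram <- function(x, ...) {
  dplyr::mutate(x$cells,
    slice = x$spec$slice,
    k_m1 = x$spec$anchors[["k_m1"]],
    k_m2 = x$spec$anchors[["k_m2"]],
    k3 = x$spec$anchors[["k3"]]
  )
}

#' @describeIn compute_phase_diagram One-row summary with the color counts.
#' @export
glance.phase_diagram <- function(x, ...) {
  tibble::tibble(
    slice = x$spec$slice,
    n_r1 = length(x$spec$r1_values),
    n_r2 = length(x$spec$r2_values),
    rb = x$spec$anchors[["k_m1"]] / x$spec$anchors[["k_m2"]],
    n_red = sum(x$cells$color == "RED"),
    n_green = sum(x$cells$color == "GREEN"),
    n_blue = sum(x$cells$color == "BLUE")
  )
}

#' Export / re-import a phase diagram as TSV
#'
#' Writes the long-format cells (`r1`, `r2`, `S`, `I`, `P`, `color`) preceded
#' by `#`-comment metadata lines recording the slice mode and anchor rates
#' (including the note that the `K1_ZERO` first axis is the reconstruction
#' parameter `k3/k_m1`). `read_phase_diagram()` round-trips the table; the color
#' matrix is reproduced exactly.
#'
#' @param diagram A `phase_diagram`.
#' @param path Output file path.
#' @return `export_phase_diagram()` returns `path` invisibly;
#'   `read_phase_diagram()` returns the cells tibble with the metadata in
#'   attributes `slice` and `anchors`.
#' @export
export_phase_diagram <- function(diagram, path) {
  stopifnot(inherits(diagram, "phase_diagram"))
  if (nrow(diagram$cells) == 0) {
    stop("empty phase diagram", call. = FALSE)
  }
  a <- diagram$spec$anchors
  meta <- c(
    paste0("# slice: ", diagram$spec$slice),
    sprintf("# anchors: k1=%.17g k_m1=%.17g k_m2=%.17g k3=%.17g",
            a[["k1"]], a[["k_m1"]], a[["k_m2"]], a[["k3"]]),
    if (diagram$spec$slice == "K1_ZERO") {
      "# note: r1 column holds the reconstruction parameter k3/k_m1"
    }
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(diagram$cells, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname export_phase_diagram
#' @export
read_phase_diagram <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  cells <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
    col_types = readr::cols(
      r1 = "d", r2 = "d", S = "d", I = "d", P = "d", color = "c"
    ),
    progress = FALSE
  )
  slice <- sub("^# slice: ", "", grep("^# slice: ", meta, value = TRUE))
  attr(cells, "slice") <- if (length(slice) == 1) slice else NA_character_
  attr(cells, "anchors") <- sub(
    "^# anchors: ", "",
    grep("^# anchors: ", meta, value = TRUE)[1]
  )
  cells
}

#' Plot a phase diagram
#'
#' Raster plot of the red/green/blue classification over the log-scaled
#' control-parameter plane.
#'
#' @param object A `phase_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phase_diagram <- function(object, ...) {
  cells <- object$cells
  x_lab <- if (object$spec$slice == "K1_ZERO") "k3 / k_m1" else "r1 = k1 / k_m1"
  if (object$spec$slice == "KM1_ZERO") {
    cells$r1 <- 1 # single collapsed row; keep a drawable coordinate
    x_lab <- "(r1 = Inf)"
  }
  ggplot2::ggplot(cells, ggplot2::aes(.data$r1, .data$r2, fill = .data$color)) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_manual(
      values = c(RED = "#d7301f", GREEN = "#31a354", BLUE = "#3182bd"),
      name = "long-time state"
    ) +
    ggplot2::labs(
      x = x_lab, y = "r2 = k2 / k_m2",
      title = sprintf(
        "Pathway fate phase diagram (%s slice, rb = %.3g)",
        object$spec$slice,
        object$spec$anchors[["k_m1"]] / object$spec$anchors[["k_m2"]]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated time course
#'
#' @param object A `pathway_timecourse` from [simulate_pathway()].
#' @param ... Unused.
#' @return A ggplot object with one line per state.
#' @export
autoplot.pathway_timecourse <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("S", "I", "P"),
    names_to = "state", values_to = "probability"
  )
  long$state <- factor(long$state, levels = pathway_states)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$probability,
    color = .data$state
  )) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_color_manual(values = c(
      S = "#3182bd", I = "#31a354", P = "#d7301f"
    )) +
    ggplot2::labs(x = "time (arbitrary units)", y = "state probability") +
    ggplot2::theme_minimal()
}
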