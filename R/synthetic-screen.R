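#' Reference rate sets for the two normal regimes
#'
#' Both references satisfy the normal-regime constraint that forward steps are
#' faster than backward steps (`k1 > k_m1`, `k2 > k_m2`). They differ only in
#' the second backward rate, i.e. in the backward-rate ratio `rb = k_m1/k_m2`:
#'
#' * `NR` (normal robust), `rb = 100`: every single knockout still repairs.
#' * `NF` (normal fragile), `rb = 1`: the F2 knockout is lethal (toxic
#'   trapping), all other single knockouts survive.
#'
#' @return Named list with `rate_set`s `NR` and `NF`.
#' @examples
#' reference_ratesets()
#' @export
reference_ratesets <- function() {
  list(
    NR = rate_set(1, 0.1, 1, 0.001, 0.1),
    NF = rate_set(1, 0.1, 1, 0.1, 0.1)
  )
}

#' Configure a synthetic genetic-interaction screen
#'
#' Describes the generative model for a synthetic screen emulating a
#' genome-wide epistasis dataset: a gene universe, planted pathways with
#' complexes nested inside them, and per-pair Bernoulli rates of negative
#' interaction — a background rate for random pairs, an elevated rate inside
#' planted pathways, and a separate rate for within-complex pairs. Negative
#' pairs receive epistasis values drawn strictly inside the stringent filter
#' (`epsilon` uniform on `neg_epsilon`, p-value uniform on `[0, 0.01]`); a
#' configurable fraction of the remaining null pairs is emitted with mild
#' `epsilon` (uniform on `null_epsilon`, p-value uniform on `[0, 1]`) so the
#' filtering step is exercised.
#'
#' @param n_genes Size of the gene universe (identifiers `g0001`, ...).
#' @param pathway_sizes Integer vector of planted pathway sizes (assigned
#'   disjointly from the start of the universe).
#' @param complex_sizes List (one element per pathway) of integer vectors of
#'   complex sizes nested inside that pathway (complexes disjoint within a
#'   pathway). When `pathway_sizes` is supplied without `complex_sizes`, no
#'   complexes are planted.
#' @param planted_pathways Indices of the pathways that carry the elevated
#'   within-pathway rate (default: the first). Pairs inside non-planted (decoy)
#'   pathways interact at the background rate.
#' @param p_bg,p_wp,p_c Per-pair probabilities of a negative interaction for
#'   background pairs, pairs within a planted pathway and within-complex pairs
#'   (`0 <= p_bg <= p_wp <= 1`, `0 <= p_c <= 1`).
#' @param null_fraction Fraction of non-negative pairs emitted as mild null
#'   records.
#' @param neg_epsilon,null_epsilon Length-2 ranges for the epsilon draws.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_genes = 200,
                          pathway_sizes = c(20, 15, 15),
                          complex_sizes = NULL,
                          planted_pathways = 1L,
                          p_bg = 0.02,
                          p_wp = 0.2,
                          p_c = 0.5,
                          null_fraction = 0.05,
                          neg_epsilon = c(-0.6, -0.15),
                          null_epsilon = c(-0.08, 0.08)) {
  if (is.null(complex_sizes)) {
    complex_sizes <- if (missing(pathway_sizes)) {
      list(5, 4, integer(0)) # documented default layout
    } else {
      rep(list(integer(0)), length(pathway_sizes))
    }
  }
  stopifnot(
    n_genes >= 2,
    all(pathway_sizes >= 2),
    length(complex_sizes) == length(pathway_sizes)
  )
  if (sum(pathway_sizes) > n_genes) {
    stop("infeasible sizes: pathways exceed the gene universe", call. = FALSE)
  }
  for (i in seq_along(complex_sizes)) {
    if (sum(complex_sizes[[i]]) > pathway_sizes[i]) {
      stop("infeasible sizes: complexes exceed their pathway", call. = FALSE)
    }
  }
  if (!(p_bg >= 0 && p_bg <= p_wp && p_wp <= 1)) {
    stop("need 0 <= p_bg <= p_wp <= 1", call. = FALSE)
  }
  if (p_c < 0 || p_c > 1 || null_fraction < 0 || null_fraction > 1) {
    stop("p_c and null_fraction must be probabilities", call. = FALSE)
  }
  planted_pathways <- as.integer(planted_pathways)
  if (!all(planted_pathways %in% seq_along(pathway_sizes))) {
    stop("planted_pathways must index pathway_sizes", call. = FALSE)
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      pathway_sizes = as.integer(pathway_sizes),
      complex_sizes = lapply(complex_sizes, as.integer),
      planted_pathways = planted_pathways,
      p_bg = p_bg, p_wp = p_wp, p_c = p_c,
      null_fraction = null_fraction,
      neg_epsilon = neg_epsilon, null_epsilon = null_epsilon
    ),
    class = "screen_config"
  )
}

# Deterministic memberships implied by a config (no randomness: pathways are
# consecutive blocks of the universe, complexes consecutive blocks of each
# pathway).
screen_memberships <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  offsets <- cumsum(c(0, utils::head(config$pathway_sizes, -1)))
  pathways <- purrr::map_dfr(seq_along(config$pathway_sizes), function(i) {
    tibble::tibble(
      set_id = sprintf("pw%02d", i),
      description = sprintf("planted pathway %d", i),
      gene = genes[offsets[i] + seq_len(config$pathway_sizes[i])]
    )
  })
  complexes <- purrr::map_dfr(seq_along(config$complex_sizes), function(i) {
    sizes <- config$complex_sizes[[i]]
    if (length(sizes) == 0) {
      return(NULL)
    }
    pw_genes <- pathways$gene[pathways$set_id == sprintf("pw%02d", i)]
    cx_off <- cumsum(c(0, utils::head(sizes, -1)))
    purrr::map_dfr(seq_along(sizes), function(j) {
      tibble::tibble(
        set_id = sprintf("pw%02d_cx%02d", i, j),
        description = sprintf("complex %d nested in pathway %d", j, i),
        gene = pw_genes[cx_off[j] + seq_len(sizes[j])]
      )
    })
  })
  list(genes = genes, pathways = pathways, complexes = complexes)
}

#' Generate a seeded synthetic interaction screen
#'
#' Draws the screen described by a [screen_config()]: every unordered gene pair
#' independently becomes a negative interaction with the rate of its label
#' (within-complex > within-pathway > background precedence), and a fraction of
#' the remaining pairs is emitted as mild null records. Fully reproducible from
#' `seed`.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed driving all randomness.
#' @return A list with elements `interactions` (tibble `gene_a`, `gene_b`,
#'   `epsilon`, `p_value`), `pathways` and `complexes` (long gene-set tibbles)
#'   and `truth` (per-pair tibble `gene_a`, `gene_b`, `label`, `negative` with
#'   `label` one of `background` / `within_pathway` / `within_complex`).
#' @examples
#' screen <- simulate_interaction_screen(screen_config(n_genes = 50,
#'   pathway_sizes = c(10, 8), complex_sizes = list(3, integer(0))
#' ), seed = 1)
#' head(screen$interactions)
#' @export
simulate_interaction_screen <- function(config = screen_config(), seed = 1L) {
  stopifnot(inherits(config, "screen_config"))
  mem <- screen_memberships(config)
  genes <- mem$genes

  idx <- utils::combn(length(genes), 2)
  pairs <- tibble::tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])

  planted_ids <- sprintf("pw%02d", config$planted_pathways)
  pw_pairs <- co_member_pairs(
    dplyr::filter(mem$pathways, .data$set_id %in% planted_ids)
  )
  cx_pairs <- co_member_pairs(mem$complexes)
  key <- function(x) paste(x$gene_a, x$gene_b, sep = "\r")
  label <- rep("background", nrow(pairs))
  label[key(pairs) %in% key(pw_pairs)] <- "within_pathway"
  label[key(pairs) %in% key(cx_pairs)] <- "within_complex"
  rate <- c(
    background = config$p_bg,
    within_pathway = config$p_wp,
    within_complex = config$p_c
  )[label]

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  negative <- stats::runif(nrow(pairs)) < rate
  keep_null <- !negative & stats::runif(nrow(pairs)) < config$null_fraction

  n_neg <- sum(negative)
  n_null <- sum(keep_null)
  interactions <- dplyr::bind_rows(
    dplyr::mutate(pairs[negative, ],
      epsilon = stats::runif(n_neg, config$neg_epsilon[1], config$neg_epsilon[2]),
      p_value = stats::runif(n_neg, 0, 0.01)
    ),
    dplyr::mutate(pairs[keep_null, ],
      epsilon = stats::runif(n_null, config$null_epsilon[1], config$null_epsilon[2]),
      p_value = stats::runif(n_null, 0, 1)
    )
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)

  list(
    interactions = interactions,
    pathways = mem$pathways,
    complexes = mem$complexes,
    planted = planted_ids,
    truth = dplyr::mutate(pairs, label = label, negative = negative)
  )
}

#' Expected normalized proportions under the generative model
#'
#' Closed-form check of the generator: for each pathway, the expected value of
#' the enrichment statistic is its per-pair negative rate (`p_wp` if planted,
#' `p_bg` otherwise) applied to the pairs that survive the within-complex
#' exclusion, `rate * (N_pairs - N_complex_pairs) / N_pairs` with
#' `N_pairs = S(S-1)/2` (within-complex pairs are generated at rate `p_c` but
#' excluded from the count, so they contribute zero).
#'
#' @inheritParams simulate_interaction_screen
#' @return A tibble with columns `pathway`, `planted`, `n_genes`, `n_pairs`,
#'   `n_complex_pairs`, `expected_proportion`.
#' @examples
#' expected_proportions(screen_config())
#' @export
expected_proportions <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  purrr::map_dfr(seq_along(config$pathway_sizes), function(i) {
    s <- config$pathway_sizes[i]
    n_pairs <- s * (s - 1) / 2
    n_cx <- sum(vapply(
      config$complex_sizes[[i]],
      function(m) m * (m - 1) / 2, numeric(1)
    ))
    planted <- i %in% config$planted_pathways
    rate <- if (planted) config$p_wp else config$p_bg
    tibble::tibble(
      pathway = sprintf("pw%02d", i),
      planted = planted,
      n_genes = s,
      n_pairs = n_pairs,
      n_complex_pairs = n_cx,
      expected_proportion = rate * (n_pairs - n_cx) / n_pairs
    )
  })
}

#' Write a synthetic screen to disk
#'
#' Writes `interactions.tsv`, `pathways.gmt`, `complexes.gmt` and `truth.tsv`
#' into a directory, in the formats read back by [read_interactions()] and
#' [read_gmt()].
#'
#' @param screen Output of [simulate_interaction_screen()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(screen$interactions, file.path(dir, "interactions.tsv"),
    progress = FALSE
  )
  write_gmt(screen$pathways, file.path(dir, "pathways.gmt"))
  if (nrow(screen$complexes) > 0) {
    write_gmt(screen$complexes, file.path(dir, "complexes.gmt"))
  } else {
    file.create(file.path(dir, "complexes.gmt"))
  }
  readr::write_tsv(screen$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
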