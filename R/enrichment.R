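#' Read a pairwise genetic-interaction table
#'
#' Expects a TSV with header columns `gene_a`, `gene_b`, `epsilon` (the
#' epistasis measure) and `p_value`. Self-pairs are rejected; pair identity is
#' unordered (`(a, b)` and `(b, a)` name the same pair).
#'
#' @param path TSV file path.
#' @return A tibble with the four columns.
#' @export
read_interactions <- function(path) {
  x <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_a = "c", gene_b = "c", epsilon = "d", p_value = "d"
    ),
    progress = FALSE
  )
  validate_interactions(x)
}

#' @noRd
validate_interactions <- function(x) {
  req <- c("gene_a", "gene_b", "epsilon", "p_value")
  if (!all(req %in% names(x))) {
    stop("interaction table needs columns gene_a, gene_b, epsilon, p_value",
      call. = FALSE
    )
  }
  if (any(x$gene_a == x$gene_b)) {
    stop("self-interactions (gene_a == gene_b) are not allowed", call. = FALSE)
  }
  if (any(x$p_value < 0 | x$p_value > 1, na.rm = TRUE)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(x)
}

# Canonical unordered pair representation: gene_a <= gene_b lexicographically.
canonicalize_pairs <- function(x) {
  dplyr::mutate(x,
    .a = pmin(.data$gene_a, .data$gene_b),
    .b = pmax(.data$gene_a, .data$gene_b),
    gene_a = .data$.a, gene_b = .data$.b,
    .a = NULL, .b = NULL
  )
}

#' Read / write gene sets in GMT format
#'
#' GMT is the conventional tab-separated gene-set format: one set per line,
#' `set_id <TAB> description <TAB> member1 <TAB> member2 ...`. Used here for
#' both pathway and complex memberships.
#'
#' @param path File path.
#' @return `read_gmt()` returns a long tibble with columns `set_id`,
#'   `description`, `gene` (members unique within a set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(
      set_id = character(), description = character(), gene = character()
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("malformed GMT line (need id, description, >=1 member): line ",
      which(bad)[1],
      call. = FALSE
    )
  }
  out <- purrr::map_dfr(parts, function(p) {
    tibble::tibble(
      set_id = p[1], description = p[2],
      gene = unique(p[-(1:2)][nzchar(p[-(1:2)])])
    )
  })
  if (anyDuplicated(unique(out[c("set_id", "description")])$set_id)) {
    stop("duplicate set_id in GMT file", call. = FALSE)
  }
  out
}

#' @rdname read_gmt
#' @param sets A long tibble with columns `set_id`, `description` (optional),
#'   `gene`.
#' @export
write_gmt <- function(sets, path) {
  if (!"description" %in% names(sets)) sets$description <- "na"
  lines <- sets |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      line = paste(c(
        .data$set_id[1], .data$description[1],
        unique(.data$gene)
      ), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}

#' Filter to stringent negative interactions
#'
#' Keeps records with `epsilon < epsilon_max` (a negative cutoff) and
#' `p_value < p_max`, then deduplicates unordered pairs, keeping the most
#' negative `epsilon` per pair.
#'
#' @param records Interaction tibble (`gene_a`, `gene_b`, `epsilon`,
#'   `p_value`).
#' @param epsilon_max Epistasis cutoff; must be negative (default -0.12, the
#'   conventional stringent cutoff for genome-wide yeast screens).
#' @param p_max P-value cutoff (default 0.05).
#' @return Filtered, pair-deduplicated tibble with canonical `gene_a < gene_b`.
#' @examples
#' x <- tibble::tibble(
#'   gene_a = c("A", "B"), gene_b = c("B", "A"),
#'   epsilon = c(-0.2, -0.3), p_value = c(0.01, 0.001)
#' )
#' filter_negative(x)
#' @export
filter_negative <- function(records, epsilon_max = -0.12, p_max = 0.05) {
  if (!is.numeric(epsilon_max) || !is.finite(epsilon_max) || epsilon_max >= 0) {
    stop("epsilon_max must be a finite negative number", call. = FALSE)
  }
  if (!is.numeric(p_max) || !is.finite(p_max)) {
    stop("p_max must be finite", call. = FALSE)
  }
  records <- validate_interactions(records)
  records |>
    dplyr::filter(.data$epsilon < epsilon_max, .data$p_value < p_max) |>
    canonicalize_pairs() |>
    dplyr::arrange(.data$epsilon) |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE)
}

# Unique unordered gene pairs co-occurring in at least one of the given sets.
co_member_pairs <- function(sets) {
  if (nrow(sets) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  sets |>
    dplyr::distinct(.data$set_id, .data$gene) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::reframe({
      g <- sort(.data$gene)
      if (length(g) < 2) {
        tibble::tibble(gene_a = character(), gene_b = character())
      } else {
        idx <- utils::combn(length(g), 2)
        tibble::tibble(gene_a = g[idx[1, ]], gene_b = g[idx[2, ]])
      }
    }) |>
    dplyr::distinct(.data$gene_a, .data$gene_b)
}

#' Count within-pathway negative interactions
#'
#' For one pathway, counts the filtered negative pairs whose two genes are both
#' pathway members (`n_neg_within`) and, of those, the pairs that are also
#' co-members of at least one molecular complex (`n_neg_within_complex`) — the
#' pairs excluded from the enrichment statistic.
#'
#' @param negatives Output of [filter_negative()].
#' @param pathway_genes Character vector of the pathway's member genes.
#' @param complexes Long gene-set tibble (as from [read_gmt()]) of complex
#'   memberships; may be empty.
#' @return Named integer vector `c(n_neg_within =, n_neg_within_complex =)`.
#' @examples
#' neg <- tibble::tibble(
#'   gene_a = c("A", "A", "D"), gene_b = c("B", "C", "E"),
#'   epsilon = -0.3, p_value = 0.001
#' )
#' cx <- tibble::tibble(set_id = "c1", description = "", gene = c("D", "E"))
#' within_pathway_counts(neg, c("A", "B", "C", "D", "E"), cx)
#' @export
within_pathway_counts <- function(negatives, pathway_genes, complexes = NULL) {
  negatives <- canonicalize_pairs(validate_interactions(negatives))
  inside <- dplyr::filter(
    negatives,
    .data$gene_a %in% pathway_genes & .data$gene_b %in% pathway_genes
  )
  if (is.null(complexes) || nrow(inside) == 0) {
    n_cx <- 0L
  } else {
    cx_pairs <- co_member_pairs(complexes)
    n_cx <- nrow(dplyr::semi_join(inside, cx_pairs,
      by = c("gene_a", "gene_b")
    ))
  }
  c(n_neg_within = nrow(inside), n_neg_within_complex = n_cx)
}

#' Normalized within-pathway interaction proportion
#'
#' The enrichment statistic: the number of within-pathway negative interactions
#' remaining after the within-complex exclusion, divided by the number of all
#' possible pairs `S(S-1)/2` for a pathway of `S` genes.
#'
#' @param n_neg_excl_complex Count of within-pathway negative pairs not
#'   explained by complex co-membership.
#' @param n_genes Pathway size `S` (must be >= 2).
#' @return The proportion.
#' @examples
#' normalized_proportion(27, 20) # 27 / 190
#' @export
normalized_proportion <- function(n_neg_excl_complex, n_genes) {
  if (any(n_genes < 2)) {
    stop("normalized proportion undefined for pathways of size < 2",
      call. = FALSE
    )
  }
  n_neg_excl_complex / (n_genes * (n_genes - 1) / 2)
}

#' Rank pathways by within-pathway negative-interaction enrichment
#'
#' Applies [within_pathway_counts()] and [normalized_proportion()] to every
#' pathway, sorts by the normalized proportion (descending; ties broken by
#' pathway size descending, then by identifier) and keeps pathways at or above
#' the display cutoff.
#'
#' @inheritParams within_pathway_counts
#' @param pathways Long gene-set tibble of pathway memberships.
#' @param min_proportion Display filter; default 0.01 (the ">= 1%" rule).
#' @return A tibble with columns `pathway`, `n_genes`, `n_neg_within`,
#'   `n_neg_within_complex`, `n_neg_excl_complex`, `normalized_proportion`.
#' @export
rank_pathways <- function(negatives, pathways, complexes = NULL,
                          min_proportion = 0.01) {
  negatives <- canonicalize_pairs(validate_interactions(negatives))
  cx_pairs <- if (is.null(complexes)) {
    tibble::tibble(gene_a = character(), gene_b = character())
  } else {
    co_member_pairs(complexes)
  }
  neg_cx <- dplyr::semi_join(negatives, cx_pairs, by = c("gene_a", "gene_b"))

  per_pathway <- pathways |>
    dplyr::distinct(.data$set_id, .data$gene) |>
    dplyr::group_by(pathway = .data$set_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_neg_within = sum(
        negatives$gene_a %in% .data$gene & negatives$gene_b %in% .data$gene
      ),
      n_neg_within_complex = sum(
        neg_cx$gene_a %in% .data$gene & neg_cx$gene_b %in% .data$gene
      ),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_genes >= 2) |>
    dplyr::mutate(
      n_neg_excl_complex = .data$n_neg_within - .data$n_neg_within_complex,
      normalized_proportion = normalized_proportion(
        .data$n_neg_excl_complex, .data$n_genes
      )
    )

  per_pathway |>
    dplyr::filter(.data$normalized_proportion >= min_proportion) |>
    dplyr::arrange(
      dplyr::desc(.data$normalized_proportion),
      dplyr::desc(.data$n_genes),
      .data$pathway
    )
}

#' Fraction of within-pathway negative interactions explained by complexes
#'
#' Over the union of all pathways, the fraction of within-pathway negative
#' pairs that are also co-members of a molecular complex. Each pair is counted
#' once even if it lies inside several pathways.
#'
#' @inheritParams rank_pathways
#' @return A fraction in \[0, 1\].
#' @export
complex_fraction <- function(negatives, pathways, complexes = NULL) {
  negatives <- canonicalize_pairs(validate_interactions(negatives))
  pw_pairs <- co_member_pairs(pathways)
  inside <- dplyr::semi_join(negatives, pw_pairs, by = c("gene_a", "gene_b"))
  if (nrow(inside) == 0) {
    stop("complex fraction undefined: no within-pathway negative interactions",
      call. = FALSE
    )
  }
  if (is.null(complexes) || nrow(complexes) == 0) {
    return(0)
  }
  cx_pairs <- co_member_pairs(complexes)
  n_cx <- nrow(dplyr::semi_join(inside, cx_pairs, by = c("gene_a", "gene_b")))
  n_cx / nrow(inside)
}

#' Bar plot of the enrichment ranking
#'
#' @param ranking Output of [rank_pathways()].
#' @param highlight Optional character vector of pathway ids to emphasize.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(ranking, highlight = NULL) {
  ranking <- dplyr::mutate(ranking,
    pathway = factor(.data$pathway, levels = rev(.data$pathway)),
    emphasized = .data$pathway %in% (highlight %||% character(0))
  )
  ggplot2::ggplot(ranking, ggplot2::aes(
    .data$normalized_proportion, .data$pathway,
    fill = .data$emphasized
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "#d7301f")) +
    ggplot2::labs(
      x = "normalized proportion of within-pathway negative interactions",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
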