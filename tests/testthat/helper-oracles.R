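# Independent oracles, kept free of the package's own solution paths.

# Markov-chain tree theorem for the 3-state scheme: the stationary weight of a
# state is the sum over spanning trees rooted at it of the product of edge
# rates. Enumerating the trees by hand for edges S->I (k1), S->P (k3),
# I->S (k_m1), I->P (k2), P->I (k_m2):
#   w(S) = k_m1 * k_m2
#   w(I) = k_m2 * (k1 + k3)
#   w(P) = k2 * (k1 + k3) + k3 * k_m1
# Valid for irreducible chains (all five rates > 0 suffices).
tree_stationary <- function(k1, k_m1, k2, k_m2, k3) {
  w <- c(
    S = k_m1 * k_m2,
    I = k_m2 * (k1 + k3),
    P = k2 * (k1 + k3) + k3 * k_m1
  )
  w / sum(w)
}

# Null-space stationary distribution computed outside the package: eigenvector
# of the generator for eigenvalue 0 (columns-as-source convention rebuilt here
# from scratch).
nullspace_stationary <- function(k1, k_m1, k2, k_m2, k3) {
  q <- rbind(
    c(-(k1 + k3), k_m1, 0),
    c(k1, -(k_m1 + k2), k_m2),
    c(k3, k2, -k_m2)
  )
  ns <- svd(q)$v[, 3]
  ns <- ns / sum(ns)
  stats::setNames(as.numeric(ns), c("S", "I", "P"))
}

# Random strictly positive (hence irreducible) rate sets on a log scale.
random_rate_sets <- function(n, seed) {
  set.seed(seed)
  replicate(n, 10^stats::runif(5, -1.3, 1.3), simplify = FALSE) |>
    lapply(function(v) rate_set(v[1], v[2], v[3], v[4], v[5]))
}

# Brute-force recount of the enrichment statistic on a toy: loops over every
# unordered gene pair, no joins, no dedup tricks.
brute_force_enrichment <- function(negatives, pathway_genes, complexes) {
  neg_keys <- character(0)
  for (i in seq_len(nrow(negatives))) {
    a <- negatives$gene_a[i]
    b <- negatives$gene_b[i]
    neg_keys <- union(neg_keys, paste(sort(c(a, b)), collapse = "|"))
  }
  in_complex <- function(a, b) {
    if (is.null(complexes) || nrow(complexes) == 0) {
      return(FALSE)
    }
    for (cx in unique(complexes$set_id)) {
      members <- complexes$gene[complexes$set_id == cx]
      if (a %in% members && b %in% members) {
        return(TRUE)
      }
    }
    FALSE
  }
  n_within <- 0L
  n_within_cx <- 0L
  genes <- sort(pathway_genes)
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      key <- paste(c(genes[i], genes[j]), collapse = "|")
      if (key %in% neg_keys) {
        n_within <- n_within + 1L
        if (in_complex(genes[i], genes[j])) {
          n_within_cx <- n_within_cx + 1L
        }
      }
    }
  }
  s <- length(pathway_genes)
  list(
    n_neg_within = n_within,
    n_neg_within_complex = n_within_cx,
    proportion = (n_within - n_within_cx) / (s * (s - 1) / 2)
  )
}

# Toy gene-set tibble builder.
gene_set <- function(set_id, genes) {
  tibble::tibble(set_id = set_id, description = set_id, gene = genes)
}

toy_negatives <- function(pairs) {
  tibble::tibble(
    gene_a = vapply(pairs, `[`, "", 1),
    gene_b = vapply(pairs, `[`, "", 2),
    epsilon = -0.3,
    p_value = 0.001
  )
}
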