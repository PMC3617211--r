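#' @noRd
enzyme_names <- c("F1", "R1", "F2", "R2", "EC")

# enzyme -> rate constant it catalyzes
enzyme_rate_map <- c(F1 = "k1", R1 = "k_m1", F2 = "k2", R2 = "k_m2", EC = "k3")

#' Define a single genetic perturbation
#'
#' A perturbation targets one of the five enzymes (`F1`, `R1`, `F2`, `R2`,
#' `EC`, mapped to the rates `k1`, `k_m1`, `k2`, `k_m2`, `k3`) and is either a
#' complete knockout (rate set to zero) or an overexpression (rate multiplied
#' by a factor > 1).
#'
#' @param enzyme One of `"F1"`, `"R1"`, `"F2"`, `"R2"`, `"EC"`.
#' @param mode `"KNOCKOUT"` or `"OVEREXPRESS"`.
#' @param factor Multiplicative factor, required (> 1) for `"OVEREXPRESS"`;
#'   must be absent (`NULL`) for a knockout. `NA` requests the catalogue-level
#'   default factor at evaluation time.
#' @return A one-row tibble with columns `enzyme`, `mode`, `factor`.
#' @examples
#' perturbation("F2", "KNOCKOUT")
#' perturbation("R2", "OVEREXPRESS", factor = 20)
#' @export
perturbation <- function(enzyme, mode = c("KNOCKOUT", "OVEREXPRESS"),
                         factor = NULL) {
  enzyme <- match.arg(enzyme, enzyme_names)
  mode <- match.arg(mode)
  if (mode == "KNOCKOUT") {
    if (!is.null(factor)) {
      stop("a knockout takes no factor", call. = FALSE)
    }
    factor <- NA_real_
  } else {
    if (is.null(factor)) factor <- NA_real_ # filled from the default at evaluation
    if (!is.na(factor) && (!is.numeric(factor) || factor <= 1)) {
      stop("overexpression factor must be > 1", call. = FALSE)
    }
  }
  tibble::tibble(enzyme = enzyme, mode = mode, factor = as.numeric(factor))
}

#' Apply perturbations to a rate set
#'
#' Knockouts set the mapped rate exactly to zero; overexpressions multiply it.
#' At most one perturbation per enzyme is allowed.
#'
#' @inheritParams pathway_generator
#' @param perturbations A tibble of perturbations (rows from [perturbation()],
#'   combined with `dplyr::bind_rows()`), or `NULL` for none.
#' @param default_factor Factor used for overexpressions whose `factor` is `NA`.
#' @return The perturbed `rate_set`.
#' @examples
#' nf <- rate_set(1, 0.1, 1, 0.1, 0.1)
#' apply_perturbations(nf, perturbation("F2", "KNOCKOUT"))
#' @export
apply_perturbations <- function(rates, perturbations, default_factor = 20) {
  r <- unclass(as_rate_set(rates))
  if (is.null(perturbations) || nrow(perturbations) == 0) {
    return(as_rate_set(r))
  }
  if (anyDuplicated(perturbations$enzyme)) {
    dup <- perturbations$enzyme[duplicated(perturbations$enzyme)][1]
    stop("conflicting perturbations for enzyme ", dup, call. = FALSE)
  }
  for (i in seq_len(nrow(perturbations))) {
    key <- enzyme_rate_map[[perturbations$enzyme[i]]]
    if (perturbations$mode[i] == "KNOCKOUT") {
      r[[key]] <- 0
    } else {
      f <- perturbations$factor[i]
      if (is.na(f)) f <- default_factor
      if (f <= 1) stop("overexpression factor must be > 1", call. = FALSE)
      r[[key]] <- r[[key]] * f
    }
  }
  as_rate_set(r)
}

# Shorthand used by the catalogue: "F2v" knockout, "R2^" overexpression.
parse_perturbation_code <- function(codes) {
  if (length(codes) == 0) {
    return(perturbation("F1", "KNOCKOUT")[0, ])
  }
  purrr::map_dfr(codes, function(code) {
    enzyme <- sub("[v^]$", "", code)
    mode <- if (endsWith(code, "^")) "OVEREXPRESS" else "KNOCKOUT"
    perturbation(enzyme, mode)
  })
}

#' Catalogue of knockout / overexpression scenarios
#'
#' The single- and double-mutant (and dosage) scenarios exercised by the model,
#' each with its baseline regime (`NR`, the normal-robust reference, or `NF`,
#' the normal-fragile reference; see [reference_ratesets()]) and the expected
#' qualitative fate. Scenarios flagged `sensitive` have fates that depend
#' quantitatively on the reference rates (partial rescues); they are reported
#' by [evaluate_scenarios()] but excluded from hard pass/fail.
#'
#' @return A tibble with columns `scenario`, `baseline`, `perturbations`
#'   (list-column of perturbation tibbles), `expected_fate`, `sensitive`,
#'   `note`.
#' @examples
#' scenario_catalogue()
#' @export
scenario_catalogue <- function() {
  row <- function(scenario, baseline, codes, expected, sensitive, note) {
    tibble::tibble(
      scenario = scenario, baseline = baseline,
      perturbations = list(parse_perturbation_code(codes)),
      expected_fate = expected, sensitive = sensitive, note = note
    )
  }
  dplyr::bind_rows(
    row("NR_baseline", "NR", character(0), "REPAIRED_MAIN", FALSE,
        "unperturbed robust normal state"),
    row("NF_baseline", "NF", character(0), "REPAIRED_MAIN", FALSE,
        "unperturbed fragile normal state"),
    row("irreversible", "NR", c("R1v", "R2v"), "REPAIRED_MAIN", FALSE,
        "removing both backward steps barely changes repair efficiency"),
    row("bpSL", "NR", c("F1v", "ECv"), "DD", FALSE,
        "main entry and compensatory route both lost: damage accumulates"),
    row("bpSL_downstream", "NR", c("F2v", "ECv"), "DT", FALSE,
        "downstream step and compensatory route lost: intermediate accumulates"),
    row("wrpSL", "NF", c("R1v", "F2v"), "DT", FALSE,
        "kinetic trap of the toxic intermediate (srs2 rad54 analog)"),
    row("F1_knockout", "NR", c("F1v"), "COMPENSATED", FALSE,
        "upstream block; repair proceeds through the compensatory route"),
    row("F2_knockout_NR", "NR", c("F2v"), "COMPENSATED", FALSE,
        "downstream block partially compensated when R1 outpaces R2"),
    row("F2_knockout_NF", "NF", c("F2v"), "DT", FALSE,
        "the one lethal single knockout in the fragile regime"),
    row("F2_R1_rescue", "NR", c("F2v", "R1^"), "COMPENSATED", FALSE,
        "R1 overexpression reroutes flux back through the compensatory path"),
    row("R2_dosage", "NF", c("R2^"), "DT", FALSE,
        "R2 overexpression alone traps the intermediate in the fragile regime"),
    row("R2_F1_rescue", "NF", c("R2^", "F1v"), "COMPENSATED", TRUE,
        "partial rescue of R2 dosage lethality; quantitatively rate-dependent"),
    row("F1_dosage_F2", "NF", c("F1^", "F2v"), "DT", FALSE,
        "synthetic dosage lethality: F1 overexpression amplifies the F2 defect"),
    row("EC_R2_dosage", "NF", c("ECv", "R2^"), "DT", FALSE,
        "compensatory block plus faster backward kinetics trap the intermediate"),
    row("R1_R2_dosage", "NF", c("R1v", "R2^"), "DT", FALSE,
        "removing R1 and overexpressing R2 also traps the intermediate")
  )
}

#' Evaluate a scenario catalogue against the model
#'
#' Applies each scenario's perturbations to its baseline reference rate set,
#' computes the limiting distribution, fate and time to repair, and compares
#' the fate with the expectation.
#'
#' @param catalogue A tibble as returned by [scenario_catalogue()].
#' @param overexpression_factor Factor (> 1) used for overexpressions without
#'   an explicit factor; default 20.
#' @param threshold Fate threshold passed to [classify_fate()].
#' @return A tibble with one row per scenario: realized rates (`k1 ... k3`),
#'   limiting probabilities (`S`, `I`, `P`), `time_to_repair`, `fate`,
#'   `expected_fate`, `sensitive` and `pass` (`NA` for sensitive scenarios).
#' @examples
#' evaluate_scenarios()
#' @export
evaluate_scenarios <- function(catalogue = scenario_catalogue(),
                               overexpression_factor = 20,
                               threshold = 0.5) {
  if (overexpression_factor <= 1) {
    stop("overexpression_factor must be > 1", call. = FALSE)
  }
  refs <- reference_ratesets()
  purrr::pmap_dfr(catalogue, function(scenario, baseline, perturbations,
                                      expected_fate, sensitive, note) {
    rates <- apply_perturbations(refs[[baseline]], perturbations,
      default_factor = overexpression_factor
    )
    d <- limiting_state(rates)
    fate <- classify_fate(rates, threshold)
    codes <- if (nrow(perturbations) == 0) {
      "none"
    } else {
      paste0(
        perturbations$enzyme,
        ifelse(perturbations$mode == "KNOCKOUT", "↓", "↑"),
        collapse = "+"
      )
    }
    tibble::tibble(
      scenario = scenario, baseline = baseline, perturbation = codes,
      tidy.rate_set(rates),
      S = d[["S"]], I = d[["I"]], P = d[["P"]],
      time_to_repair = time_to_repair(rates, threshold),
      fate = fate, expected_fate = expected_fate, sensitive = sensitive,
      pass = if (sensitive) NA else fate == expected_fate
    )
  })
}
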