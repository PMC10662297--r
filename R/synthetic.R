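#' Synthetic cost-per-patient table
#'
#' Emulates a hospital cost-per-patient extract for revision surgery after
#' aseptic loosening: one row per patient, one column per cost category,
#' independent gamma draws per category with the stated mean and coefficient
#' of variation. The real 30-patient sample behind the base-case means is not
#' public, so this generator is the package's stand-in; dispersion defaults
#' (cv 0.3 for surgery, 0.2 elsewhere) are synthetic choices, not observed
#' values.
#'
#' @param n number of patients (default 30, the size of the original
#'   extract).
#' @param means named vector of category means in SEK; defaults to the
#'   base-case unit costs without the IMA fee (the historical extract
#'   predates IMA use).
#' @param cv coefficient of variation, either a single value or a named
#'   vector per category (default 0.3 for Surgery, 0.2 otherwise); `cv = 0`
#'   yields the means exactly.
#' @param seed integer seed; identical seeds yield identical tables.
#' @param p_acute share of patients flagged as acute (unplanned) surgery;
#'   their Surgery draw uses `acute_multiplier` times the surgery mean.
#' @param acute_multiplier acute-surgery cost multiplier (default 1.5).
#' @return tibble with `patient_id`, one numeric column per category, and a
#'   logical `acute_surgery` flag.
#' @export
#' @examples
#' gen_cost_records(n = 5, seed = 7)
gen_cost_records <- function(n = 30,
                             means = default_cost_table()[
                               c("X-ray", "Physician visit", "CT",
                                 "Follow-up", "Surgery", "Other treatment")],
                             cv = NULL, seed = 1L, p_acute = 0,
                             acute_multiplier = 1.5) {
  stopifnot(n >= 1, all(means >= 0), p_acute >= 0, p_acute <= 1,
            acute_multiplier > 0)
  categories <- names(means)
  if (is.null(categories)) stop("means must be named", call. = FALSE)
  if (is.null(cv)) {
    cv <- stats::setNames(ifelse(categories == "Surgery", 0.3, 0.2),
                          categories)
  } else if (length(cv) == 1 && is.null(names(cv))) {
    cv <- stats::setNames(rep(cv, length(categories)), categories)
  }
  if (any(cv < 0)) stop("coefficient of variation must be >= 0",
                        call. = FALSE)
  missing_cv <- setdiff(categories, names(cv))
  if (length(missing_cv)) {
    stop("no cv for category: ", paste(missing_cv, collapse = ", "),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    acute <- stats::runif(n) < p_acute
    cols <- lapply(categories, function(cat) {
      m <- rep(unname(means[cat]), n)
      if (cat == "Surgery") m[acute] <- m[acute] * acute_multiplier
      v <- unname(cv[cat])
      if (v == 0) {
        m
      } else {
        shape <- 1 / v^2
        stats::rgamma(n, shape = shape, rate = shape / m)
      }
    })
    names(cols) <- categories
    out <- tibble::tibble(patient_id = seq_len(n))
    for (cat in categories) out[[cat]] <- cols[[cat]]
    out$acute_surgery <- acute
    out
  })
}

#' Synthetic surgeon-questionnaire probability elicitation
#'
#' Emulates per-respondent answers to "what share of patients follows each
#' branch?" questions: each respondent's probability vector at each node is
#' an independent Dirichlet draw centred on the base vector, with spread
#' controlled by a concentration parameter (higher = more agreement between
#' surgeons). Zero base probabilities are floored at 1e-6 (renormalised)
#' before setting the Dirichlet parameters.
#'
#' @param n_respondents number of respondents (the published panels had 11
#'   non-IMA and 12 IMA-experienced surgeons).
#' @param base_vectors named list: node label = named base probability
#'   vector.
#' @param concentration positive scalar Dirichlet concentration.
#' @param seed integer seed.
#' @param cohort cohort label stored with each response.
#' @return long tibble: `respondent`, `cohort`, `node`, `branch`,
#'   `probability`; each respondent-node vector sums to 1.
#' @export
#' @examples
#' gen_elicitation(3, list(initial_xray = c(loose = 0.7, not_loose = 0.15,
#'                                          uncertain = 0.15)), seed = 1)
gen_elicitation <- function(n_respondents = 11,
                            base_vectors,
                            concentration = 20, seed = 1L,
                            cohort = "non-IMA") {
  stopifnot(n_respondents >= 1, concentration > 0, is.list(base_vectors),
            length(base_vectors) >= 1, !is.null(names(base_vectors)))
  withr::with_seed(seed, {
    rows <- list()
    for (node in names(base_vectors)) {
      base <- base_vectors[[node]]
      if (abs(sum(base) - 1) > 1e-9 || any(base < 0)) {
        stop("base vector for node '", node,
             "' is not a probability vector", call. = FALSE)
      }
      base <- pmax(base, 1e-6)
      base <- base / sum(base)
      branches <- names(base) %||% as.character(seq_along(base))
      for (r in seq_len(n_respondents)) {
        p <- rdirichlet1(concentration * base)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          respondent = r, cohort = cohort, node = node, branch = branches,
          probability = p
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Summarise elicitation responses per branch
#'
#' @param responses long tibble from [gen_elicitation()].
#' @return tibble with `node`, `branch`, `min`, `mean`, `max` across
#'   respondents — the low/mean/high bounds that feed scenario analyses.
#' @export
summarize_elicitation <- function(responses) {
  stopifnot(all(c("node", "branch", "probability") %in% names(responses)))
  key <- interaction(responses$node, responses$branch, drop = TRUE,
                     sep = "\r")
  agg <- function(f) tapply(responses$probability, key, f)
  keys <- strsplit(names(agg(min)), "\r", fixed = TRUE)
  out <- tibble::tibble(
    node = vapply(keys, `[[`, character(1), 1),
    branch = vapply(keys, `[[`, character(1), 2),
    min = as.numeric(agg(min)),
    mean = as.numeric(agg(mean)),
    max = as.numeric(agg(max))
  )
  out[order(out$node, out$branch), ]
}
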