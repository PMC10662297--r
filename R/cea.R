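#' Quadrant of the cost-effectiveness plane
#'
#' Classifies an (incremental effect, incremental cost) pair: NE (more
#' effective, more costly), SE (more effective, cheaper — dominant), SW
#' (less effective, cheaper), NW (less effective, more costly — dominated).
#' A zero on either axis returns `"axis"`.
#'
#' @param delta_cost incremental cost (SEK).
#' @param delta_effect incremental effect (QALYs).
#' @return one of `"NE"`, `"SE"`, `"SW"`, `"NW"`, `"axis"`. Vectorised.
#' @export
classify_quadrant <- function(delta_cost, delta_effect) {
  stopifnot(all(is.finite(delta_cost)), all(is.finite(delta_effect)))
  out <- rep("axis", length(delta_cost))
  out[delta_cost > 0 & delta_effect > 0] <- "NE"
  out[delta_cost < 0 & delta_effect > 0] <- "SE"
  out[delta_cost < 0 & delta_effect < 0] <- "SW"
  out[delta_cost > 0 & delta_effect < 0] <- "NW"
  out
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_effect - delta_cost`. Positive NMB at a
#' willingness-to-pay `wtp` is equivalent, for a positive incremental effect,
#' to the ICER lying below `wtp`.
#'
#' @inheritParams classify_quadrant
#' @param wtp willingness to pay per QALY (SEK), positive.
#' @return NMB in SEK. Vectorised.
#' @export
net_monetary_benefit <- function(delta_cost, delta_effect, wtp) {
  stopifnot(all(wtp > 0))
  wtp * delta_effect - delta_cost
}

#' Compare two evaluated arms
#'
#' Computes incremental cost and effect (intervention minus comparator), the
#' ICER where defined, the cost-effectiveness-plane quadrant, and a
#' cost-effectiveness verdict at each willingness-to-pay threshold.
#' A strategy is judged cost-effective at threshold `lambda` iff its net
#' monetary benefit `lambda * dE - dC` is non-negative; for `dE > 0` this is
#' exactly "ICER at most lambda", for `dE < 0` it requires savings of at
#' least `lambda` per QALY forgone, and dominance (`dC <= 0`, `dE >= 0`, not
#' both zero) is always cost-effective.
#'
#' @param intervention,comparator lists with `expected_cost` and
#'   `expected_qaly` (as returned by [evaluate_arm()]) or numeric
#'   `c(cost, effect)` pairs.
#' @param thresholds willingness-to-pay values in SEK/QALY (default 500,000
#'   and 700,000).
#' @return a `cea_result`: list with `delta_cost`, `delta_effect`, `icer`
#'   (NA when `delta_effect == 0`), `dominance` (`"dominant"`, `"dominated"`
#'   or `NA`), `quadrant`, `nmb` and logical `verdicts` (both named by
#'   threshold).
#' @export
#' @examples
#' compare_arms(c(94184, 1.34), c(93279, 1.33))
compare_arms <- function(intervention, comparator,
                         thresholds = c(5e5, 7e5)) {
  as_ce <- function(x) {
    if (is.list(x)) c(x$expected_cost, x$expected_qaly) else as.numeric(x)
  }
  int <- as_ce(intervention)
  com <- as_ce(comparator)
  if (length(int) != 2 || length(com) != 2 ||
      any(!is.finite(c(int, com)))) {
    stop("arms must be finite (cost, effect) pairs", call. = FALSE)
  }
  stopifnot(all(thresholds > 0))
  dc <- int[1] - com[1]
  de <- int[2] - com[2]
  icer <- if (de != 0) dc / de else NA_real_
  dominance <- NA_character_
  if (dc <= 0 && de >= 0 && (dc < 0 || de > 0)) dominance <- "dominant"
  if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) dominance <- "dominated"
  nmb <- net_monetary_benefit(dc, de, thresholds)
  names(nmb) <- format(thresholds, scientific = FALSE, trim = TRUE)
  verdicts <- nmb >= 0
  structure(
    list(delta_cost = dc, delta_effect = de, icer = icer,
         dominance = dominance, quadrant = classify_quadrant(dc, de),
         thresholds = thresholds, nmb = nmb, verdicts = verdicts),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  incremental cost:   SEK %s\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental effect: %.4f QALY\n", x$delta_effect))
  if (!is.na(x$dominance)) {
    cat("  ", x$dominance, "\n", sep = "")
  } else if (!is.na(x$icer)) {
    cat(sprintf("  ICER: SEK %s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat("  ICER undefined (zero incremental effect)\n")
  }
  cat("  quadrant:", x$quadrant, "\n")
  for (i in seq_along(x$verdicts)) {
    cat(sprintf("  cost-effective at SEK %s/QALY: %s\n",
                names(x$verdicts)[i], x$verdicts[i]))
  }
  invisible(x)
}

#' Serialise a cea_result for JSON output
#' @param x a `cea_result`.
#' @return plain list mirroring the result, with dominance markers in place
#'   of an ICER on the axes.
#' @keywords internal
cea_result_to_list <- function(x) {
  icer_out <- if (!is.na(x$icer)) {
    x$icer
  } else if (identical(x$dominance, "dominant")) {
    "dominant"
  } else if (identical(x$dominance, "dominated")) {
    "dominated"
  } else {
    "undefined"
  }
  list(
    delta_cost_sek = x$delta_cost,
    delta_qaly = x$delta_effect,
    icer_sek_per_qaly = icer_out,
    quadrant = x$quadrant,
    verdicts = as.list(stats::setNames(as.logical(x$verdicts),
                                       names(x$verdicts)))
  )
}
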