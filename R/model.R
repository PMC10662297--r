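#' Decision-tree building blocks
#'
#' A pathway is modelled as a tree of chance nodes. Each `chance_node` has a
#' label and a list of branches; each branch carries a label, a probability,
#' and a child that is either another chance node or a [terminal_state()].
#' Branch probabilities at a node must sum to 1 (tolerance 1e-9).
#'
#' @param label node label; shared labels across arms mean "same uncertain
#'   quantity" and receive a common draw in probabilistic sensitivity
#'   analysis.
#' @param branches list of [branch()] objects.
#' @return a `chance_node` object.
#' @export
#' @examples
#' leaf <- terminal_state("not loose", c("Physician visit", "X-ray"),
#'                        "other_treatment")
#' node <- chance_node("initial_xray", list(
#'   branch("loose", 0.7, terminal_state("surgery",
#'     c("Physician visit", "X-ray", "Surgery"), "immediate_surgery")),
#'   branch("not loose", 0.3, leaf)
#' ))
chance_node <- function(label, branches) {
  stopifnot(is.character(label), length(label) == 1, is.list(branches),
            length(branches) >= 1)
  ok <- vapply(branches, inherits, logical(1), what = "tree_branch")
  if (!all(ok)) stop("branches must be built with branch()", call. = FALSE)
  structure(list(label = label, branches = branches), class = "chance_node")
}

#' @rdname chance_node
#' @param p branch probability in \[0, 1\].
#' @param child a `chance_node` or [terminal_state()].
#' @export
branch <- function(label, p, child) {
  stopifnot(is.character(label), length(label) == 1, is.numeric(p),
            length(p) == 1)
  if (!inherits(child, "chance_node") && !inherits(child, "terminal_state")) {
    stop("branch child must be a chance_node or terminal_state",
         call. = FALSE)
  }
  structure(list(label = label, p = p, child = child), class = "tree_branch")
}

#' Terminal state of a pathway
#'
#' A leaf of the decision tree: the full set of resource-use components
#' accumulated along that path (names resolved against the cost table;
#' duplicates allowed — e.g. two physician visits) and the name of the HRQoL
#' profile the patient follows over the horizon.
#'
#' @param label terminal label.
#' @param cost_components character vector of cost-component names.
#' @param hrqol_profile name of a profile in the registry.
#' @return a `terminal_state` object.
#' @export
terminal_state <- function(label, cost_components, hrqol_profile) {
  stopifnot(is.character(label), length(label) == 1,
            is.character(hrqol_profile), length(hrqol_profile) == 1)
  structure(
    list(label = label, cost_components = as.character(cost_components),
         hrqol_profile = hrqol_profile),
    class = "terminal_state"
  )
}

#' One arm of the comparison
#'
#' @param label arm label, e.g. `"X-ray/IMA"`.
#' @param root the root [chance_node()].
#' @param horizon_years model horizon in years (no discounting is applied
#'   over the 2-year default).
#' @return a `pathway_model` object.
#' @export
pathway_model <- function(label, root, horizon_years = 2) {
  stopifnot(inherits(root, "chance_node"), horizon_years > 0)
  structure(list(label = label, root = root, horizon = horizon_years),
            class = "pathway_model")
}

#' Unit costs per resource-use component, in SEK
#'
#' Defaults are the base-case Swedish university-hospital unit costs:
#' X-ray 1,029; physician visit 2,635; IMA 9,000; surgery 152,187; CT 4,353;
#' follow-up 5,318; other treatment 5,318.
#'
#' @param ... named costs overriding or extending the defaults (e.g.
#'   `` `Acute surgery` = 228280 `` for unplanned revision).
#' @return named numeric vector of class `cost_table`.
#' @export
default_cost_table <- function(...) {
  costs <- c(
    "X-ray" = 1029, "Physician visit" = 2635, "IMA" = 9000,
    "Surgery" = 152187, "CT" = 4353, "Follow-up" = 5318,
    "Other treatment" = 5318
  )
  extra <- c(...)
  if (length(extra)) costs[names(extra)] <- extra
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("costs must be finite and non-negative", call. = FALSE)
  }
  structure(costs, class = c("cost_table", "numeric"))
}

max_tree_depth <- 32L

walk_paths <- function(node, prob = 1, path = character(0), depth = 0L) {
  if (depth > max_tree_depth) {
    stop("tree deeper than ", max_tree_depth,
         " levels: cycle or runaway structure", call. = FALSE)
  }
  if (inherits(node, "terminal_state")) {
    return(list(list(probability = prob, terminal = node,
                     path = paste(c(path, node$label), collapse = " > "))))
  }
  out <- list()
  for (b in node$branches) {
    out <- c(out, walk_paths(b$child, prob * b$p, c(path, b$label),
                             depth + 1L))
  }
  out
}

#' Validate a pathway model against its cost table and profile registry
#'
#' Collects, rather than raises, violations: branch probabilities outside
#' \[0, 1\] or not summing to 1 (tolerance 1e-9), cost components missing
#' from the cost table, HRQoL profile names that do not resolve, negative
#' costs, non-positive horizon.
#'
#' @param model a [pathway_model()].
#' @param costs a [default_cost_table()]-style named vector.
#' @param profiles named list of [hrqol_trajectory()] objects.
#' @return character vector of violation messages; empty if valid.
#' @export
validate_model <- function(model, costs, profiles) {
  violations <- character(0)
  if (!inherits(model, "pathway_model")) {
    return("not a pathway_model object")
  }
  if (!is.numeric(model$horizon) || model$horizon <= 0) {
    violations <- c(violations,
                    sprintf("[%s] horizon must be positive", model$label))
  }
  if (any(costs < 0, na.rm = TRUE) || any(!is.finite(costs))) {
    violations <- c(violations, "cost table has negative or non-finite entries")
  }
  check_node <- function(node, where) {
    if (inherits(node, "terminal_state")) {
      missing_c <- setdiff(unique(node$cost_components), names(costs))
      if (length(missing_c)) {
        violations <<- c(violations, sprintf(
          "[%s] unknown cost component(s): %s", where,
          paste(missing_c, collapse = ", ")))
      }
      if (!node$hrqol_profile %in% names(profiles)) {
        violations <<- c(violations, sprintf(
          "[%s] unknown HRQoL profile: %s", where, node$hrqol_profile))
      }
      return(invisible(NULL))
    }
    p <- vapply(node$branches, `[[`, numeric(1), "p")
    if (any(p < 0 | p > 1)) {
      violations <<- c(violations, sprintf(
        "[%s] branch probability outside [0, 1]", where))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      violations <<- c(violations, sprintf(
        "[%s] branch probabilities sum to %.10g, not 1", where, sum(p)))
    }
    for (b in node$branches) {
      check_node(b$child, paste(where, b$label, sep = " > "))
    }
  }
  check_node(model$root, paste0(model$label, ": ", model$root$label))
  violations
}

#' Enumerate every root-to-terminal path of an arm
#'
#' @param model a [pathway_model()].
#' @return a tibble with one row per path: `path` (labels joined by " > "),
#'   `probability` (product of branch probabilities along the path),
#'   `terminal_label`, `profile`, and a `components` list-column. The
#'   probabilities of a valid tree sum to 1.
#' @export
enumerate_paths <- function(model) {
  stopifnot(inherits(model, "pathway_model"))
  paths <- walk_paths(model$root)
  tibble::tibble(
    path = vapply(paths, `[[`, character(1), "path"),
    probability = vapply(paths, `[[`, numeric(1), "probability"),
    terminal_label = vapply(paths, function(p) p$terminal$label, character(1)),
    profile = vapply(paths, function(p) p$terminal$hrqol_profile,
                     character(1)),
    components = lapply(paths, function(p) p$terminal$cost_components)
  )
}

#' Per-path costs and QALYs of an arm
#'
#' Extends [enumerate_paths()] with each path's total cost (sum of its
#' component unit costs, duplicates counted) and QALY (trapezoid integral of
#' its terminal's HRQoL profile).
#'
#' @inheritParams validate_model
#' @return tibble with columns `path`, `probability`, `cost`, `qaly`.
#' @export
path_table <- function(model, costs, profiles) {
  paths <- enumerate_paths(model)
  resolve_cost <- function(cmp) {
    missing_c <- setdiff(unique(cmp), names(costs))
    if (length(missing_c)) {
      stop("unknown cost component(s): ", paste(missing_c, collapse = ", "),
           call. = FALSE)
    }
    sum(costs[cmp])
  }
  resolve_qaly <- function(profile) {
    traj <- profiles[[profile]]
    if (is.null(traj)) {
      stop("unknown HRQoL profile: ", profile, call. = FALSE)
    }
    trapezoid_qaly(traj)
  }
  paths$cost <- vapply(paths$components, resolve_cost, numeric(1))
  paths$qaly <- vapply(paths$profile, resolve_qaly, numeric(1))
  paths[c("path", "probability", "cost", "qaly")]
}

#' Expected cost and QALY of one arm
#'
#' Exact path enumeration: the expectation is the probability-weighted sum of
#' each terminal path's cost and QALY.
#'
#' @inheritParams validate_model
#' @return list with `expected_cost` (SEK) and `expected_qaly` (years).
#' @export
#' @examples
#' bc <- base_case()
#' evaluate_arm(bc$arms[["X-ray/IMA"]], bc$costs, bc$profiles)
evaluate_arm <- function(model, costs, profiles) {
  pt <- path_table(model, costs, profiles)
  list(
    expected_cost = sum(pt$probability * pt$cost),
    expected_qaly = sum(pt$probability * pt$qaly)
  )
}
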