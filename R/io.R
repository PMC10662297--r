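#' Load a model-specification file
#'
#' Reads a YAML (or JSON) model file into a validated bundle. The schema:
#' top-level `arms` (list of `{label, root}` with nested
#' `{label, branches: [{label, p, node|terminal}]}` nodes and
#' `{components, profile}` terminals), `costs` (component = SEK), `profiles`
#' (name = trajectory spec, see [build_profile()]), `horizon_years` and
#' `thresholds`. Any top-level field other than `arms` may be omitted and is
#' filled from the packaged base-case fixture; the filled fields are recorded
#' in the bundle's `defaults_filled` attribute so every number in downstream
#' output is traceable to user config or the fixture.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` model file.
#' @return a `ce_bundle`: list with `arms` (named list of
#'   [pathway_model()]), `costs`, `profiles`, `thresholds`, `horizon`.
#' @export
#' @examples
#' bc <- load_model(system.file("extdata", "base_case.yaml",
#'                              package = "imacea"))
#' names(bc$arms)
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw) || !is.list(raw)) {
    stop("model file is empty or not a mapping: ", path, call. = FALSE)
  }
  if (is.null(raw$arms) || !length(raw$arms)) {
    stop("model file schema violation: missing required key 'arms'",
         call. = FALSE)
  }
  defaults_filled <- character(0)
  fixture <- NULL
  get_default <- function(key) {
    if (is.null(fixture)) {
      fixture <<- yaml::read_yaml(system.file("extdata", "base_case.yaml",
                                              package = "imacea"))
    }
    defaults_filled <<- c(defaults_filled, key)
    fixture[[key]]
  }
  costs_raw <- raw$costs %||% get_default("costs")
  profiles_raw <- raw$profiles %||% get_default("profiles")
  thresholds <- unlist(raw$thresholds %||% get_default("thresholds"))
  horizon_years <- raw$horizon_years %||% get_default("horizon_years")

  costs <- unlist(costs_raw)
  if (any(!is.finite(costs)) || any(costs < 0)) {
    stop("schema violation under 'costs': values must be non-negative ",
         "numbers", call. = FALSE)
  }
  class(costs) <- c("cost_table", "numeric")
  profiles <- lapply(profiles_raw, function(spec) {
    spec$horizon <- spec$horizon %||% (horizon_years * 12)
    build_profile(spec)
  })
  parse_node <- function(x, where) {
    if (!is.null(x$terminal)) {
      t <- x$terminal
      if (is.null(t$components) || is.null(t$profile)) {
        stop("schema violation at ", where,
             ": terminal needs 'components' and 'profile'", call. = FALSE)
      }
      return(terminal_state(x$label %||% "terminal",
                            unlist(t$components), t$profile))
    }
    spec <- x$node %||% x
    if (is.null(spec$branches)) {
      stop("schema violation at ", where,
           ": node needs 'branches' or 'terminal'", call. = FALSE)
    }
    branches <- lapply(seq_along(spec$branches), function(i) {
      b <- spec$branches[[i]]
      if (is.null(b$p) || is.null(b$label)) {
        stop("schema violation at ", where, " branch ", i,
             ": needs 'label' and 'p'", call. = FALSE)
      }
      branch(b$label, b$p, parse_node(b, paste(where, b$label, sep = " > ")))
    })
    chance_node(spec$label %||% "node", branches)
  }
  arms <- list()
  for (a in raw$arms) {
    if (is.null(a$label) || is.null(a$root)) {
      stop("schema violation under 'arms': each arm needs 'label' and ",
           "'root'", call. = FALSE)
    }
    arms[[a$label]] <- pathway_model(
      a$label, parse_node(list(node = a$root, label = a$root$label),
                          a$label),
      horizon_years
    )
  }
  bundle <- structure(
    list(arms = arms, costs = costs, profiles = profiles,
         thresholds = thresholds, horizon = horizon_years),
    class = "ce_bundle"
  )
  attr(bundle, "defaults_filled") <- unique(defaults_filled)
  violations <- unlist(lapply(arms, validate_model, costs = costs,
                              profiles = profiles))
  if (length(violations)) {
    stop("model validation failed:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  bundle
}

#' The packaged base-case bundle
#'
#' Loads the shipped two-arm base case: an X-ray/IMA pathway versus an
#' X-ray/X-ray follow-up pathway over a 2-year horizon, populated with the
#' published transition probabilities, SEK unit costs and HRQoL trajectory
#' parameters.
#'
#' @return a `ce_bundle`; see [load_model()].
#' @export
base_case <- function() {
  load_model(system.file("extdata", "base_case.yaml", package = "imacea"))
}

#' Write a bundle back to a model file
#'
#' Inverse of [load_model()]: a written-and-reloaded bundle evaluates to
#' identical expected costs and QALYs.
#'
#' @param bundle a `ce_bundle`.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(bundle, path) {
  ser_node <- function(node) {
    if (inherits(node, "terminal_state")) {
      return(list(terminal = list(components = as.list(node$cost_components),
                                  profile = node$hrqol_profile)))
    }
    list(node = list(
      label = node$label,
      branches = lapply(node$branches, function(b) {
        c(list(label = b$label, p = b$p), ser_node(b$child))
      })
    ))
  }
  ser_profile <- function(traj) {
    spec <- attr(traj, "spec")
    if (is.null(spec)) {
      spec <- list(type = "knots", times = traj$times,
                   utilities = traj$utilities)
    }
    spec
  }
  doc <- list(
    horizon_years = bundle$horizon,
    thresholds = as.list(unname(bundle$thresholds)),
    costs = as.list(stats::setNames(as.numeric(bundle$costs),
                                    names(bundle$costs))),
    profiles = lapply(bundle$profiles, ser_profile),
    arms = lapply(names(bundle$arms), function(a) {
      list(label = a, root = ser_node(bundle$arms[[a]]$root)$node)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a scenario file
#'
#' @param path YAML/JSON file with a top-level `scenarios` list, each entry
#'   `{id, overrides: {target: value}}`.
#' @return list of scenarios suitable for [one_way_scenarios()].
#' @export
load_scenarios <- function(path) {
  if (!file.exists(path)) {
    stop("scenario file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$scenarios)) {
    stop("scenario file schema violation: missing key 'scenarios'",
         call. = FALSE)
  }
  lapply(raw$scenarios, function(sc) {
    if (is.null(sc$id)) stop("scenario without an 'id'", call. = FALSE)
    list(id = sc$id,
         overrides = lapply(sc$overrides %||% list(), function(v) unlist(v)))
  })
}

#' Evaluate a bundle: per-arm expectations and the arm comparison
#'
#' @param bundle a `ce_bundle`; the first arm is taken as the intervention.
#' @return list with `arms` (tibble: `arm`, `expected_cost`,
#'   `expected_qaly`), `comparison` (a `cea_result`), and `paths` (named list
#'   of per-arm [path_table()] tibbles).
#' @export
#' @examples
#' ev <- evaluate_bundle(base_case())
#' ev$arms
#' ev$comparison
evaluate_bundle <- function(bundle) {
  stopifnot(length(bundle$arms) >= 1)
  evals <- lapply(bundle$arms, evaluate_arm, costs = bundle$costs,
                  profiles = bundle$profiles)
  arms_tbl <- tibble::tibble(
    arm = names(evals),
    expected_cost = vapply(evals, `[[`, numeric(1), "expected_cost"),
    expected_qaly = vapply(evals, `[[`, numeric(1), "expected_qaly")
  )
  comparison <- if (length(evals) >= 2) {
    compare_arms(evals[[1]], evals[[2]], bundle$thresholds)
  } else {
    NULL
  }
  paths <- lapply(bundle$arms, path_table, costs = bundle$costs,
                  profiles = bundle$profiles)
  list(arms = arms_tbl, comparison = comparison, paths = paths)
}

default_tornado_ranges <- function(bundle, output = "cost",
                                   cost_rel = c(0.8, 1.2),
                                   utility_abs = 0.05) {
  ranges <- list()
  if (output %in% c("cost", "icer")) {
    for (cmp in names(bundle$costs)) {
      base <- unname(bundle$costs[cmp])
      ranges[[paste0("cost:", cmp)]] <- list(cost_rel[1] * base,
                                             cost_rel[2] * base)
    }
  }
  if (output %in% c("qaly", "icer")) {
    for (prof in names(bundle$profiles)) {
      spec <- attr(bundle$profiles[[prof]], "spec")
      if (is.null(spec)) next
      for (par in intersect(names(spec), c("baseline", "plateau", "level"))) {
        base <- spec[[par]]
        ranges[[paste0("utility:", prof, ":", par)]] <-
          list(max(0, base - utility_abs), min(1, base + utility_abs))
      }
    }
  }
  ranges
}

#' Run the full analysis pipeline
#'
#' Evaluates the base comparison and, per the flags, the probabilistic
#' sensitivity analysis, scenario table and tornado tables, writing results
#' under `out_dir`: `results.json`, `paths.csv`, `psa_replicates.csv`,
#' `scenarios.csv`, `tornado_<output>.csv`, optional figures, and a
#' `MANIFEST.txt` recording each stage's completion. Outputs are
#' deterministic given `seed` (substreams for PSA and scenarios are derived
#' from it by fixed offsets).
#'
#' @param model path to a model file; `NULL` uses the packaged base case.
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param psa run the PSA (default `TRUE`).
#' @param n_psa PSA replicate count (default 1000).
#' @param scenarios path to a scenario file; `NULL` skips the scenario table.
#' @param tornado_outputs character subset of `c("cost", "qaly")` for which
#'   default-range tornado tables are produced; empty vector skips them.
#' @param plots write CE-plane / tornado figures (PNG) next to the tables.
#' @return invisibly, a list with `status` (0 on success), `files` written,
#'   and the in-memory `results`.
#' @export
run_pipeline <- function(model = NULL, out_dir = "imacea-results", seed = 1L,
                         psa = TRUE, n_psa = 1000, scenarios = NULL,
                         tornado_outputs = c("cost", "qaly"),
                         plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  files <- character(0)
  status <- 0L
  note <- function(stage, ok, detail = "") {
    manifest <<- c(manifest, sprintf("%s: %s%s", stage,
                                     if (ok) "ok" else "FAILED",
                                     if (nzchar(detail)) paste0(" (", detail,
                                                                ")") else ""))
    if (!ok) status <<- 1L
  }
  results <- list()
  bundle <- tryCatch(
    if (is.null(model)) base_case() else load_model(model),
    error = function(e) e
  )
  if (inherits(bundle, "error")) {
    note("load_model", FALSE, conditionMessage(bundle))
    writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
    return(invisible(list(status = status, files = files,
                          results = results)))
  }
  note("load_model", TRUE,
       paste0("defaults filled: ",
              paste(attr(bundle, "defaults_filled") %||% "none",
                    collapse = ", ")))

  ev <- evaluate_bundle(bundle)
  results$arms <- ev$arms
  results$comparison <- ev$comparison
  path_tbl <- do.call(rbind, lapply(names(ev$paths), function(a) {
    cbind(arm = a, ev$paths[[a]])
  }))
  f <- file.path(out_dir, "paths.csv")
  utils::write.csv(path_tbl, f, row.names = FALSE)
  files <- c(files, f)
  note("evaluate", TRUE)

  if (psa) {
    psa_res <- tryCatch(
      run_psa(bundle, n = n_psa, seed = derive_seed(seed, "psa")),
      error = function(e) e
    )
    if (inherits(psa_res, "error")) {
      note("psa", FALSE, conditionMessage(psa_res))
    } else {
      results$psa <- psa_res
      f <- file.path(out_dir, "psa_replicates.csv")
      utils::write.csv(psa_res$draws, f, row.names = FALSE)
      files <- c(files, f)
      if (plots) {
        fp <- file.path(out_dir, "ce_plane.png")
        ggplot2::ggsave(fp, plot_ce_plane(psa_res), width = 7, height = 5,
                        dpi = 150)
        files <- c(files, fp)
      }
      note("psa", TRUE, sprintf("n=%d, seed=%d", psa_res$n, psa_res$seed))
    }
  }

  if (!is.null(scenarios)) {
    sc_tbl <- tryCatch(
      one_way_scenarios(bundle, load_scenarios(scenarios)),
      error = function(e) e
    )
    if (inherits(sc_tbl, "error")) {
      note("scenarios", FALSE, conditionMessage(sc_tbl))
    } else {
      results$scenarios <- sc_tbl
      f <- file.path(out_dir, "scenarios.csv")
      utils::write.csv(sc_tbl, f, row.names = FALSE)
      files <- c(files, f)
      skipped <- attr(sc_tbl, "skipped")
      note("scenarios", TRUE,
           if (length(skipped)) paste("skipped:", length(skipped)) else "")
    }
  }

  for (outp in tornado_outputs) {
    tt <- tryCatch(
      tornado(bundle, default_tornado_ranges(bundle, outp), output = outp),
      error = function(e) e
    )
    stage <- paste0("tornado_", outp)
    if (inherits(tt, "error")) {
      note(stage, FALSE, conditionMessage(tt))
    } else {
      results[[stage]] <- tt
      f <- file.path(out_dir, paste0(stage, ".csv"))
      utils::write.csv(tt, f, row.names = FALSE)
      files <- c(files, f)
      if (plots) {
        fp <- file.path(out_dir, paste0(stage, ".png"))
        ggplot2::ggsave(fp, plot_tornado(tt), width = 7, height = 5,
                        dpi = 150)
        files <- c(files, fp)
      }
      note(stage, TRUE)
    }
  }

  json <- list(
    arms = stats::setNames(
      lapply(seq_len(nrow(ev$arms)), function(i) {
        list(expected_cost_sek = ev$arms$expected_cost[i],
             expected_qaly = ev$arms$expected_qaly[i])
      }),
      ev$arms$arm
    ),
    comparison = if (!is.null(ev$comparison)) {
      cea_result_to_list(ev$comparison)
    },
    psa_summary = if (!is.null(results$psa)) {
      c(results$psa$summary,
        list(n = results$psa$n, seed = results$psa$seed,
             mode = results$psa$mode))
    },
    metadata = list(
      seed = seed,
      package_version = as.character(utils::packageVersion("imacea")),
      defaults_filled_from_fixture =
        as.list(attr(bundle, "defaults_filled") %||% character(0)),
      currency = "SEK"
    )
  )
  f <- file.path(out_dir, "results.json")
  jsonlite::write_json(json, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  note("results_json", TRUE)

  writeLines(manifest, file.path(out_dir, "MANIFEST.txt"))
  invisible(list(status = status, files = files, results = results))
}

#' Cost-effectiveness plane of a PSA
#'
#' Scatter of per-replicate incremental effect (x) against incremental cost
#' (y), with a ray through the origin for each willingness-to-pay threshold.
#'
#' @param psa a `psa_result` from [run_psa()].
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  draws <- psa$draws
  rays <- do.call(rbind, lapply(psa$thresholds, function(wtp) {
    xr <- range(c(0, draws$delta_effect))
    data.frame(wtp = format(wtp, scientific = FALSE, trim = TRUE),
               x = xr, y = wtp * xr)
  }))
  ggplot2::ggplot(draws,
                  ggplot2::aes(x = .data$delta_effect,
                               y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = rays,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    linetype = .data$wtp),
                       colour = "firebrick") +
    ggplot2::labs(x = "Incremental effect (QALY)",
                  y = "Incremental cost (SEK)",
                  linetype = "WTP (SEK/QALY)",
                  title = sprintf("Cost-effectiveness plane (%d replicates)",
                                  psa$n)) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param entries a tornado table from [tornado()].
#' @return a ggplot object.
#' @export
plot_tornado <- function(entries) {
  base_out <- attr(entries, "base_output")
  df <- entries
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df,
                  ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$low_output, xend = .data$high_output,
                   yend = .data$parameter),
      linewidth = 5, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base_out, linetype = 2) +
    ggplot2::labs(x = paste("Output:", attr(entries, "output") %||% ""),
                  y = NULL, title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
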