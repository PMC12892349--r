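#' Declare forking paths
#'
#' A multiverse is declared as an ordered set of decisions, each with a
#' list of defensible options. Options may be numbers, strings, booleans,
#' or calls declared with [option_call()]; each is substituted verbatim
#' (numbers), quoted (strings), as `TRUE`/`FALSE` (booleans), or as an
#' invocation snippet (calls) wherever the template says `{{decision}}`.
#'
#' @param ... Named arguments: each name is a decision, each value a vector
#'   or list of options.
#' @return An object of class `forking_paths`.
#' @examples
#' fp <- forking_paths(negative_weights = c("abs", "zero"),
#'                     density = c(0.1, 0.2, 0.3, 0.4, 0.5))
#' @export
forking_paths <- function(...) {
  decisions <- list(...)
  if (length(decisions) == 0L) stop("declare at least one decision")
  nm <- names(decisions)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every decision must be named")
  if (anyDuplicated(nm)) stop("duplicate decision names")
  if (any(nm != make.names(nm)))
    stop("decision names must be valid identifiers: ",
         paste(nm[nm != make.names(nm)], collapse = ", "))
  decisions <- lapply(decisions, function(opts) {
    if (!is.list(opts)) opts <- as.list(opts)
    if (length(opts) == 0L) stop("every decision needs at least one option")
    opts
  })
  for (d in nm) {
    disp <- vapply(decisions[[d]], option_display, "")
    if (anyDuplicated(disp))
      stop("options of decision '", d, "' are not distinct")
  }
  structure(decisions, class = "forking_paths")
}

#' Declare a function-call option
#'
#' @param fn Function name (string).
#' @param ... Named literal arguments.
#' @return A callable option usable inside [forking_paths()].
#' @export
option_call <- function(fn, ...) {
  structure(list(fn = fn, args = list(...)), class = "option_call")
}

# plain display form (manifest, rules, result tables)
option_display <- function(opt) {
  if (inherits(opt, "option_call")) {
    args <- paste(names(opt$args),
                  vapply(opt$args, option_code, ""), sep = " = ",
                  collapse = ", ")
    paste0(opt$fn, "(", args, ")")
  } else if (is.character(opt)) opt
  else if (is.logical(opt)) as.character(opt)
  else format(opt, digits = 15)
}

# R source-code rendering substituted into templates
option_code <- function(opt) {
  if (inherits(opt, "option_call")) option_display(opt)
  else if (is.character(opt)) paste0('"', opt, '"')
  else if (is.logical(opt)) as.character(opt)
  else format(opt, digits = 15)
}

#' Expand forking paths into universe assignments
#'
#' Cartesian product of all options in row-major declaration order (first
#' decision varies slowest), minus assignments matched by any exclusion
#' rule. A rule is a named list of decision = option pairs; an assignment
#' matching *all* pairs of *any* rule is removed.
#'
#' @param fp A [forking_paths] object.
#' @param rules List of exclusion rules (named lists).
#' @return List of assignments; each is a named list of options in
#'   declaration order.
#' @export
expand_universes <- function(fp, rules = list()) {
  stopifnot(inherits(fp, "forking_paths"))
  nm <- names(fp)
  check_rules(rules, nm)
  counts <- lengths(fp)
  total <- prod(counts)
  out <- vector("list", total)
  idx <- rep(1L, length(counts))
  for (u in seq_len(total)) {
    out[[u]] <- stats::setNames(
      lapply(seq_along(nm), function(d) fp[[d]][[idx[d]]]), nm)
    # increment mixed-radix counter, last decision fastest
    for (d in rev(seq_along(counts))) {
      idx[d] <- idx[d] + 1L
      if (idx[d] <= counts[d]) break
      idx[d] <- 1L
    }
  }
  if (length(rules) > 0L)
    out <- Filter(function(a) !matches_any_rule(a, rules), out)
  out
}

check_rules <- function(rules, decision_names) {
  for (r in rules) {
    if (length(r) == 0L || is.null(names(r)) || any(!nzchar(names(r))))
      stop("each exclusion rule must be a non-empty named list")
    unknown <- setdiff(names(r), decision_names)
    if (length(unknown) > 0L)
      stop("exclusion rule names unknown decision: ",
           paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

matches_any_rule <- function(assignment, rules) {
  disp <- vapply(assignment, option_display, "")
  for (r in rules) {
    want <- vapply(r, option_display, "")
    if (all(disp[names(r)] == want)) return(TRUE)
  }
  FALSE
}

template_placeholders <- function(template) {
  m <- gregexpr("\\{\\{([^}]*)\\}\\}", template)[[1L]]
  if (m[1L] == -1L) return(character(0))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  vapply(seq_along(starts), function(i)
    substr(template, starts[i] + 2L, starts[i] + lens[i] - 3L), "")
}

validate_template <- function(template, fp) {
  ph <- unique(template_placeholders(template))
  unknown <- setdiff(ph, names(fp))
  if (length(unknown) > 0L)
    stop("template placeholder does not match any declared decision: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(names(fp), ph)
  if (length(missing) > 0L)
    stop("decision never used in the template: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Render a template for one assignment
#'
#' Replaces every `{{decision}}` placeholder by the assigned option's
#' source-code rendering. Errors if any placeholder remains unresolved.
#'
#' @param template Template text (analysis body).
#' @param assignment Named list of options (one element of
#'   [expand_universes()] output).
#' @return Script text.
#' @export
render_template <- function(template, assignment) {
  out <- template
  for (d in names(assignment)) {
    out <- gsub(paste0("{{", d, "}}"), option_code(assignment[[d]]),
                out, fixed = TRUE)
  }
  left <- template_placeholders(out)
  if (length(left) > 0L)
    stop("unresolved placeholder: ", paste(unique(left), collapse = ", "))
  out
}

#' Create a multiverse: one runnable script per universe
#'
#' Expands the forking paths, renders the template once per valid
#' assignment, and writes standalone scripts `universe_<id>.R` (1-based
#' ids in row-major declaration order), a `manifest.csv`, and a
#' machine-readable `multiverse.json` into `out_dir`. Re-running on
#' identical inputs reproduces identical files. Each script defines
#' `._mv` (its id and result path) before the rendered template body;
#' the template should end by calling [save_universe_results()].
#'
#' @param fp A [forking_paths] object.
#' @param template Template text containing `{{decision}}` placeholders;
#'   every declared decision must appear at least once.
#' @param rules List of exclusion rules (see [expand_universes()]).
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a data frame (invisibly): universe_id, one
#'   column per decision, script, status.
#' @export
multiverse_create <- function(fp, template, rules = list(), out_dir) {
  stopifnot(inherits(fp, "forking_paths"))
  validate_template(template, fp)
  assignments <- expand_universes(fp, rules)
  if (length(assignments) == 0L)
    stop("exclusion rules removed every universe")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "results"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "scripts"), showWarnings = FALSE)
  rows <- list()
  for (u in seq_along(assignments)) {
    a <- assignments[[u]]
    script_rel <- file.path("scripts", paste0("universe_", u, ".R"))
    script_path <- file.path(out_dir, script_rel)
    body <- render_template(template, a)
    header <- c(
      paste0("# universe ", u, " of ", length(assignments),
             " -- generated by multiverse_create(); do not edit"),
      paste0("._mv <- list(universe_id = ", u, "L, results_dir = ",
             option_code(normalizePath(file.path(out_dir, "results"))), ")"),
      "")
    writeLines(c(header, body), script_path)
    rows[[u]] <- c(universe_id = u,
                   vapply(a, option_display, ""),
                   script = script_rel, status = "pending")
  }
  manifest <- as.data.frame(do.call(rbind, rows),
                            stringsAsFactors = FALSE)
  manifest$universe_id <- as.integer(manifest$universe_id)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  desc <- list(
    decisions = lapply(fp, function(opts)
      lapply(opts, function(o) list(display = option_display(o),
                                    code = option_code(o)))),
    rules = lapply(rules, function(r)
      lapply(r, option_display)),
    n_universes = length(assignments),
    template = template)
  jsonlite::write_json(desc, file.path(out_dir, "multiverse.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

read_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", out_dir,
                               "; run multiverse_create() first")
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character") |>
    (\(m) { m$universe_id <- as.integer(m$universe_id); m })()
}

#' Tabular overview of a multiverse
#'
#' @param out_dir Directory written by [multiverse_create()].
#' @return Data frame: one row per universe, one column per decision,
#'   plus script and status.
#' @export
multiverse_summary <- function(out_dir) {
  read_manifest(out_dir)
}

#' Save the results of one universe
#'
#' Call this at the end of a universe script (the generated header defines
#' where the record goes). Outcomes must be named scalars; optional
#' confidence intervals are carried through to the specification curve but
#' never computed by the engine.
#'
#' @param outcomes Named list/vector of scalar outcomes.
#' @param ci Optional named list of `c(low, high)` intervals; names must
#'   be a subset of the outcome names and satisfy low <= estimate <= high.
#' @param .mv Internal override of the generated `._mv` context (used by
#'   tests).
#' @export
save_universe_results <- function(outcomes, ci = NULL, .mv = NULL) {
  mv <- .mv
  if (is.null(mv) && exists("._mv", globalenv(), inherits = FALSE))
    mv <- get("._mv", globalenv())
  if (is.null(mv))
    stop("no universe context: save_universe_results() must run inside ",
         "a generated universe script")
  outcomes <- as.list(outcomes)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    stop("outcomes must be named")
  for (nm in names(outcomes))
    if (!is.numeric(outcomes[[nm]]) || length(outcomes[[nm]]) != 1L)
      stop("outcome '", nm, "' must be a single number")
  if (!is.null(ci)) {
    for (nm in names(ci)) {
      if (!nm %in% names(outcomes))
        stop("ci for unknown outcome '", nm, "'")
      lohi <- ci[[nm]]
      est <- outcomes[[nm]]
      if (length(lohi) != 2L || lohi[1L] > est || est > lohi[2L])
        stop("ci for '", nm, "' must satisfy low <= estimate <= high")
    }
  }
  rec <- list(universe_id = mv$universe_id, outcomes = outcomes)
  if (!is.null(ci) && length(ci) > 0L)
    rec$ci <- lapply(ci, function(x) list(low = x[1L], high = x[2L]))
  jsonlite::write_json(
    rec, file.path(mv$results_dir,
                   paste0("universe_", mv$universe_id, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Run universe scripts
#'
#' Executes each universe script as an isolated `Rscript` subprocess in
#' its own working directory. A failing universe is recorded
#' (status = "failed", stderr captured) without aborting its siblings.
#' The manifest is updated in place and an aggregate `results.csv` is
#' written.
#'
#' @param out_dir Directory written by [multiverse_create()].
#' @param ids Subset of universe ids to run (default: all).
#' @param workers Number of parallel workers (forked processes).
#' @return Updated manifest data frame; attribute `n_failed` gives the
#'   number of failed universes.
#' @export
multiverse_run <- function(out_dir, ids = NULL, workers = 1) {
  manifest <- read_manifest(out_dir)
  if (is.null(ids)) ids <- manifest$universe_id
  missing_ids <- setdiff(ids, manifest$universe_id)
  if (length(missing_ids) > 0L)
    stop("unknown universe ids: ", paste(missing_ids, collapse = ", "))
  run_one <- function(id) {
    row <- manifest[manifest$universe_id == id, ]
    script <- file.path(out_dir, row$script)
    if (!file.exists(script))
      return(list(id = id, status = "failed",
                  error = paste("missing script:", row$script)))
    wd <- file.path(out_dir, "work", paste0("universe_", id))
    dir.create(wd, recursive = TRUE, showWarnings = FALSE)
    errfile <- file.path(wd, "stderr.txt")
    owd <- getwd()
    setwd(wd)
    on.exit(setwd(owd), add = TRUE)
    status <- system2(
      "Rscript", shQuote(normalizePath(script)),
      stdout = FALSE, stderr = errfile,
      env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)))
    if (identical(status, 0L)) {
      list(id = id, status = "ok", error = NA_character_)
    } else {
      msg <- tryCatch(paste(readLines(errfile), collapse = "\n"),
                      error = function(e) "unknown error")
      list(id = id, status = "failed", error = msg)
    }
  }
  outs <- if (workers > 1L) {
    parallel::mclapply(ids, run_one, mc.cores = workers)
  } else {
    lapply(ids, run_one)
  }
  for (o in outs) {
    manifest$status[manifest$universe_id == o$id] <- o$status
    if (o$status == "failed") {
      rec <- list(universe_id = o$id, outcomes = NULL, ci = NULL,
                  error = o$error)
      jsonlite::write_json(
        rec, file.path(out_dir, "results",
                       paste0("universe_", o$id, ".json")),
        auto_unbox = TRUE, pretty = TRUE)
    }
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  res <- multiverse_results(out_dir)
  utils::write.csv(res, file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  attr(manifest, "n_failed") <-
    sum(manifest$status[manifest$universe_id %in% ids] == "failed")
  manifest
}

#' Collect multiverse results
#'
#' Joins the manifest with the per-universe result records. Failed
#' universes are kept (flagged by `status`/`error`), never dropped
#' silently.
#'
#' @param out_dir Directory written by [multiverse_create()].
#' @return Data frame: universe_id, decision columns, outcome columns,
#'   CI columns (`<outcome>_ci_low/high` when present), status, error.
#' @export
multiverse_results <- function(out_dir) {
  manifest <- read_manifest(out_dir)
  files <- file.path(out_dir, "results",
                     paste0("universe_", manifest$universe_id, ".json"))
  if (!any(file.exists(files)))
    stop("no results found in ", out_dir, "; run multiverse_run() first")
  recs <- lapply(files, function(f)
    if (file.exists(f)) jsonlite::read_json(f) else NULL)
  outcome_names <- unique(unlist(lapply(recs, function(r) names(r$outcomes))))
  out <- manifest[, setdiff(names(manifest), "script"), drop = FALSE]
  for (nm in outcome_names) {
    out[[nm]] <- vapply(recs, function(r) {
      v <- r$outcomes[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, 0)
  }
  for (nm in outcome_names) {
    lows <- vapply(recs, function(r) {
      v <- r$ci[[nm]]
      if (is.null(v)) NA_real_ else as.numeric(v$low)
    }, 0)
    if (any(!is.na(lows))) {
      out[[paste0(nm, "_ci_low")]] <- lows
      out[[paste0(nm, "_ci_high")]] <- vapply(recs, function(r) {
        v <- r$ci[[nm]]
        if (is.null(v)) NA_real_ else as.numeric(v$high)
      }, 0)
    }
  }
  out$error <- vapply(recs, function(r) {
    if (is.null(r) || length(r$error) == 0L) NA_character_
    else as.character(r$error)[1L]
  }, "")
  out
}

#' Specification curve
#'
#' Orders universes by an outcome (ascending, ties broken by universe id)
#' and draws the classic two-panel figure: outcome estimates with optional
#' CI whiskers on top, and below a decision-indicator matrix with one row
#' per decision option marking each universe's choices. Also writes the
#' ordered table as CSV.
#'
#' @param results Result table from [multiverse_results()] (or a
#'   compatible data frame with `universe_id` and decision columns).
#' @param outcome Name of the outcome column to rank by.
#' @param decisions Character vector of decision column names; default:
#'   all non-outcome, non-bookkeeping columns.
#' @param out_prefix If non-NULL, files `<out_prefix>.csv`, `.png` and
#'   `.svg` are written.
#' @return The ordered table (rank, universe_id, outcome, decisions),
#'   invisibly when plotting.
#' @export
specification_curve <- function(results, outcome, decisions = NULL,
                                out_prefix = NULL) {
  if (!outcome %in% names(results))
    stop("unknown outcome: ", outcome)
  ok <- results[!is.na(results[[outcome]]), , drop = FALSE]
  if (nrow(ok) < 2L)
    stop("specification curve needs the outcome in at least 2 universes")
  if (is.null(decisions)) {
    book <- c("universe_id", "status", "error", outcome,
              paste0(outcome, c("_ci_low", "_ci_high")))
    decisions <- setdiff(names(ok), book)
    decisions <- decisions[!grepl("_ci_(low|high)$", decisions)]
  }
  ord <- order(ok[[outcome]], ok$universe_id)
  ok <- ok[ord, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  tab <- ok[, c("rank", "universe_id", outcome, decisions), drop = FALSE]
  if (!is.null(out_prefix)) {
    utils::write.csv(tab, paste0(out_prefix, ".csv"), row.names = FALSE)
    draw <- function() spec_curve_draw(ok, outcome, decisions)
    grDevices::png(paste0(out_prefix, ".png"), width = 900, height = 700)
    draw()
    grDevices::dev.off()
    grDevices::svg(paste0(out_prefix, ".svg"), width = 9, height = 7)
    draw()
    grDevices::dev.off()
    return(invisible(tab))
  }
  tab
}

spec_curve_draw <- function(ok, outcome, decisions) {
  n <- nrow(ok)
  lo_col <- paste0(outcome, "_ci_low")
  hi_col <- paste0(outcome, "_ci_high")
  has_ci <- lo_col %in% names(ok) && any(!is.na(ok[[lo_col]]))
  opts <- unlist(lapply(decisions, function(d)
    paste0(d, ": ", unique(ok[[d]]))), use.names = FALSE)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  graphics::layout(matrix(1:2), heights = c(1.2, 1))
  graphics::par(mar = c(0.5, 10, 2, 1))
  ylim <- if (has_ci)
    range(c(ok[[lo_col]], ok[[hi_col]], ok[[outcome]]), na.rm = TRUE)
  else range(ok[[outcome]])
  graphics::plot(seq_len(n), ok[[outcome]], pch = 16, xaxt = "n",
                 xlab = "", ylab = outcome, ylim = ylim,
                 main = "Specification curve")
  if (has_ci)
    graphics::segments(seq_len(n), ok[[lo_col]], seq_len(n), ok[[hi_col]],
                       col = "grey50")
  graphics::par(mar = c(4, 10, 0.5, 1))
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, length(opts) + 0.5),
                 xlab = "universe (ranked)", ylab = "", yaxt = "n", xaxt = "s")
  graphics::axis(2, at = seq_along(opts), labels = opts, las = 2,
                 cex.axis = 0.7)
  yi <- 0L
  for (d in decisions) {
    for (o in unique(ok[[d]])) {
      yi <- yi + 1L
      hit <- which(ok[[d]] == o)
      graphics::points(hit, rep(yi, length(hit)), pch = 15, cex = 0.8)
    }
  }
  invisible(NULL)
}

#' Visualize the multiverse decision tree
#'
#' Writes the layered decision graph (root, one level per decision in
#' declaration order, one leaf per valid universe) as Graphviz DOT and as
#' JSON.
#'
#' @param fp A [forking_paths] object.
#' @param rules Exclusion rules (see [expand_universes()]).
#' @param out_prefix Files `<out_prefix>.dot` and `.json` are written.
#' @return List with `n_leaves` (= number of valid universes) and
#'   `n_nodes`, invisibly.
#' @export
multiverse_visualize <- function(fp, rules = list(), out_prefix) {
  stopifnot(inherits(fp, "forking_paths"))
  assignments <- expand_universes(fp, rules)
  nm <- names(fp)
  # prefix tree over valid assignments
  nodes <- list(list(id = 0L, label = "data", level = 0L))
  edges <- list()
  key2id <- new.env(parent = emptyenv())
  assign("root", 0L, envir = key2id)
  next_id <- 1L
  for (a in assignments) {
    parent_key <- "root"
    for (d in seq_along(nm)) {
      disp <- option_display(a[[d]])
      key <- paste(parent_key, disp, sep = "|")
      if (!exists(key, key2id, inherits = FALSE)) {
        assign(key, next_id, envir = key2id)
        nodes[[length(nodes) + 1L]] <-
          list(id = next_id, label = paste0(nm[d], " = ", disp), level = d)
        edges[[length(edges) + 1L]] <-
          c(get(parent_key, key2id), next_id)
        next_id <- next_id + 1L
      }
      parent_key <- key
    }
  }
  dot <- c("digraph multiverse {", "  rankdir=TB;",
           vapply(nodes, function(n)
             sprintf("  n%d [label=\"%s\"];", n$id, n$label), ""),
           vapply(edges, function(e)
             sprintf("  n%d -> n%d;", e[1L], e[2L]), ""),
           "}")
  writeLines(dot, paste0(out_prefix, ".dot"))
  jsonlite::write_json(
    list(nodes = nodes,
         edges = lapply(edges, function(e) list(from = e[1L], to = e[2L])),
         n_leaves = length(assignments)),
    paste0(out_prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(n_leaves = length(assignments),
                 n_nodes = length(nodes)))
}
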