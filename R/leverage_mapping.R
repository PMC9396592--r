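#' Meadows's twelve places to intervene in a system
#'
#' The leverage-point hierarchy ranks intervention targets from 12
#' (parameters: constants, subsidies, taxes, standards) down to 1
#' (transcending paradigms), with lower numbers carrying greater capacity
#' to change system behavior.
#'
#' @return Data frame with columns \code{level} (12..1) and \code{name}.
#' @export
leverage_levels <- function() {
  data.frame(
    level = 12:1,
    name = c(
      "Parameters (constants, subsidies, taxes, standards)",
      "Buffers (sizes of stabilizing stocks)",
      "Material stocks and flows",
      "Delays (relative to system change rates)",
      "Balancing feedback loops",
      "Reinforcing feedback loops",
      "Information flows",
      "Rules (incentives, punishments, constraints)",
      "Self-organization",
      "Goals of the system",
      "Mindset or paradigm",
      "Transcending paradigms"),
    stringsAsFactors = FALSE)
}

#' Model feature kinds and their leverage levels
#'
#' The closed set of feature kinds an intervention can act on, in
#' one-to-one correspondence with the twelve leverage levels.
#'
#' @return Named integer vector: feature kind -> level.
#' @export
feature_kinds <- function() {
  c(parameter_on_exogenous = 12L, buffer_capacity = 11L,
    stock_flow_structure = 10L, delay = 9L, balancing_loop = 8L,
    reinforcing_loop = 7L, information_link = 6L, rule = 5L,
    self_organization = 4L, goal = 3L, paradigm = 2L, transcend = 1L)
}

#' Map a feature kind to its leverage level
#'
#' Deterministic total lookup: e.g. an intervention on a parameter feeding
#' an exogenous driver sits at level 12, one weakening a reinforcing loop
#' at level 7.
#'
#' @param kind One of the names of \code{\link{feature_kinds}}.
#' @return Integer level (1-12) with the level name as the
#'   \code{"name"} attribute.
#' @export
#' @examples
#' classify_feature("reinforcing_loop")  # 7
classify_feature <- function(kind) {
  fk <- feature_kinds()
  if (length(kind) != 1 || !(kind %in% names(fk)))
    cld_stop(paste0("unknown feature kind '", kind, "'; expected one of: ",
                    paste(names(fk), collapse = ", ")), "cld_argument_error")
  lv <- unname(fk[[kind]])
  ll <- leverage_levels()
  structure(lv, name = ll$name[ll$level == lv])
}

#' Construct an intervention candidate
#'
#' @param description Free-text description of the intervention.
#' @param feature_kind Feature kind acted on (see
#'   \code{\link{feature_kinds}}).
#' @param targets Character vector of variable ids and/or loop labels the
#'   intervention acts on.
#' @param action One of \code{"strengthen"}, \code{"weaken"}, \code{"add"},
#'   \code{"remove"}, \code{"retune"}.
#' @return An \code{intervention_candidate}; its \code{level} is derived
#'   from the feature kind and never stored independently.
#' @export
intervention_candidate <- function(description, feature_kind,
                                   targets = character(0),
                                   action = c("strengthen", "weaken", "add",
                                              "remove", "retune")) {
  action <- match.arg(action)
  level <- classify_feature(feature_kind)
  structure(list(description = description, feature_kind = feature_kind,
                 targets = targets, action = action,
                 level = as.integer(level),
                 level_name = attr(level, "name")),
            class = "intervention_candidate")
}

#' @export
print.intervention_candidate <- function(x, ...) {
  cat(sprintf("<intervention_candidate> [%d. %s] %s: %s%s\n", x$level,
              x$level_name, x$action, x$description,
              if (length(x$targets))
                paste0(" (", paste(x$targets, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Generate intervention candidates from model structure
#'
#' Produces the candidates that are mechanically derivable from the signed
#' graph: one \emph{retune} per exogenous driver (level 12, a parameter at
#' the model boundary), one \emph{strengthen} per balancing loop (level 8),
#' one \emph{weaken} per reinforcing loop (level 7), one
#' \emph{add}-information-link per proposed link (level 6), and — only for
#' links explicitly tagged \code{delay} — one \emph{retune} per such link
#' (level 9). Buffers, rules, goals and paradigms are not distinguishable
#' from graph structure and must come from a curated candidate file
#' (\code{\link{read_candidates}}).
#'
#' @param model A valid \code{cld_model}.
#' @param loops Labelled loops from \code{\link{label_loops}} (may be
#'   \code{NULL} to enumerate here).
#' @param exogenous A \code{cld_exogenous_report} (may be \code{NULL}).
#' @return List of \code{intervention_candidate}, grouped by level in
#'   descending order (12 first) and deterministic within level.
#' @export
enumerate_candidates <- function(model, loops = NULL, exogenous = NULL) {
  if (is.null(loops)) loops <- label_loops(enumerate_feedback_loops(model))
  if (is.null(exogenous)) exogenous <- find_exogenous_drivers(model)
  ids <- model$variables$id
  loop_vars <- unique(unlist(lapply(loops, `[[`, "variable_cycle")))
  if (length(setdiff(c(exogenous$exogenous, loop_vars), ids)))
    cld_stop("loops/exogenous report does not derive from this model",
             "cld_consistency_error")

  out <- list()
  for (id in exogenous$exogenous)
    out[[length(out) + 1L]] <- intervention_candidate(
      sprintf("Retune the parameter driving exogenous variable '%s'", id),
      "parameter_on_exogenous", id, "retune")

  dl <- model$links[!model$links$proposed, , drop = FALSE]
  delay_rows <- which(vapply(dl$tags, function(t)
    "delay" %in% split_multi(t), logical(1)))
  for (i in delay_rows)
    out[[length(out) + 1L]] <- intervention_candidate(
      sprintf("Retune the delay on link '%s' -> '%s'", dl$from[i], dl$to[i]),
      "delay", c(dl$from[i], dl$to[i]), "retune")

  for (lp in loops) {
    if (lp$loop_class == "balancing")
      out[[length(out) + 1L]] <- intervention_candidate(
        sprintf("Strengthen balancing loop %s", lp$label),
        "balancing_loop", lp$label, "strengthen")
  }
  for (lp in loops) {
    if (lp$loop_class == "reinforcing")
      out[[length(out) + 1L]] <- intervention_candidate(
        sprintf("Weaken reinforcing loop %s", lp$label),
        "reinforcing_loop", lp$label, "weaken")
  }
  pl <- model$links[model$links$proposed, , drop = FALSE]
  for (i in seq_len(nrow(pl)))
    out[[length(out) + 1L]] <- intervention_candidate(
      sprintf("Add information link '%s' -> '%s'", pl$from[i], pl$to[i]),
      "information_link", c(pl$from[i], pl$to[i]), "add")

  lv <- vapply(out, `[[`, integer(1), "level")
  keys <- vapply(out, function(cand)
    paste(cand$targets, collapse = "|"), character(1))
  out[order(-lv, keys)]
}

#' Read intervention candidates from a CSV file
#'
#' The file has columns \code{description}, \code{feature_kind},
#' \code{targets} ("|"-delimited variable ids / loop labels) and
#' \code{action}.
#'
#' @param path CSV path.
#' @return List of \code{intervention_candidate}.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) cld_stop(paste("no such file:", path),
                                   "cld_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("description", "feature_kind", "action"))
    if (is.null(df[[col]]))
      cld_stop(sprintf("candidate file is missing column '%s'", col),
               "cld_schema_error")
  lapply(seq_len(nrow(df)), function(i)
    intervention_candidate(df$description[i], df$feature_kind[i],
                           split_multi(df$targets[i] %||% ""),
                           df$action[i]))
}

#' Render the twelve-level leverage table
#'
#' Produces a markdown table listing all 12 levels in descending order
#' (level 12 first), printing \code{None} for levels with no candidate,
#' plus the total candidate count — the shape of a leverage-point analysis
#' summary.
#'
#' @param candidates List of \code{intervention_candidate}.
#' @return A single markdown string.
#' @export
render_leverage_table <- function(candidates) {
  ll <- leverage_levels()
  lv <- vapply(candidates, `[[`, integer(1), "level")
  lines <- c("| Meadows's place to intervene | Interventions |",
             "| --- | --- |")
  for (i in seq_len(nrow(ll))) {
    here <- candidates[lv == ll$level[i]]
    cell <- if (length(here) == 0) "None" else
      paste(vapply(here, function(cand) {
        tg <- if (length(cand$targets))
          sprintf(" (%s %s)", cand$action,
                  paste(cand$targets, collapse = ", ")) else ""
        paste0(cand$description, tg)
      }, character(1)), collapse = "; ")
    lines <- c(lines, sprintf("| %d. %s | %s |", ll$level[i], ll$name[i],
                              cell))
  }
  lines <- c(lines, "", sprintf("%d candidate intervention(s).",
                                length(candidates)))
  paste(lines, collapse = "\n")
}
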