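#' Stakeholder-filtered view of a model
#'
#' Restricts a model to the entities supported by one stakeholder source,
#' mirroring the selective display of a model by stakeholder type. A
#' variable is included when its sources contain the stakeholder; a link is
#' included only when the link itself carries the source tag \emph{and}
#' both endpoints survive — links whose endpoints are filtered out are
#' dropped and counted.
#'
#' @param model A valid \code{cld_model}.
#' @param source One of \code{\link{stakeholder_sources}()}.
#' @return A \code{cld_view}: list with \code{source}, \code{model} (the
#'   restricted sub-model) and \code{dropped_links} (count).
#' @export
stakeholder_view <- function(model, source) {
  if (!(source %in% stakeholder_sources()))
    cld_stop(paste0("unknown stakeholder source '", source, "'; expected: ",
                    paste(stakeholder_sources(), collapse = ", ")),
             "cld_argument_error")
  v <- model$variables
  keep_v <- vapply(v$sources, function(s) source %in% split_multi(s),
                   logical(1))
  vv <- v[keep_v, , drop = FALSE]
  l <- model$links
  tagged <- vapply(l$sources, function(s) source %in% split_multi(s),
                   logical(1))
  surviving <- tagged & l$from %in% vv$id & l$to %in% vv$id
  dropped <- sum(tagged & !surviving)
  sub <- sort_model(new_cld_model(paste0(model$name, " [", source, "]"),
                                  vv, l[surviving, , drop = FALSE],
                                  model$metadata))
  if (n_variables(sub) == 0)
    cld_warn(paste("no entities tagged with source", source),
             "cld_empty_warning")
  structure(list(source = source, model = sub, dropped_links = dropped),
            class = "cld_view")
}

#' @export
print.cld_view <- function(x, ...) {
  cat(sprintf("<cld_view> source %s: %d variables, %d links (%d dangling dropped)\n",
              x$source, n_variables(x$model), n_links(x$model),
              x$dropped_links))
  invisible(x)
}

#' Extract a named sub-model region
#'
#' Returns the induced subgraph on the variables assigned to one named
#' region (the \code{sub_model} field): the region's variables plus every
#' link with both endpoints inside it.
#'
#' @param model A valid \code{cld_model}.
#' @param region_name A region name occurring in the variables'
#'   \code{sub_model} fields.
#' @return A \code{cld_model}.
#' @export
submodel_region <- function(model, region_name) {
  regions <- sort(unique(model$variables$sub_model[
    nzchar(model$variables$sub_model)]))
  if (!(region_name %in% regions))
    cld_stop(paste0("unknown region '", region_name, "'; known regions: ",
                    if (length(regions)) paste(regions, collapse = ", ")
                    else "(none)"), "cld_lookup_error")
  vv <- model$variables[model$variables$sub_model == region_name, ,
                        drop = FALSE]
  l <- model$links
  keep <- l$from %in% vv$id & l$to %in% vv$id
  sort_model(new_cld_model(paste0(model$name, " [", region_name, "]"),
                           vv, l[keep, , drop = FALSE], model$metadata))
}

#' Render a markdown walkthrough of a model and its analyses
#'
#' Produces a deterministic markdown document that walks a reader through
#' the model the way a step-by-step web presentation would: overview
#' counts, per-region narratives with attached quotes, named feedback
#' loops with their class and member variables, the hub table, the
#' exogenous-driver list, archetype findings and the leverage table.
#' Analyses not supplied are computed from the model.
#'
#' @param model A valid \code{cld_model}.
#' @param loops Labelled loops (default: enumerate and label here).
#' @param hubs A \code{cld_hub_report} (default computed).
#' @param exogenous A \code{cld_exogenous_report} (default computed).
#' @param archetypes Output of \code{\link{detect_archetypes}} (default
#'   computed with \code{max_path_length = 2}).
#' @param leverage Markdown leverage table (default rendered from
#'   \code{\link{enumerate_candidates}}).
#' @return A single markdown string.
#' @export
render_walkthrough <- function(model, loops = NULL, hubs = NULL,
                               exogenous = NULL, archetypes = NULL,
                               leverage = NULL) {
  if (is.null(loops)) loops <- label_loops(enumerate_feedback_loops(model))
  if (is.null(hubs)) hubs <- find_hubs(model)
  if (is.null(exogenous)) exogenous <- find_exogenous_drivers(model)
  if (is.null(archetypes)) archetypes <- detect_archetypes(model)
  if (is.null(leverage))
    leverage <- render_leverage_table(
      enumerate_candidates(model, loops, exogenous))

  v <- model$variables
  out <- c(sprintf("# %s", model$name), "",
           sprintf("%d variables, %d causal links (%d proposed), %d feedback loops.",
                   n_variables(model), n_links(model),
                   sum(model$links$proposed), length(loops)), "")

  regions <- sort(unique(v$sub_model[nzchar(v$sub_model)]))
  if (length(regions)) {
    out <- c(out, "## Regions", "")
    for (r in regions) {
      members <- v[v$sub_model == r, , drop = FALSE]
      out <- c(out, sprintf("### %s", r), "",
               sprintf("Variables: %s.", paste(members$label,
                                               collapse = "; ")))
      quotes <- members$note[nzchar(members$note)]
      for (q in quotes) out <- c(out, "", paste0("> ", q))
      out <- c(out, "")
    }
  }

  out <- c(out, "## Feedback loops", "")
  if (length(loops) == 0) out <- c(out, "No feedback loops.", "")
  for (lp in loops) {
    out <- c(out, sprintf("- **%s** (%s): %s", lp$label, lp$loop_class,
                          paste(lp$variable_cycle, collapse = " -> ")))
  }
  out <- c(out, "", "## Hubs", "",
           sprintf("Upper decile of link density: %d or more causal links.",
                   hubs$threshold), "",
           "| Variable | Link density |", "| --- | --- |",
           sprintf("| %s | %d |", hubs$hubs$id, hubs$hubs$link_density),
           "", "## Exogenous drivers", "")
  out <- c(out, if (length(exogenous$exogenous))
    sprintf("- %s", exogenous$exogenous) else "None.")

  out <- c(out, "", "## Archetypes", "")
  for (nm in names(archetypes)) {
    ms <- archetypes[[nm]]
    out <- c(out, sprintf("- **%s**: %d match(es)", nm, length(ms)))
    for (m in ms)
      out <- c(out, sprintf("    - %s",
                            paste(sprintf("%s=%s", names(m$role_binding),
                                          m$role_binding),
                                  collapse = ", ")))
  }
  out <- c(out, "", "## Leverage points", "", leverage, "")
  paste(out, collapse = "\n")
}
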