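#' System-archetype templates
#'
#' An archetype template is a role-labelled signed pattern: a set of role
#' identifiers (e.g. \code{goal}, \code{state}, \code{gap}), template edges
#' requiring a net polarity between two roles, and loop constraints
#' requiring that a subset of roles closes into a cycle of a given class
#' (reinforcing or balancing). Matching binds roles injectively to model
#' variables such that every template edge is realized by a
#' polarity-consistent simple path.
#'
#' @param name Template name.
#' @param roles Character vector of role identifiers.
#' @param edges Data frame with columns \code{from}, \code{to},
#'   \code{polarity} (required net polarity of the realizing path).
#' @param loop_constraints List of lists with \code{roles} (cycle, in
#'   order) and \code{class} (\code{"reinforcing"}/\code{"balancing"}).
#' @return An \code{archetype_template}.
#' @export
archetype_template <- function(name, roles, edges, loop_constraints = list()) {
  tpl <- structure(list(name = name, roles = roles,
                        edges = as.data.frame(edges,
                                              stringsAsFactors = FALSE),
                        loop_constraints = loop_constraints),
                   class = "archetype_template")
  bad <- validate_template(tpl)
  if (length(bad))
    cld_stop(paste0("invalid template '", name, "': ",
                    paste(bad, collapse = "; ")), "cld_template_error")
  tpl
}

#' @rdname archetype_template
#' @param template An \code{archetype_template}.
#' @return \code{validate_template}: character vector of violations (empty
#'   when the template is well-formed).
#' @export
validate_template <- function(template) {
  bad <- character(0)
  e <- template$edges
  if (anyDuplicated(template$roles)) bad <- c(bad, "duplicate roles")
  undeclared <- setdiff(unique(c(e$from, e$to)), template$roles)
  if (length(undeclared))
    bad <- c(bad, paste("edge references undeclared role(s):",
                        paste(undeclared, collapse = ", ")))
  if (!all(e$polarity %in% polarities()))
    bad <- c(bad, "edge polarity must be positive/negative")
  ekey <- paste(e$from, e$to)
  for (lc in template$loop_constraints) {
    if (!(lc$class %in% c("reinforcing", "balancing")))
      bad <- c(bad, "loop constraint class must be reinforcing/balancing")
    r <- lc$roles
    need <- paste(r, c(r[-1], r[1]))
    if (!all(need %in% ekey))
      bad <- c(bad, paste("loop constraint cycle not covered by edges:",
                          paste(r, collapse = " -> ")))
  }
  bad
}

#' @export
print.archetype_template <- function(x, ...) {
  cat(sprintf("<archetype_template> %s: %d roles, %d edges, %d loop constraint(s)\n",
              x$name, length(x$roles), nrow(x$edges),
              length(x$loop_constraints)))
  invisible(x)
}

#' Built-in archetype templates
#'
#' Templates for four common archetypes from the standard catalogue:
#' \describe{
#'   \item{drifting_goals}{Two balancing loops sharing a gap variable — one
#'     correcting the state through corrective action, one eroding the goal
#'     through an alternative action. Ambitious goals are quietly adjusted
#'     when an alternative way of relieving the gap exists.}
#'   \item{fixes_that_fail}{A balancing quick fix whose unintended
#'     consequence feeds the problem back, forming a reinforcing loop.}
#'   \item{shifting_the_burden}{Symptomatic and fundamental balancing
#'     solutions, with a side effect of the symptomatic one undermining the
#'     fundamental one.}
#'   \item{limits_to_success}{A reinforcing growth engine coupled to a
#'     balancing loop through a limiting factor.}
#' }
#'
#' @return Named list of \code{archetype_template}s.
#' @export
builtin_templates <- function() {
  drifting <- archetype_template(
    "drifting_goals",
    roles = c("goal", "state", "gap", "corrective_action",
              "goal_eroding_action"),
    edges = data.frame(
      from = c("goal", "state", "gap", "corrective_action", "gap",
               "goal_eroding_action"),
      to = c("gap", "gap", "corrective_action", "state",
             "goal_eroding_action", "goal"),
      polarity = c("positive", "negative", "positive", "positive",
                   "positive", "negative"),
      stringsAsFactors = FALSE),
    loop_constraints = list(
      list(roles = c("gap", "corrective_action", "state"),
           class = "balancing"),
      list(roles = c("gap", "goal_eroding_action", "goal"),
           class = "balancing")))

  fixes <- archetype_template(
    "fixes_that_fail",
    roles = c("problem_symptom", "quick_fix", "unintended_consequence"),
    edges = data.frame(
      from = c("problem_symptom", "quick_fix", "quick_fix",
               "unintended_consequence"),
      to = c("quick_fix", "problem_symptom", "unintended_consequence",
             "problem_symptom"),
      polarity = c("positive", "negative", "positive", "positive"),
      stringsAsFactors = FALSE),
    loop_constraints = list(
      list(roles = c("problem_symptom", "quick_fix"), class = "balancing"),
      list(roles = c("problem_symptom", "quick_fix",
                     "unintended_consequence"), class = "reinforcing")))

  shifting <- archetype_template(
    "shifting_the_burden",
    roles = c("problem_symptom", "symptomatic_solution",
              "fundamental_solution", "side_effect"),
    edges = data.frame(
      from = c("problem_symptom", "symptomatic_solution", "problem_symptom",
               "fundamental_solution", "symptomatic_solution",
               "side_effect"),
      to = c("symptomatic_solution", "problem_symptom",
             "fundamental_solution", "problem_symptom", "side_effect",
             "fundamental_solution"),
      polarity = c("positive", "negative", "positive", "negative",
                   "positive", "negative"),
      stringsAsFactors = FALSE),
    loop_constraints = list(
      list(roles = c("problem_symptom", "symptomatic_solution"),
           class = "balancing"),
      list(roles = c("problem_symptom", "fundamental_solution"),
           class = "balancing"),
      list(roles = c("problem_symptom", "symptomatic_solution",
                     "side_effect", "fundamental_solution"),
           class = "reinforcing")))

  limits <- archetype_template(
    "limits_to_success",
    roles = c("efforts", "performance", "limiting_factor"),
    edges = data.frame(
      from = c("efforts", "performance", "performance", "limiting_factor"),
      to = c("performance", "efforts", "limiting_factor", "performance"),
      polarity = c("positive", "positive", "positive", "negative"),
      stringsAsFactors = FALSE),
    loop_constraints = list(
      list(roles = c("efforts", "performance"), class = "reinforcing"),
      list(roles = c("performance", "limiting_factor"),
           class = "balancing")))

  list(drifting_goals = drifting, fixes_that_fail = fixes,
       shifting_the_burden = shifting, limits_to_success = limits)
}

# all simple directed paths u -> v of length <= maxlen with the required
# net polarity (product of link signs); returns list of id vectors
signed_paths <- function(g, u, v, maxlen, polarity) {
  want <- if (polarity == "negative") -1L else 1L
  res <- list()
  visit <- function(cur, path, sign) {
    nb <- g$adj[[cur]]
    sg <- g$sign[[cur]]
    for (j in seq_along(nb)) {
      w <- nb[j]
      s2 <- sign * polarity_sign(sg[j])
      if (w == v) {
        if (s2 == want) res[[length(res) + 1L]] <<- c(path, w)
      } else if (!(w %in% path) && length(path) < maxlen) {
        visit(w, c(path, w), s2)
      }
    }
  }
  if (maxlen >= 1) visit(u, u, 1L)
  res
}

#' Match an archetype template in a model
#'
#' Finds all injective bindings of template roles to model variables such
#' that each template edge is realized by a simple directed path of length
#' at most \code{max_path_length} whose net polarity (product of link
#' signs) equals the edge's requirement, and every loop constraint closes
#' into a simple cycle of the required class in the model (realizing paths
#' of a constrained cycle must not share interior variables). Proposed
#' links are excluded.
#'
#' @param model A valid \code{cld_model}.
#' @param template An \code{archetype_template}.
#' @param max_path_length Maximum path length realizing one template edge
#'   (default 1: direct links only).
#' @param include_proposed Include proposed links? Default FALSE.
#' @return List of \code{archetype_match} objects in deterministic order,
#'   one per distinct role binding.
#' @export
match_template <- function(model, template, max_path_length = 1,
                           include_proposed = FALSE) {
  if (!is.numeric(max_path_length) || max_path_length < 1)
    cld_stop("max_path_length must be >= 1", "cld_argument_error")
  g <- build_adjacency(model, include_proposed)
  n <- length(g$ids)
  roles <- template$roles
  e <- template$edges
  matches <- list()
  if (n < length(roles)) return(matches)

  binding <- integer(length(roles))
  names(binding) <- roles

  edge_paths_ok <- function(bnd, upto) {
    # every edge with both roles bound among the first `upto` roles must
    # have at least one realizing path
    for (i in seq_len(nrow(e))) {
      fi <- match(e$from[i], roles)
      ti <- match(e$to[i], roles)
      if (fi <= upto && ti <= upto) {
        p <- signed_paths(g, bnd[fi], bnd[ti], max_path_length,
                          e$polarity[i])
        if (length(p) == 0) return(FALSE)
      }
    }
    TRUE
  }

  finalize <- function(bnd) {
    # choose one realizing path per edge (shortest, then lexicographic),
    # subject to loop constraints being simple cycles in the model
    all_paths <- lapply(seq_len(nrow(e)), function(i) {
      p <- signed_paths(g, bnd[match(e$from[i], roles)],
                        bnd[match(e$to[i], roles)],
                        max_path_length, e$polarity[i])
      keys <- vapply(p, function(q) sprintf("%03d %s", length(q),
                                            paste(q, collapse = " ")),
                     character(1))
      p[order(keys)]
    })
    ekey <- paste(e$from, e$to)
    chosen <- vector("list", nrow(e))

    constraint_ok <- function() {
      for (lc in template$loop_constraints) {
        r <- lc$roles
        idx <- match(paste(r, c(r[-1], r[1])), ekey)
        if (any(vapply(chosen[idx], is.null, logical(1)))) next
        interior <- unlist(lapply(chosen[idx], function(p)
          p[-c(1, length(p))]))
        members <- c(bnd[match(r, roles)], interior)
        if (anyDuplicated(members)) return(FALSE)
        sgn <- 1L
        for (i in idx) {
          p <- chosen[[i]]
          for (k in seq_len(length(p) - 1)) {
            j <- match(p[k + 1], g$adj[[p[k]]])
            sgn <- sgn * polarity_sign(g$sign[[p[k]]][j])
          }
        }
        cls <- if (sgn > 0) "reinforcing" else "balancing"
        if (cls != lc$class) return(FALSE)
      }
      TRUE
    }

    pick <- function(i) {
      if (i > nrow(e)) return(constraint_ok())
      for (p in all_paths[[i]]) {
        chosen[i] <<- list(p)
        if (constraint_ok() && pick(i + 1L)) return(TRUE)
      }
      chosen[i] <<- list(NULL)
      FALSE
    }
    if (!pick(1L)) return(NULL)

    mp <- lapply(chosen, function(p) g$ids[p])
    names(mp) <- paste(e$from, "->", e$to)
    rb <- g$ids[bnd]
    names(rb) <- roles
    structure(list(template_name = template$name, role_binding = rb,
                   matched_paths = mp,
                   path_polarities = stats::setNames(e$polarity,
                                                     names(mp))),
              class = "archetype_match")
  }

  assign_role <- function(k) {
    if (k > length(roles)) {
      m <- finalize(binding)
      if (!is.null(m)) matches[[length(matches) + 1L]] <<- m
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v %in% binding[seq_len(k - 1)]) next
      binding[k] <<- v
      if (edge_paths_ok(binding, k)) assign_role(k + 1L)
    }
    binding[k] <<- 0L
  }
  assign_role(1L)

  keys <- vapply(matches, function(m)
    paste(m$role_binding, collapse = " | "), character(1))
  matches[order(keys)]
}

#' @export
print.archetype_match <- function(x, ...) {
  cat(sprintf("<archetype_match> %s\n", x$template_name))
  for (r in names(x$role_binding))
    cat(sprintf("  %-22s -> %s\n", r, x$role_binding[[r]]))
  invisible(x)
}

#' Detect all built-in archetypes in a model
#'
#' Runs \code{\link{match_template}} for every built-in template and
#' returns the matches keyed by template name; templates with no match map
#' to empty lists.
#'
#' @param model A valid \code{cld_model}.
#' @param max_path_length Maximum path length per template edge (default 2,
#'   since archetypes in coded models often abstract multi-link chains).
#' @param templates Named list of templates (default
#'   \code{\link{builtin_templates}()}).
#' @param include_proposed Include proposed links? Default FALSE.
#' @return Named list: template name -> list of \code{archetype_match}.
#' @export
detect_archetypes <- function(model, max_path_length = 2,
                              templates = builtin_templates(),
                              include_proposed = FALSE) {
  out <- lapply(templates, function(tpl)
    match_template(model, tpl, max_path_length, include_proposed))
  names(out) <- vapply(templates, `[[`, character(1), "name")
  out
}

#' Read archetype templates from a declarative JSON file
#'
#' Template files hold an array of objects with \code{name}, \code{roles},
#' \code{edges} (array of \code{[from, to, polarity]} triples) and optional
#' \code{loop_constraints} (array of objects with \code{roles} and
#' \code{class}), so further archetypes from the standard catalogue can be
#' added without code changes.
#'
#' @param path Path to a JSON template file.
#' @return Named list of validated \code{archetype_template}s.
#' @export
read_templates <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tpls <- lapply(doc, function(t) {
    edges <- do.call(rbind, lapply(t$edges, function(ed)
      data.frame(from = ed[[1]], to = ed[[2]],
                 polarity = parse_polarity(ed[[3]]),
                 stringsAsFactors = FALSE)))
    lcs <- lapply(t$loop_constraints %||% list(), function(lc)
      list(roles = unlist(lc$roles), class = lc$class))
    archetype_template(t$name, unlist(t$roles), edges, lcs)
  })
  names(tpls) <- vapply(tpls, `[[`, character(1), "name")
  tpls
}
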