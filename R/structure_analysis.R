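#' Classify feedback-loop polarity
#'
#' A feedback loop is reinforcing (self-amplifying, exponential behavior)
#' when it contains an even number of negative links, and balancing
#' (goal-seeking, trend toward a set point) when the number of negative
#' links is odd.
#'
#' @param link_signs Character vector of \code{"positive"}/\code{"negative"}
#'   along the cycle (any sign-token dialect accepted).
#' @return \code{"reinforcing"} or \code{"balancing"}.
#' @export
#' @examples
#' classify_loop_polarity(c("+", "-", "-"))  # reinforcing
classify_loop_polarity <- function(link_signs) {
  if (length(link_signs) == 0)
    cld_stop("sign list must be nonempty", "cld_argument_error")
  signs <- parse_polarity(link_signs)
  if (sum(signs == "negative") %% 2 == 0) "reinforcing" else "balancing"
}

# rotate a simple cycle so it starts at the lexicographically smallest id;
# this is the canonical representation under which loop identity is stable
canonical_rotation <- function(ids) {
  k <- which(ids == min(ids))[1]
  if (k == 1) ids else ids[c(k:length(ids), seq_len(k - 1))]
}

cycle_key <- function(ids) paste(canonical_rotation(ids), collapse = " -> ")

new_cld_loop <- function(variable_cycle, link_signs, label = NA_character_) {
  structure(list(variable_cycle = variable_cycle,
                 link_signs = link_signs,
                 loop_class = classify_loop_polarity(link_signs),
                 label = label),
            class = "cld_loop")
}

#' @export
print.cld_loop <- function(x, ...) {
  sgn <- ifelse(x$link_signs == "positive", "+", "-")
  arrows <- paste0(" -(", sgn, ")-> ")
  path <- paste0(x$variable_cycle,
                 c(arrows[-length(arrows)], ""), collapse = "")
  cat(sprintf("<cld_loop%s> %s: %s -(%s)-> [start]\n",
              if (is.na(x$label)) "" else paste0(" ", x$label),
              x$loop_class, path, sgn[length(sgn)]))
  invisible(x)
}

# adjacency lists over integer-indexed, lexicographically sorted ids
build_adjacency <- function(model, include_proposed = FALSE) {
  ids <- sort(model$variables$id)
  l <- model$links
  if (!include_proposed) l <- l[!l$proposed, , drop = FALSE]
  from <- match(l$from, ids)
  to <- match(l$to, ids)
  adj <- vector("list", length(ids))
  sign <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- which(from == i)
    ord <- order(to[sel])
    adj[[i]] <- to[sel][ord]
    sign[[i]] <- l$polarity[sel][ord]
  }
  list(ids = ids, adj = adj, sign = sign)
}

#' Enumerate feedback loops
#'
#' Finds every simple directed cycle of the model's non-proposed causal
#' links (optionally capped in length), classifies each as reinforcing or
#' balancing, and returns them in canonical rotation (starting at the
#' lexicographically smallest variable id) in a deterministic order: by
#' length, then by id sequence.
#'
#' Enumeration starts a depth-first search at each variable in id order,
#' visiting only variables that sort after the start, so each cycle is
#' discovered exactly once at its canonical rotation. Simple-cycle counts
#' can explode combinatorially in dense graphs, so enumeration aborts with
#' an error once \code{max_count} cycles have been found; set
#' \code{max_length} to bound the search instead.
#'
#' @param model A valid \code{cld_model}.
#' @param max_length Optional maximum cycle length (number of links).
#' @param max_count Safety cap on the number of cycles (default 100000).
#' @param include_proposed Include proposed (dotted) links? Default FALSE.
#' @return List of \code{cld_loop} objects.
#' @export
enumerate_feedback_loops <- function(model, max_length = NULL,
                                     max_count = 100000,
                                     include_proposed = FALSE) {
  g <- build_adjacency(model, include_proposed)
  n <- length(g$ids)
  maxlen <- if (is.null(max_length)) n else min(max_length, n)
  found <- vector("list", 256)
  n_found <- 0L

  add_cycle <- function(path_idx, path_sign) {
    n_found <<- n_found + 1L
    if (n_found > max_count)
      cld_stop(sprintf(
        paste0("more than %d simple cycles; supply max_length to bound ",
               "the enumeration"), max_count), "cld_enumeration_error")
    if (n_found > length(found)) length(found) <<- 2L * n_found
    found[[n_found]] <<- list(idx = path_idx, sign = path_sign)
  }

  # DFS rooted at s, restricted to vertices with index > s, so every cycle
  # is emitted once, rooted at its smallest vertex
  for (s in seq_len(n)) {
    stack_idx <- integer(maxlen)
    stack_sign <- character(maxlen)
    on_path <- logical(n)

    dfs <- function(v, depth) {
      nb <- g$adj[[v]]
      sg <- g$sign[[v]]
      for (j in seq_along(nb)) {
        w <- nb[j]
        if (w == s && depth >= 2) {
          add_cycle(stack_idx[seq_len(depth)],
                    c(stack_sign[seq_len(depth - 1)], sg[j]))
        } else if (w > s && !on_path[w] && depth < maxlen) {
          stack_idx[depth + 1L] <<- w
          stack_sign[depth] <<- sg[j]
          on_path[w] <<- TRUE
          dfs(w, depth + 1L)
          on_path[w] <<- FALSE
        }
      }
    }
    stack_idx[1L] <- s
    on_path[s] <- TRUE
    dfs(s, 1L)
    on_path[s] <- FALSE
  }

  if (n_found == 0L) return(list())
  found <- found[seq_len(n_found)]
  loops <- lapply(found, function(f)
    new_cld_loop(g$ids[f$idx], f$sign))
  keys <- vapply(loops, function(lp)
    paste(lp$variable_cycle, collapse = " -> "), character(1))
  lens <- vapply(loops, function(lp) length(lp$variable_cycle), integer(1))
  loops[order(lens, keys)]
}

#' Per-variable degree summary
#'
#' Link density is the total number of causal links incident on a variable
#' (in-degree plus out-degree), counted over non-proposed links by default.
#'
#' @param model A valid \code{cld_model}.
#' @param include_proposed Count proposed links too? Default FALSE.
#' @return Data frame with \code{id}, \code{in_degree}, \code{out_degree},
#'   \code{link_density}, sorted by id.
#' @export
degree_summary <- function(model, include_proposed = FALSE) {
  ids <- sort(model$variables$id)
  l <- model$links
  if (!include_proposed) l <- l[!l$proposed, , drop = FALSE]
  indeg <- as.integer(table(factor(l$to, levels = ids)))
  outdeg <- as.integer(table(factor(l$from, levels = ids)))
  data.frame(id = ids, in_degree = indeg, out_degree = outdeg,
             link_density = indeg + outdeg, stringsAsFactors = FALSE)
}

#' Find exogenous drivers, sinks and orphans
#'
#' Exogenous drivers are variables connected to outgoing but not incoming
#' causal links — places where the modeling team has set the model
#' boundary. Sinks have only incoming links; orphans have none and are
#' reported separately (the exogenous definition requires an outgoing
#' link). All remaining variables are interior.
#'
#' @param model A valid \code{cld_model}.
#' @param include_proposed Count proposed links? Default FALSE.
#' @return A \code{cld_exogenous_report}: list with sorted id vectors
#'   \code{exogenous}, \code{sinks}, \code{orphans}, \code{interior}.
#' @export
find_exogenous_drivers <- function(model, include_proposed = FALSE) {
  d <- degree_summary(model, include_proposed)
  structure(list(
    exogenous = d$id[d$out_degree > 0 & d$in_degree == 0],
    sinks = d$id[d$in_degree > 0 & d$out_degree == 0],
    orphans = d$id[d$link_density == 0],
    interior = d$id[d$in_degree > 0 & d$out_degree > 0]),
    class = "cld_exogenous_report")
}

#' @export
print.cld_exogenous_report <- function(x, ...) {
  cat(sprintf(
    "<cld_exogenous_report> %d exogenous, %d sinks, %d orphans, %d interior\n",
    length(x$exogenous), length(x$sinks), length(x$orphans),
    length(x$interior)))
  invisible(x)
}

#' Find hubs by the upper-decile link-density rule
#'
#' A hub is a variable in the upper decile of link density. With \code{n}
#' variables and decile \code{q} (default 0.9), the qualifying threshold is
#' the \code{k}-th largest link density where
#' \code{k = ceiling((1 - q) * n)}; every variable whose density reaches
#' the threshold is a hub, so ties at the threshold extend the hub set
#' beyond \code{k}.
#'
#' @param model A valid \code{cld_model} with at least one variable.
#' @param decile Upper quantile defining hubs, in (0, 1). Default 0.9.
#' @param include_proposed Count proposed links? Default FALSE.
#' @return A \code{cld_hub_report}: list with \code{decile},
#'   \code{threshold}, \code{hubs} (data frame \code{id},
#'   \code{link_density}, sorted by decreasing density then id) and
#'   \code{degenerate} (TRUE when every variable ties, e.g. all densities
#'   equal).
#' @export
find_hubs <- function(model, decile = 0.9, include_proposed = FALSE) {
  if (!is.numeric(decile) || length(decile) != 1 ||
      decile <= 0 || decile >= 1)
    cld_stop("decile must be a single number in (0, 1)", "cld_argument_error")
  d <- degree_summary(model, include_proposed)
  n <- nrow(d)
  if (n == 0)
    cld_stop("model has no variables", "cld_argument_error")
  k <- ceiling((1 - decile) * n)
  dens <- sort(d$link_density, decreasing = TRUE)
  threshold <- dens[k]
  hubs <- d[d$link_density >= threshold, , drop = FALSE]
  hubs <- hubs[order(-hubs$link_density, hubs$id), c("id", "link_density")]
  rownames(hubs) <- NULL
  degenerate <- nrow(hubs) == n
  if (degenerate)
    cld_warn("every variable qualifies as a hub (degenerate density ties)",
             "cld_degenerate_warning")
  structure(list(decile = decile, threshold = threshold, hubs = hubs,
                 degenerate = degenerate),
            class = "cld_hub_report")
}

#' @export
print.cld_hub_report <- function(x, ...) {
  cat(sprintf(
    "<cld_hub_report> upper %.0f%% of link density: threshold %d, %d hub(s)\n",
    100 * (1 - x$decile), x$threshold, nrow(x$hubs)))
  invisible(x)
}

#' Attach registry names to enumerated loops
#'
#' Matches a registry of named cycles (e.g. \code{R1}, \code{B9}) against
#' enumerated loops by canonical rotation; loops without a registry name
#' receive systematic names \code{loop_0001}, \code{loop_0002}, ... in
#' enumeration order. Registry entries that match no enumerated loop raise
#' an unmatched-label warning and are skipped.
#'
#' @param loops List of \code{cld_loop} from
#'   \code{\link{enumerate_feedback_loops}}.
#' @param registry Named list; each element a character vector of variable
#'   ids forming a cycle (any rotation).
#' @return The loop list with \code{label} fields filled in.
#' @export
label_loops <- function(loops, registry = list()) {
  keys <- vapply(loops, function(lp) cycle_key(lp$variable_cycle),
                 character(1))
  reg_keys <- vapply(registry, function(v) cycle_key(norm_id(v)),
                     character(1))
  if (anyDuplicated(names(registry)))
    cld_stop("registry labels must be unique", "cld_argument_error")
  unmatched <- names(registry)[!(reg_keys %in% keys)]
  if (length(unmatched))
    cld_warn(paste("registry label(s) matching no enumerated loop:",
                   paste(unmatched, collapse = ", ")),
             "cld_unmatched_label_warning")
  counter <- 0L
  for (i in seq_along(loops)) {
    hit <- which(reg_keys == keys[i])
    if (length(hit)) {
      loops[[i]]$label <- names(registry)[hit[1]]
    } else {
      counter <- counter + 1L
      loops[[i]]$label <- sprintf("loop_%04d", counter)
    }
  }
  loops
}
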