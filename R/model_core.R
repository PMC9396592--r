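#' Causal-loop diagram models
#'
#' A \code{cld_model} is a provenance-tagged signed digraph: a set of
#' variables (nodes) and directed causal links (edges), each link carrying a
#' polarity, optional tags, the stakeholder sources supporting it, and a
#' \code{proposed} flag for potential ("dotted") links that are stored but
#' excluded from structural analysis by default.
#'
#' Variables are keyed by a normalized id derived from the display label
#' (see \code{\link{norm_id}}); self-loops are rejected and at most one link
#' may exist per ordered (source, target) pair. Links in both directions
#' between the same pair of variables, with possibly different signs, are
#' permitted and never merged.
#'
#' @name cld_model
NULL

variable_columns <- c("id", "label", "tags", "sources", "sub_model", "note")
link_columns <- c("from", "to", "polarity", "tags", "sources", "proposed", "note")

empty_variables <- function() {
  data.frame(id = character(0), label = character(0), tags = character(0),
             sources = character(0), sub_model = character(0),
             note = character(0), stringsAsFactors = FALSE)
}

empty_links <- function() {
  data.frame(from = character(0), to = character(0), polarity = character(0),
             tags = character(0), sources = character(0),
             proposed = logical(0), note = character(0),
             stringsAsFactors = FALSE)
}

new_cld_model <- function(name = "model", variables = empty_variables(),
                          links = empty_links(), metadata = list()) {
  rownames(variables) <- NULL
  rownames(links) <- NULL
  structure(list(name = name, variables = variables, links = links,
                 metadata = metadata),
            class = "cld_model")
}

# canonical entity order so that identical models compare identical()
sort_model <- function(model) {
  v <- model$variables
  l <- model$links
  model$variables <- v[order(v$id), , drop = FALSE]
  model$links <- l[order(l$from, l$to), , drop = FALSE]
  rownames(model$variables) <- NULL
  rownames(model$links) <- NULL
  model
}

#' Number of variables / links in a model
#'
#' @param model A \code{cld_model}.
#' @return Integer count.
#' @export
n_variables <- function(model) nrow(model$variables)

#' @rdname n_variables
#' @param include_proposed Count proposed (dotted) links too? Default TRUE:
#'   link counts include proposals, structural analyses exclude them.
#' @export
n_links <- function(model, include_proposed = TRUE) {
  if (include_proposed) nrow(model$links) else sum(!model$links$proposed)
}

#' @export
print.cld_model <- function(x, ...) {
  cat(sprintf("<cld_model> %s: %d variables, %d causal links (%d proposed)\n",
              x$name, n_variables(x), n_links(x), sum(x$links$proposed)))
  regs <- sort(unique(x$variables$sub_model[nzchar(x$variables$sub_model)]))
  if (length(regs)) cat("  regions:", paste(regs, collapse = ", "), "\n")
  invisible(x)
}

normalize_variable_rows <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) return(empty_variables())
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (is.null(rows$label)) cld_stop("variable rows need a 'label' column",
                                    "cld_schema_error")
  data.frame(
    id = norm_id(rows$label),
    label = trimws(as.character(rows$label)),
    tags = canon_multi(rows$tags %||% rep("", nrow(rows))),
    sources = canon_multi(rows$sources %||% rep("", nrow(rows))),
    sub_model = {
      s <- as.character(rows$sub_model %||% rep("", nrow(rows)))
      ifelse(is.na(s), "", trimws(s))
    },
    note = {
      s <- as.character(rows$note %||% rep("", nrow(rows)))
      ifelse(is.na(s), "", s)
    },
    stringsAsFactors = FALSE)
}

normalize_link_rows <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0) return(empty_links())
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (col in c("from", "to", "polarity")) {
    if (is.null(rows[[col]]))
      cld_stop(sprintf("link rows need a '%s' column", col), "cld_schema_error")
  }
  prop <- rows$proposed %||% rep(FALSE, nrow(rows))
  if (is.character(prop)) prop <- tolower(trimws(prop)) %in% c("true", "yes", "1")
  prop[is.na(prop)] <- FALSE
  data.frame(
    from = norm_id(rows$from),
    to = norm_id(rows$to),
    polarity = parse_polarity(rows$polarity),
    tags = canon_multi(rows$tags %||% rep("", nrow(rows))),
    sources = canon_multi(rows$sources %||% rep("", nrow(rows))),
    proposed = as.logical(prop),
    note = {
      s <- as.character(rows$note %||% rep("", nrow(rows)))
      ifelse(is.na(s), "", s)
    },
    stringsAsFactors = FALSE)
}

#' Assemble a model from coded variable and link tables
#'
#' Builds a valid \code{cld_model} from the tables produced by coding causal
#' structure out of interview data: a variables table (columns \code{label},
#' optionally \code{tags}, \code{sources}, \code{sub_model}, \code{note})
#' and a links table (columns \code{from}, \code{to}, \code{polarity},
#' optionally \code{tags}, \code{sources}, \code{proposed}, \code{note}).
#' Variables named only in link rows are auto-created and inherit the
#' sources of the links naming them. Assembly has set semantics: the row
#' order of the input never affects the result.
#'
#' Duplicate links for the same ordered pair are merged (tags and sources
#' unioned) when their polarities agree and raise a conflict error when they
#' disagree; self-loops are rejected.
#'
#' @param variable_rows Data frame of variable records (may be \code{NULL}).
#' @param link_rows Data frame of link records (may be \code{NULL}).
#' @param name Model name.
#' @param metadata Optional named list of free-form annotations.
#' @return A valid \code{cld_model}.
#' @export
#' @examples
#' m <- assemble_model(
#'   data.frame(label = c("A", "B")),
#'   data.frame(from = "A", to = "B", polarity = "+"))
#' n_links(m)
assemble_model <- function(variable_rows = NULL, link_rows = NULL,
                           name = "model", metadata = list()) {
  vars <- normalize_variable_rows(variable_rows)
  links <- normalize_link_rows(link_rows)

  if (any(links$from == links$to)) {
    bad <- unique(links$from[links$from == links$to])
    cld_stop(sprintf("self-loops are not allowed (on: %s)",
                     paste(bad, collapse = ", ")), "cld_selfloop_error")
  }

  # merge duplicate variable rows for one id (labels may differ in case)
  if (anyDuplicated(vars$id)) {
    pieces <- split(vars, vars$id)
    vars <- do.call(rbind, lapply(pieces, function(p) {
      data.frame(id = p$id[1], label = p$label[1],
                 tags = Reduce(union_multi, p$tags),
                 sources = Reduce(union_multi, p$sources),
                 sub_model = p$sub_model[nzchar(p$sub_model)][1] %|na|% "",
                 note = p$note[nzchar(p$note)][1] %|na|% "",
                 stringsAsFactors = FALSE)
    }))
  }

  # merge duplicate ordered link pairs; conflicting polarity is a data error
  if (nrow(links)) {
    key <- paste(links$from, links$to, sep = " -> ")
    if (anyDuplicated(key)) {
      conflicts <- vapply(split(links$polarity, key),
                          function(p) length(unique(p)) > 1, logical(1))
      if (any(conflicts)) {
        cld_stop(sprintf(
          "conflicting polarities for ordered link pair(s): %s",
          paste(names(conflicts)[conflicts], collapse = "; ")),
          "cld_conflict_error")
      }
      pieces <- split(links, key)
      links <- do.call(rbind, lapply(pieces, function(p) {
        data.frame(from = p$from[1], to = p$to[1], polarity = p$polarity[1],
                   tags = Reduce(union_multi, p$tags),
                   sources = Reduce(union_multi, p$sources),
                   proposed = all(p$proposed),
                   note = p$note[nzchar(p$note)][1] %|na|% "",
                   stringsAsFactors = FALSE)
      }))
    }
  }

  # auto-create endpoint variables named only in link rows, inheriting the
  # provenance of the links that name them
  mentioned <- unique(c(links$from, links$to))
  missing_ids <- setdiff(mentioned, vars$id)
  if (length(missing_ids)) {
    inherited <- vapply(missing_ids, function(id) {
      hit <- links$from == id | links$to == id
      Reduce(union_multi, links$sources[hit], accumulate = FALSE)
    }, character(1))
    vars <- rbind(vars, data.frame(
      id = missing_ids, label = missing_ids, tags = "",
      sources = inherited, sub_model = "", note = "",
      stringsAsFactors = FALSE))
  }

  model <- sort_model(new_cld_model(name, vars, links, metadata))
  stopifnot(nrow(validate_model(model)) == 0)
  model
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a[1])) b else a[1]

#' Validate a model against the type invariants
#'
#' Checks referential integrity (every link endpoint exists), id uniqueness
#' and label-derivability, non-empty labels, absence of self-loops and
#' duplicate ordered pairs, and admissible polarity and source values.
#' Violations are returned, not raised.
#'
#' @param model A \code{cld_model} (possibly constructed by hand).
#' @return Data frame with columns \code{entity}, \code{id}, \code{rule},
#'   \code{message}; zero rows iff the model is valid.
#' @export
validate_model <- function(model) {
  out <- list()
  add <- function(entity, id, rule, message) {
    out[[length(out) + 1L]] <<- data.frame(
      entity = entity, id = id, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }
  v <- model$variables
  l <- model$links

  dup <- v$id[duplicated(v$id)]
  for (id in unique(dup)) add("variable", id, "unique_id", "duplicate variable id")
  empty <- v$id[!nzchar(trimws(v$label))]
  for (id in empty) add("variable", id, "nonempty_label", "variable label is empty")
  mismatch <- v$id[nzchar(trimws(v$label)) & v$id != norm_id(v$label)]
  for (id in mismatch) add("variable", id, "id_from_label",
                           "id is not the normalized label")
  badsrc <- v$id[vapply(v$sources, function(s)
    length(setdiff(split_multi(s), stakeholder_sources())) > 0, logical(1))]
  for (id in badsrc) add("variable", id, "known_source",
                         "unknown stakeholder source tag")

  if (nrow(l)) {
    key <- paste(l$from, l$to, sep = " -> ")
    for (k in unique(key[duplicated(key)]))
      add("link", k, "unique_pair", "duplicate ordered link pair")
    for (k in key[l$from == l$to])
      add("link", k, "no_self_loop", "self-loop")
    dangling <- !(l$from %in% v$id) | !(l$to %in% v$id)
    for (k in key[dangling])
      add("link", k, "referential_integrity", "endpoint not in variable table")
    for (k in key[!(l$polarity %in% polarities())])
      add("link", k, "polarity", "polarity not positive/negative")
    badls <- vapply(l$sources, function(s)
      length(setdiff(split_multi(s), stakeholder_sources())) > 0, logical(1))
    for (k in key[badls]) add("link", k, "known_source",
                              "unknown stakeholder source tag")
    if (!is.logical(l$proposed) || anyNA(l$proposed))
      add("model", model$name, "proposed_flag", "proposed must be TRUE/FALSE")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(entity = character(0), id = character(0),
               rule = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' Merge two models
#'
#' Takes the union of variables and links, unioning tags and stakeholder
#' provenance on entities present in both inputs — the operation used when
#' causal structures coded from one stakeholder group are folded into a
#' draft model built from another. Merging a model with itself is the
#' identity.
#'
#' When the same ordered link pair carries different polarities in the two
#' inputs, \code{conflict_policy} decides: \code{"error"} (default) raises a
#' conflict error listing every conflicting pair, \code{"prefer_base"} /
#' \code{"prefer_addition"} keep one side's polarity while still unioning
#' provenance.
#'
#' @param base,addition Valid \code{cld_model}s.
#' @param conflict_policy One of \code{"error"}, \code{"prefer_base"},
#'   \code{"prefer_addition"}.
#' @return The merged \code{cld_model}.
#' @export
merge_models <- function(base, addition,
                         conflict_policy = c("error", "prefer_base",
                                             "prefer_addition")) {
  conflict_policy <- match.arg(conflict_policy)
  bl <- base$links; al <- addition$links
  bkey <- paste(bl$from, bl$to, sep = " -> ")
  akey <- paste(al$from, al$to, sep = " -> ")
  shared <- intersect(bkey, akey)
  conflict <- shared[bl$polarity[match(shared, bkey)] !=
                     al$polarity[match(shared, akey)]]
  if (length(conflict) && conflict_policy == "error") {
    cld_stop(sprintf("polarity conflict on shared link pair(s): %s",
                     paste(conflict, collapse = "; ")), "cld_conflict_error")
  }
  if (length(conflict) && conflict_policy == "prefer_addition") {
    bl$polarity[match(conflict, bkey)] <- al$polarity[match(conflict, akey)]
  }
  # under prefer_base the base polarity already stands

  vrows <- rbind(base$variables, addition$variables)
  lrows <- rbind(bl, al)
  # drop the addition's copy of conflicting pairs so assemble sees one polarity
  lk <- paste(lrows$from, lrows$to, sep = " -> ")
  drop <- which(lk %in% conflict & seq_along(lk) > nrow(bl))
  pol_fixed <- lrows
  if (length(drop)) {
    # keep provenance of the dropped rows by unioning into the kept copy
    for (i in drop) {
      j <- match(lk[i], lk)
      pol_fixed$sources[j] <- union_multi(pol_fixed$sources[j], lrows$sources[i])
      pol_fixed$tags[j] <- union_multi(pol_fixed$tags[j], lrows$tags[i])
    }
    pol_fixed <- pol_fixed[-drop, , drop = FALSE]
  }
  assemble_model(vrows, pol_fixed, name = base$name,
                 metadata = utils::modifyList(base$metadata, addition$metadata))
}

#' Diff two model revisions
#'
#' Computes an exact, invertible difference between two models, the summary
#' produced after a participatory validation round (e.g. "8 variables and 15
#' connections were added"). \code{\link{apply_diff}} replays a diff onto
#' the base model and reproduces the revision exactly.
#'
#' @param before,after Valid \code{cld_model}s.
#' @return A \code{cld_diff}: added/removed variable ids, added/removed link
#'   pairs, field-level changes, plus the payload rows needed to replay it.
#' @export
diff_models <- function(before, after) {
  bv <- before$variables; av <- after$variables
  bl <- before$links; al <- after$links
  bkey <- paste(bl$from, bl$to, sep = " -> ")
  akey <- paste(al$from, al$to, sep = " -> ")

  added_vars <- setdiff(av$id, bv$id)
  removed_vars <- setdiff(bv$id, av$id)
  added_links <- setdiff(akey, bkey)
  removed_links <- setdiff(bkey, akey)

  changed <- list()
  note_change <- function(entity, id, field, old, new) {
    changed[[length(changed) + 1L]] <<- data.frame(
      entity = entity, id = id, field = field,
      old = as.character(old), new = as.character(new),
      stringsAsFactors = FALSE)
  }
  for (id in intersect(bv$id, av$id)) {
    b <- bv[bv$id == id, ]; a <- av[av$id == id, ]
    for (f in c("label", "tags", "sources", "sub_model", "note"))
      if (!identical(b[[f]], a[[f]])) note_change("variable", id, f, b[[f]], a[[f]])
  }
  for (k in intersect(bkey, akey)) {
    b <- bl[match(k, bkey), ]; a <- al[match(k, akey), ]
    for (f in c("polarity", "tags", "sources", "proposed", "note"))
      if (!identical(b[[f]], a[[f]])) note_change("link", k, f, b[[f]], a[[f]])
  }
  changed <- if (length(changed)) do.call(rbind, changed) else
    data.frame(entity = character(0), id = character(0), field = character(0),
               old = character(0), new = character(0), stringsAsFactors = FALSE)

  structure(list(
    added_variables = sort(added_vars),
    removed_variables = sort(removed_vars),
    added_links = sort(added_links),
    removed_links = sort(removed_links),
    changed = changed,
    added_variable_rows = av[av$id %in% added_vars, , drop = FALSE],
    added_link_rows = al[akey %in% added_links, , drop = FALSE]),
    class = "cld_diff")
}

#' @export
print.cld_diff <- function(x, ...) {
  cat(sprintf(paste0("<cld_diff> +%d/-%d variables, +%d/-%d links, ",
                     "%d field change(s)\n"),
              length(x$added_variables), length(x$removed_variables),
              length(x$added_links), length(x$removed_links),
              nrow(x$changed)))
  invisible(x)
}

#' Check whether a diff is empty
#' @param diff A \code{cld_diff}.
#' @return TRUE iff the diff records no additions, removals or changes.
#' @export
is_empty_diff <- function(diff) {
  length(diff$added_variables) + length(diff$removed_variables) +
    length(diff$added_links) + length(diff$removed_links) +
    nrow(diff$changed) == 0
}

#' @rdname diff_models
#' @param base The model the diff was computed against.
#' @param diff A \code{cld_diff} from \code{diff_models}.
#' @export
apply_diff <- function(base, diff) {
  v <- base$variables
  l <- base$links
  lkey <- paste(l$from, l$to, sep = " -> ")
  l <- l[!(lkey %in% diff$removed_links), , drop = FALSE]
  v <- v[!(v$id %in% diff$removed_variables), , drop = FALSE]
  v <- rbind(v, diff$added_variable_rows)
  l <- rbind(l, diff$added_link_rows)
  ch <- diff$changed
  for (i in seq_len(nrow(ch))) {
    if (ch$entity[i] == "variable") {
      j <- match(ch$id[i], v$id)
      val <- ch$new[i]
      v[[ch$field[i]]][j] <- val
    } else {
      j <- match(ch$id[i], paste(l$from, l$to, sep = " -> "))
      val <- if (ch$field[i] == "proposed") as.logical(ch$new[i]) else ch$new[i]
      l[[ch$field[i]]][j] <- val
    }
  }
  sort_model(new_cld_model(base$name, v, l, base$metadata))
}
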