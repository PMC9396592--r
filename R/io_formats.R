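#' Parse a coded causal note
#'
#' Interview transcripts are coded by attaching notes of the form
#' \code{"<source label> (<sign>) <target label>"} to quotations, e.g.
#' \code{"VA provider turnover (-) Veteran satisfaction with VA care"}.
#' Both the ASCII hyphen and the Unicode minus are accepted as the negative
#' sign. Labels may contain parentheses as long as the content is not a lone
#' sign token.
#'
#' @param text A single coded-note string.
#' @return A \code{cld_coded_note}: list with \code{raw},
#'   \code{source_label}, \code{polarity}, \code{target_label}.
#' @export
#' @examples
#' parse_causal_note("VA provider turnover (-) Veteran satisfaction with VA care")
parse_causal_note <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text)))
    cld_stop("coded note must be a single nonempty string", "cld_parse_error")
  pat <- "\\(\\s*([+−–-])\\s*\\)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1)
    cld_stop(sprintf("no sign token '(+)' or '(-)' found in note: %s", text),
             "cld_parse_error")
  if (length(m) > 1)
    cld_stop(sprintf(
      "multiple sign tokens found in note (at positions %s): %s",
      paste(as.integer(m), collapse = ", "), text), "cld_parse_error")
  start <- as.integer(m)
  len <- attr(m, "match.length")
  src <- trimws(substr(text, 1, start - 1))
  tgt <- trimws(substr(text, start + len, nchar(text)))
  if (!nzchar(src) || !nzchar(tgt))
    cld_stop(sprintf("empty label on one side of the sign token: %s", text),
             "cld_parse_error")
  sign <- gsub("[()\\s]", "", regmatches(text, m)[[1]], perl = TRUE)
  structure(list(raw = text, source_label = src,
                 polarity = parse_polarity(sign), target_label = tgt),
            class = "cld_coded_note")
}

#' @rdname parse_causal_note
#' @param note A \code{cld_coded_note} (or compatible list).
#' @return \code{format_causal_note} returns the canonical one-line form.
#' @export
format_causal_note <- function(note) {
  sign <- if (note$polarity == "negative") "-" else "+"
  sprintf("%s (%s) %s", note$source_label, sign, note$target_label)
}

#' Turn coded notes into link rows
#'
#' @param notes Character vector of coded-note strings.
#' @param sources Optional "|"-delimited stakeholder sources applied to
#'   every resulting link.
#' @return Data frame of link rows suitable for \code{\link{assemble_model}}.
#' @export
notes_to_links <- function(notes, sources = "") {
  parsed <- lapply(notes, parse_causal_note)
  data.frame(
    from = vapply(parsed, `[[`, character(1), "source_label"),
    to = vapply(parsed, `[[`, character(1), "target_label"),
    polarity = vapply(parsed, `[[`, character(1), "polarity"),
    sources = sources, stringsAsFactors = FALSE)
}

# header matching for table dialects: case-insensitive, spaces/underscores
# ignored; "type" on a connections table is the polarity column and
# "description" is the note column (web-platform import convention)
match_column <- function(nms, wanted) {
  canon <- function(x) gsub("[ _]", "", tolower(x))
  hit <- which(canon(nms) %in% canon(wanted))
  if (length(hit)) hit[1] else NA_integer_
}

element_synonyms <- list(
  label = c("label", "element", "name", "variable"),
  tags = c("tags", "tag"),
  sources = c("sources", "source", "datasources"),
  sub_model = c("submodel", "region", "group"),
  note = c("note", "description", "quote"))

connection_synonyms <- list(
  from = c("from", "source"),
  to = c("to", "target"),
  polarity = c("polarity", "type", "sign", "valence"),
  tags = c("tags", "tag"),
  sources = c("sources", "datasources"),
  proposed = c("proposed", "dotted", "potential"),
  note = c("note", "description", "quote"))

remap_table <- function(df, synonyms, mandatory, what) {
  out <- list()
  for (col in names(synonyms)) {
    j <- match_column(names(df), synonyms[[col]])
    if (is.na(j)) {
      if (col %in% mandatory)
        cld_stop(sprintf("%s table is missing mandatory column '%s'",
                         what, col), "cld_schema_error")
    } else out[[col]] <- df[[j]]
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a model from elements and connections tables
#'
#' Reads the two-table on-disk representation (the dialect used for
#' uploading coded models to web visualization platforms): an elements CSV
#' with at least a \code{Label} column, and a connections CSV with
#' \code{From}, \code{To} and a polarity column (\code{Type},
#' \code{Polarity}, \code{Sign} or \code{Valence}). Header matching is
#' case-insensitive. Multi-valued cells (tags, sources) are
#' \code{"|"}-delimited.
#'
#' @param elements_source Path to the elements CSV (or \code{NULL} for none).
#' @param connections_source Path to the connections CSV.
#' @param name Model name (defaults to the connections file stem).
#' @return A valid \code{cld_model}.
#' @export
read_model_tables <- function(elements_source, connections_source,
                              name = NULL) {
  ev <- NULL
  if (!is.null(elements_source)) {
    if (!file.exists(elements_source))
      cld_stop(paste("no such file:", elements_source), "cld_io_error")
    edf <- utils::read.csv(elements_source, stringsAsFactors = FALSE,
                           check.names = FALSE)
    ev <- remap_table(edf, element_synonyms, "label", "elements")
  }
  if (!file.exists(connections_source))
    cld_stop(paste("no such file:", connections_source), "cld_io_error")
  cdf <- utils::read.csv(connections_source, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(cdf) == 0) {
    cld_warn("connections table is empty; model will have no links",
             "cld_empty_warning")
    cl <- NULL
  } else {
    cl <- remap_table(cdf, connection_synonyms, c("from", "to", "polarity"),
                      "connections")
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(connections_source))
  assemble_model(ev, cl, name = name)
}

#' Write a model as elements and connections tables
#'
#' Inverse of \code{\link{read_model_tables}}: writes \code{elements.csv}
#' and \code{connections.csv} under \code{dir}. Re-reading the pair yields a
#' model identical to the input at the semantic level.
#'
#' @param model A valid \code{cld_model}.
#' @param dir Destination directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_model_tables <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  epath <- file.path(dir, "elements.csv")
  cpath <- file.path(dir, "connections.csv")
  ev <- model$variables
  utils::write.csv(data.frame(
    Label = ev$label, Tags = ev$tags, Sources = ev$sources,
    `Sub model` = ev$sub_model, Note = ev$note, check.names = FALSE,
    stringsAsFactors = FALSE), epath, row.names = FALSE)
  cl <- model$links
  utils::write.csv(data.frame(
    From = cl$from, To = cl$to, Type = ifelse(cl$polarity == "positive",
                                              "same", "opposite"),
    Tags = cl$tags, Sources = cl$sources, Proposed = cl$proposed,
    Note = cl$note, check.names = FALSE, stringsAsFactors = FALSE),
    cpath, row.names = FALSE)
  invisible(c(elements = epath, connections = cpath))
}

#' Export / import a model as blueprint JSON
#'
#' The blueprint document has the two-array shape used by web CLD
#' platforms: \code{{"elements": [...], "connections": [...]}}, plus the
#' model name and metadata. A JSON-Schema describing the document ships
#' with the package (\code{system.file("extdata", "blueprint-schema.json",
#' package = "causalloop")}); \code{validate_blueprint} checks a parsed
#' document against the same constraints.
#'
#' @param model A valid \code{cld_model}.
#' @param path Optional file path; when \code{NULL} the JSON text is
#'   returned.
#' @return \code{export_blueprint_json}: JSON text (invisibly when written
#'   to a file). \code{import_blueprint_json}: a \code{cld_model}.
#' @export
export_blueprint_json <- function(model, path = NULL) {
  v <- model$variables
  l <- model$links
  doc <- list(
    name = model$name,
    metadata = if (length(model$metadata)) model$metadata else NULL,
    elements = lapply(seq_len(nrow(v)), function(i) list(
      label = v$label[i],
      tags = as.list(split_multi(v$tags[i])),
      sources = as.list(split_multi(v$sources[i])),
      subModel = if (nzchar(v$sub_model[i])) v$sub_model[i] else NULL,
      note = if (nzchar(v$note[i])) v$note[i] else NULL)),
    connections = lapply(seq_len(nrow(l)), function(i) list(
      from = l$from[i], to = l$to[i], polarity = l$polarity[i],
      tags = as.list(split_multi(l$tags[i])),
      sources = as.list(split_multi(l$sources[i])),
      proposed = l$proposed[i],
      note = if (nzchar(l$note[i])) l$note[i] else NULL)))
  doc <- drop_nulls(doc)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

#' @rdname export_blueprint_json
#' @param json JSON text or a path to a JSON file.
#' @export
import_blueprint_json <- function(json) {
  if (length(json) == 1 && !grepl("^[[:space:]]*\\{", json) &&
      file.exists(json)) json <- paste(readLines(json, warn = FALSE),
                                       collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  bad <- validate_blueprint(doc)
  if (length(bad))
    cld_stop(paste("blueprint document invalid:",
                   paste(bad, collapse = "; ")), "cld_schema_error")
  vars <- if (length(doc$elements)) data.frame(
    label = vapply(doc$elements, `[[`, character(1), "label"),
    tags = vapply(doc$elements, function(e)
      join_multi(unlist(e$tags) %||% character(0)), character(1)),
    sources = vapply(doc$elements, function(e)
      join_multi(unlist(e$sources) %||% character(0)), character(1)),
    sub_model = vapply(doc$elements, function(e)
      e$subModel %||% "", character(1)),
    note = vapply(doc$elements, function(e) e$note %||% "", character(1)),
    stringsAsFactors = FALSE) else NULL
  links <- if (length(doc$connections)) data.frame(
    from = vapply(doc$connections, `[[`, character(1), "from"),
    to = vapply(doc$connections, `[[`, character(1), "to"),
    polarity = vapply(doc$connections, `[[`, character(1), "polarity"),
    tags = vapply(doc$connections, function(e)
      join_multi(unlist(e$tags) %||% character(0)), character(1)),
    sources = vapply(doc$connections, function(e)
      join_multi(unlist(e$sources) %||% character(0)), character(1)),
    proposed = vapply(doc$connections, function(e)
      isTRUE(e$proposed), logical(1)),
    note = vapply(doc$connections, function(e) e$note %||% "", character(1)),
    stringsAsFactors = FALSE) else NULL
  assemble_model(vars, links, name = doc$name %||% "model",
                 metadata = doc$metadata %||% list())
}

#' @rdname export_blueprint_json
#' @param doc A parsed blueprint document (nested list).
#' @return \code{validate_blueprint}: character vector of violations
#'   (empty when the document conforms).
#' @export
validate_blueprint <- function(doc) {
  bad <- character(0)
  if (!is.list(doc)) return("document is not an object")
  if (!is.null(doc$elements) && !is.list(doc$elements))
    bad <- c(bad, "'elements' is not an array")
  if (!is.null(doc$connections) && !is.list(doc$connections))
    bad <- c(bad, "'connections' is not an array")
  for (i in seq_along(doc$elements)) {
    e <- doc$elements[[i]]
    if (!is.character(e$label %||% NULL) || !nzchar(e$label))
      bad <- c(bad, sprintf("elements[%d] lacks a nonempty 'label'", i))
  }
  for (i in seq_along(doc$connections)) {
    cn <- doc$connections[[i]]
    for (f in c("from", "to", "polarity"))
      if (!is.character(cn[[f]] %||% NULL) || !nzchar(cn[[f]]))
        bad <- c(bad, sprintf("connections[%d] lacks '%s'", i, f))
    if (is.character(cn$polarity %||% NULL) &&
        !(cn$polarity %in% polarities()))
      bad <- c(bad, sprintf("connections[%d] polarity '%s' not admissible",
                            i, cn$polarity))
  }
  bad
}

#' Export a model as GraphViz DOT
#'
#' Positive links are drawn blue and negative links red, matching the usual
#' CLD color convention; proposed (potential) links are dashed.
#'
#' @param model A valid \code{cld_model}.
#' @param path Optional output file; when \code{NULL} the DOT text is
#'   returned.
#' @return DOT source text (invisibly when written to a file).
#' @export
export_dot <- function(model, path = NULL) {
  esc <- function(x) gsub('"', '\\\\"', x)
  v <- model$variables
  l <- model$links
  lines <- c(sprintf('digraph "%s" {', esc(model$name)),
             "  rankdir=LR;",
             "  node [shape=box, style=rounded];",
             sprintf('  "%s" [label="%s"];', esc(v$id), esc(v$label)))
  if (nrow(l)) {
    col <- ifelse(l$polarity == "positive", "blue", "red")
    sgn <- ifelse(l$polarity == "positive", "+", "−")
    style <- ifelse(l$proposed, ", style=dashed", "")
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [color=%s, label="%s"%s];',
      esc(l$from), esc(l$to), col, sgn, style))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
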