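# internal helpers shared across modules

cld_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cld_error"), call = call))
}

cld_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "cld_warning")))
}

#' Normalize a variable label into an identifier
#'
#' Identifiers are lower-cased, whitespace-collapsed versions of display
#' labels, so that hand-edited tables and coded notes referring to the same
#' variable unify on assembly.
#'
#' @param label Character vector of display labels.
#' @return Character vector of normalized ids.
#' @export
#' @examples
#' norm_id("  VA Provider   Turnover ")
norm_id <- function(label) {
  x <- tolower(trimws(as.character(label)))
  gsub("[[:space:]]+", " ", x)
}

# Multi-valued cells (tags, stakeholder sources) are stored as
# "|"-delimited strings in canonical form: split, trimmed, unique, sorted.
split_multi <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  parts <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
  sort(unique(parts[nzchar(parts)]))
}

join_multi <- function(parts) {
  parts <- sort(unique(trimws(parts[nzchar(trimws(parts))])))
  paste(parts, collapse = "|")
}

canon_multi <- function(x) {
  vapply(as.character(x), function(s) {
    if (is.na(s)) "" else join_multi(strsplit(s, "|", fixed = TRUE)[[1]])
  }, character(1), USE.NAMES = FALSE)
}

union_multi <- function(a, b) {
  join_multi(c(split_multi(a), split_multi(b)))
}

# Run an expression with a locally seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
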