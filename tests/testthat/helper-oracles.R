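# Independent oracles kept deliberately naive: they share no code with the
# package's enumeration or matching paths.

# Brute-force simple-cycle enumeration: plain DFS from every start vertex,
# keeping only cycles whose recorded rotation starts at their smallest id.
brute_force_cycles <- function(model, include_proposed = FALSE) {
  l <- model$links
  if (!include_proposed) l <- l[!l$proposed, , drop = FALSE]
  ids <- sort(model$variables$id)
  out <- list()
  walk <- function(start, path) {
    cur <- path[length(path)]
    succ <- l$to[l$from == cur]
    for (w in succ) {
      if (w == start) {
        if (length(path) >= 2 && path[1] == min(path))
          out[[length(out) + 1L]] <<- path
      } else if (!(w %in% path)) {
        walk(start, c(path, w))
      }
    }
  }
  for (s in ids) walk(s, s)
  out
}

cycle_signature <- function(cycle_ids) {
  k <- which(cycle_ids == min(cycle_ids))[1]
  rot <- if (k == 1) cycle_ids else
    cycle_ids[c(k:length(cycle_ids), seq_len(k - 1))]
  paste(rot, collapse = " -> ")
}

# Brute-force archetype matching at path length 1: enumerate every
# injective role assignment and check each template edge as a direct link.
brute_force_matches <- function(model, template) {
  l <- model$links[!model$links$proposed, , drop = FALSE]
  ids <- sort(model$variables$id)
  roles <- template$roles
  e <- template$edges
  link_pol <- function(a, b) {
    hit <- which(l$from == a & l$to == b)
    if (length(hit)) l$polarity[hit] else NA_character_
  }
  res <- character(0)
  perms <- function(pool, acc) {
    if (length(acc) == length(roles)) {
      ok <- TRUE
      for (i in seq_len(nrow(e))) {
        p <- link_pol(acc[match(e$from[i], roles)],
                      acc[match(e$to[i], roles)])
        if (is.na(p) || p != e$polarity[i]) { ok <- FALSE; break }
      }
      # loop constraints follow from edge polarities at length 1 as long
      # as the cycle closes over distinct bound variables, which
      # injectivity already guarantees
      if (ok) res <<- c(res, paste(acc, collapse = "|"))
      return(invisible())
    }
    for (v in pool) perms(setdiff(pool, v), c(acc, v))
  }
  perms(ids, character(0))
  sort(res)
}

random_small_model <- function(n_vars, n_links, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_vars))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- pairs[sample(nrow(pairs), min(n_links, nrow(pairs))), ]
  pick$polarity <- sample(c("positive", "negative"), nrow(pick),
                          replace = TRUE)
  assemble_model(data.frame(label = ids), pick, name = "random")
}

complete_digraph <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs$polarity <- "positive"
  assemble_model(data.frame(label = ids), pairs, name = "complete")
}
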