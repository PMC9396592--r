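#' Configuration for the synthetic CLD generator
#'
#' Describes the statistical shape of a generated causal-loop diagram:
#' size, sign balance, number of source-only (exogenous) variables, planted
#' hub densities, planted archetype instances, and per-stakeholder tagging
#' probabilities. The defaults for \code{p_negative} and
#' \code{source_tag_probs} reflect a stakeholder-coded access-to-care
#' model: balancing loops (needing negative links) are common, veteran and
#' VSO perspectives overlap heavily, clinic sources are fewer, and a small
#' share of links is imputed by the modeling team.
#'
#' @param n_vars Number of variables.
#' @param n_links Number of causal links (at most \code{n_vars*(n_vars-1)}).
#' @param p_negative Probability a background link is negative, in [0, 1].
#' @param n_exogenous Number of planted source-only variables.
#' @param hub_spec Integer vector of target link densities for planted hubs.
#' @param planted_archetypes Character vector of built-in template names,
#'   one entry per planted instance (currently \code{"drifting_goals"}).
#' @param source_tag_probs Named numeric vector of per-source tagging
#'   probabilities over \code{\link{stakeholder_sources}()}.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated \code{synth_config}.
#' @export
synth_config <- function(n_vars, n_links, p_negative = 0.35,
                         n_exogenous = 0, hub_spec = integer(0),
                         planted_archetypes = character(0),
                         source_tag_probs = c(veteran = 0.55,
                                              non_va_clinic = 0.35,
                                              va_system = 0.20,
                                              vso = 0.50,
                                              modeler = 0.15),
                         seed = 1) {
  cfg <- structure(list(n_vars = as.integer(n_vars),
                        n_links = as.integer(n_links),
                        p_negative = p_negative,
                        n_exogenous = as.integer(n_exogenous),
                        hub_spec = as.integer(hub_spec),
                        planted_archetypes = planted_archetypes,
                        source_tag_probs = source_tag_probs,
                        seed = as.integer(seed)),
                   class = "synth_config")
  check_feasible(cfg)
  cfg
}

check_feasible <- function(cfg) {
  fail <- function(msg) cld_stop(msg, "cld_feasibility_error")
  if (cfg$n_vars < 1) fail("n_vars must be positive")
  if (cfg$n_links < 0 || cfg$n_links > cfg$n_vars * (cfg$n_vars - 1))
    fail("n_links must lie in [0, n_vars*(n_vars-1)]")
  if (cfg$p_negative < 0 || cfg$p_negative > 1)
    fail("p_negative must lie in [0, 1]")
  if (cfg$n_exogenous < 0 || cfg$n_exogenous > cfg$n_vars)
    fail("n_exogenous must lie in [0, n_vars]")
  if (length(cfg$hub_spec) && any(cfg$hub_spec > cfg$n_vars - 1))
    fail("a planted hub density cannot exceed n_vars - 1")
  if (length(cfg$hub_spec) && any(cfg$hub_spec < 1))
    fail("planted hub densities must be positive")
  bad <- setdiff(cfg$planted_archetypes, names(builtin_templates()))
  if (length(bad))
    fail(paste("unknown archetype template(s):", paste(bad, collapse = ", ")))
  n_arch_vars <- sum(vapply(cfg$planted_archetypes, function(nm)
    length(builtin_templates()[[nm]]$roles), integer(1)))
  n_arch_links <- sum(vapply(cfg$planted_archetypes, function(nm)
    nrow(builtin_templates()[[nm]]$edges), integer(1)))
  if (n_arch_vars + length(cfg$hub_spec) + cfg$n_exogenous > cfg$n_vars)
    fail("not enough variables for the planted structure")
  if (n_arch_links + sum(cfg$hub_spec) + cfg$n_exogenous > cfg$n_links)
    fail("not enough links for the planted structure")
  if (any(cfg$source_tag_probs < 0) || any(cfg$source_tag_probs > 1) ||
      !all(names(cfg$source_tag_probs) %in% stakeholder_sources()))
    fail("source_tag_probs must be probabilities named by stakeholder source")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d vars, %d links, p(neg)=%.2f, %d exogenous, %d hub(s), %d archetype(s), seed %d\n",
    x$n_vars, x$n_links, x$p_negative, x$n_exogenous, length(x$hub_spec),
    length(x$planted_archetypes), x$seed))
  invisible(x)
}

#' The published-model-shaped generator preset
#'
#' A configuration emulating the statistical shape of the deposited
#' access-to-care model: 94 variables, 144 signed links, 31 source-only
#' exogenous drivers, ten hubs with link densities
#' 12, 9, 9, 8, 7, 7, 6, 6, 6, 6 (so the upper decile of link density is
#' six or more links), and one planted drifting-goals archetype.
#'
#' @param seed Integer seed.
#' @return A \code{synth_config}.
#' @export
paper_shape_config <- function(seed = 1) {
  synth_config(n_vars = 94, n_links = 144, p_negative = 0.35,
               n_exogenous = 31,
               hub_spec = c(12L, 9L, 9L, 8L, 7L, 7L, 6L, 6L, 6L, 6L),
               planted_archetypes = "drifting_goals", seed = seed)
}

var_id <- function(i) sprintf("var %03d", i)
var_label <- function(i) sprintf("Var %03d", i)

#' Generate a random CLD with planted structure
#'
#' Builds a model in four deterministic stages driven by the seed:
#' exogenous drivers are reserved first (they never receive incoming
#' links), archetype instances are planted next on fresh variables with
#' their template signs, hubs are planted by wiring spokes up to each
#' target density, and the remaining links are placed uniformly over the
#' still-admissible ordered pairs. Background placement never touches a
#' planted hub (their densities stay exact) and caps every other
#' variable's density below the smallest planted hub density, so planted
#' hubs are exactly the upper tail. Stakeholder source tags are sampled
#' independently per entity with at least one source guaranteed.
#'
#' @param config A \code{synth_config}.
#' @return List with \code{model} (a valid \code{cld_model}) and
#'   \code{truth} (a \code{planted_truth}: \code{planted_exogenous},
#'   \code{planted_hubs} data frame, \code{planted_loops} with intended
#'   classes, \code{planted_archetype_bindings}).
#' @export
generate_random_cld <- function(config) {
  check_feasible(config)
  with_local_seed(config$seed, generate_random_cld_impl(config))
}

generate_random_cld_impl <- function(cfg) {
  n <- cfg$n_vars
  ids <- var_id(seq_len(n))
  links <- data.frame(from = character(0), to = character(0),
                      polarity = character(0), stringsAsFactors = FALSE)
  pair_seen <- new.env(parent = emptyenv())
  degree <- stats::setNames(integer(n), ids)

  has_pair <- function(a, b) !is.null(pair_seen[[paste(a, b)]])
  add_link <- function(a, b, polarity) {
    stopifnot(a != b, !has_pair(a, b))
    pair_seen[[paste(a, b)]] <- TRUE
    degree[a] <<- degree[a] + 1L
    degree[b] <<- degree[b] + 1L
    links[nrow(links) + 1L, ] <<- list(a, b, polarity)
  }
  rand_polarity <- function() {
    if (stats::runif(1) < cfg$p_negative) "negative" else "positive"
  }

  # stage 1: reserve exogenous drivers (no incoming links, ever)
  exo <- sort(sample(ids, cfg$n_exogenous))
  free <- setdiff(ids, exo)

  # stage 2: plant archetype instances on fresh non-exogenous variables
  bindings <- list()
  planted_loops <- list()
  tpls <- builtin_templates()
  for (nm in cfg$planted_archetypes) {
    tpl <- tpls[[nm]]
    vars <- sample(free, length(tpl$roles))
    free <- setdiff(free, vars)
    bnd <- stats::setNames(vars, tpl$roles)
    e <- tpl$edges
    for (i in seq_len(nrow(e)))
      add_link(bnd[[e$from[i]]], bnd[[e$to[i]]], e$polarity[i])
    bindings[[length(bindings) + 1L]] <-
      list(template = nm, binding = bnd)
    for (lc in tpl$loop_constraints)
      planted_loops[[length(planted_loops) + 1L]] <-
        list(cycle = unname(bnd[lc$roles]), class = lc$class)
  }

  # stage 3: plant hubs; spokes avoid other hubs (densities stay exact)
  # and stay under the background density cap so planted hubs are exactly
  # the upper tail of the degree distribution
  cap <- if (length(cfg$hub_spec)) min(cfg$hub_spec) - 1L else Inf
  hub_ids <- character(0)
  if (length(cfg$hub_spec)) {
    spec <- sort(cfg$hub_spec, decreasing = TRUE)
    hub_ids <- sample(free, length(spec))
    free_nonhub <- setdiff(ids, c(hub_ids))
    for (h in seq_along(hub_ids)) {
      hub <- hub_ids[h]
      want <- spec[h]
      # incoming spokes drawn preferentially from exogenous drivers that
      # still lack an outgoing link (hubs interface with exogenous drivers)
      n_in <- want %/% 2L
      n_out <- want - n_in
      uncovered <- exo[degree[exo] == 0L]
      in_pool <- c(sample(uncovered), sample(setdiff(free_nonhub, exo)))
      in_pool <- in_pool[!vapply(in_pool, has_pair, logical(1), b = hub)]
      in_pool <- in_pool[in_pool != hub & degree[in_pool] < cap]
      out_pool <- sample(setdiff(free_nonhub, exo))
      out_pool <- out_pool[!vapply(out_pool, function(t)
        has_pair(hub, t), logical(1))]
      out_pool <- out_pool[out_pool != hub & degree[out_pool] < cap]
      if (length(in_pool) < n_in || length(out_pool) < n_out)
        cld_stop("hub planting ran out of admissible spokes",
                 "cld_feasibility_error")
      for (s in in_pool[seq_len(n_in)]) add_link(s, hub, rand_polarity())
      for (t in out_pool[seq_len(n_out)]) add_link(hub, t, rand_polarity())
    }
  }

  # stage 4a: every exogenous driver needs at least one outgoing link
  targets <- setdiff(ids, c(exo, hub_ids))
  for (x in exo[degree[exo] == 0L]) {
    pool <- sample(targets)
    pool <- pool[!vapply(pool, function(t) has_pair(x, t), logical(1))]
    pool <- pool[degree[pool] < cap]
    if (length(pool) == 0)
      cld_stop("no admissible target for an exogenous driver",
               "cld_feasibility_error")
    add_link(x, pool[1], rand_polarity())
  }
  if (nrow(links) > cfg$n_links)
    cld_stop("planted structure already exceeds n_links",
             "cld_feasibility_error")

  # stage 4b: uniform background fill over admissible ordered pairs
  sources_pool <- setdiff(ids, hub_ids)          # never touch a hub
  targets_pool <- setdiff(ids, c(hub_ids, exo))  # never into an exogenous
  candidates <- expand.grid(from = sources_pool, to = targets_pool,
                            stringsAsFactors = FALSE)
  candidates <- candidates[candidates$from != candidates$to, , drop = FALSE]
  candidates <- candidates[sample(nrow(candidates)), , drop = FALSE]
  i <- 1L
  while (nrow(links) < cfg$n_links) {
    if (i > nrow(candidates))
      cld_stop("background fill exhausted admissible pairs",
               "cld_feasibility_error")
    a <- candidates$from[i]; b <- candidates$to[i]
    i <- i + 1L
    if (has_pair(a, b)) next
    if (degree[a] >= cap || degree[b] >= cap) next
    add_link(a, b, rand_polarity())
  }

  # stakeholder tags: independent per entity, at least one guaranteed
  draw_sources <- function() {
    p <- cfg$source_tag_probs
    got <- names(p)[stats::runif(length(p)) < p]
    if (length(got) == 0) got <- "modeler"
    join_multi(got)
  }
  vrows <- data.frame(label = var_label(seq_len(n)),
                      sources = vapply(seq_len(n), function(i)
                        draw_sources(), character(1)),
                      stringsAsFactors = FALSE)
  lrows <- links
  lrows$sources <- vapply(seq_len(nrow(links)), function(i)
    draw_sources(), character(1))

  model <- assemble_model(vrows, lrows,
                          name = sprintf("synthetic cld (seed %d)",
                                         cfg$seed))
  truth <- structure(list(
    planted_exogenous = exo,
    planted_hubs = data.frame(id = hub_ids,
                              density = unname(degree[hub_ids]),
                              stringsAsFactors = FALSE),
    planted_loops = planted_loops,
    planted_archetype_bindings = bindings),
    class = "planted_truth")
  list(model = model, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf(
    "<planted_truth> %d exogenous, %d hub(s), %d loop(s), %d archetype binding(s)\n",
    length(x$planted_exogenous), nrow(x$planted_hubs),
    length(x$planted_loops), length(x$planted_archetype_bindings)))
  invisible(x)
}

#' Hand-coded drifting-goals staffing fixture
#'
#' A small model of VA provider staffing encoding the drifting-goals
#' configuration: a reinforcing loop R1 in which patient load per provider
#' drives burnout, which erodes retention, which raises patient load; a
#' balancing recruitment loop B9 closing the staffing gap; a balancing loop
#' B10 in which sending veterans to community care relieves hiring pressure
#' by lowering the staffing goal; and a balancing loop B11 in which
#' community care drives downsizing of VA services. Rurality enters as an
#' exogenous driver of patient load and retention difficulty.
#'
#' @return A valid \code{cld_model} whose variables carry a
#'   \code{"staffing challenges"} region and stakeholder source tags.
#' @export
make_fig5_fixture <- function() {
  vars <- data.frame(
    label = c("VA staffing goal", "Filled VA provider positions",
              "VA staffing gap", "Provider recruitment and retention efforts",
              "Veterans sent to community care", "Downsizing of VA services",
              "Patient load per provider", "VA provider burnout",
              "VA provider retention", "Rurality"),
    sources = c("va_system", "va_system", "va_system|modeler", "va_system",
                "veteran|vso", "veteran", "va_system", "va_system|veteran",
                "va_system|veteran", "veteran|vso|modeler"),
    sub_model = "staffing challenges",
    note = c("", "", "", "",
             "Veterans worried community care would shrink VA hiring.",
             "", "", "Provider turnover compromised continuity of care.",
             "", ""),
    stringsAsFactors = FALSE)
  links <- data.frame(
    from = c("VA staffing goal", "Filled VA provider positions",
             "VA staffing gap", "Provider recruitment and retention efforts",
             "VA staffing gap", "Veterans sent to community care",
             "Veterans sent to community care", "Downsizing of VA services",
             "Patient load per provider", "VA provider burnout",
             "VA provider retention", "VA provider retention",
             "Filled VA provider positions", "Rurality", "Rurality"),
    to = c("VA staffing gap", "VA staffing gap",
           "Provider recruitment and retention efforts",
           "Filled VA provider positions",
           "Veterans sent to community care", "VA staffing goal",
           "Downsizing of VA services", "VA staffing goal",
           "VA provider burnout", "VA provider retention",
           "Patient load per provider", "Filled VA provider positions",
           "Patient load per provider", "Patient load per provider",
           "VA provider retention"),
    polarity = c("+", "-", "+", "+", "+", "-", "+", "-", "+", "-", "-",
                 "+", "-", "+", "-"),
    sources = "va_system|veteran",
    stringsAsFactors = FALSE)
  assemble_model(vars, links, name = "va provider staffing (drifting goals)")
}

#' Registry of named loops for the staffing fixture
#'
#' @return Named list of id cycles for R1, B9, B10 and B11 in
#'   \code{\link{make_fig5_fixture}}.
#' @export
fig5_loop_registry <- function() {
  list(
    R1 = c("patient load per provider", "va provider burnout",
           "va provider retention"),
    B9 = c("va staffing gap", "provider recruitment and retention efforts",
           "filled va provider positions"),
    B10 = c("va staffing gap", "veterans sent to community care",
            "va staffing goal"),
    B11 = c("va staffing gap", "veterans sent to community care",
            "downsizing of va services", "va staffing goal"))
}

#' Planted-feature recovery experiment
#'
#' For each configuration in a grid, repeatedly generates a model with its
#' planted truth, runs the structural analyses, and reports the fraction
#' of planted exogenous drivers, hubs, loops and archetype bindings that
#' the analyses recover exactly. Deterministic for a fixed seed.
#'
#' @param configs List of \code{synth_config} (a grid).
#' @param n_reps Repetitions per configuration.
#' @param seed Integer master seed; per-repetition seeds are derived from
#'   it.
#' @param max_path_length Path bound for archetype matching (default 1:
#'   planted template edges are single links).
#' @return Data frame with one row per configuration: recovery fractions
#'   per feature kind (NA when a kind was not planted).
#' @export
recovery_experiment <- function(configs, n_reps, seed = 1,
                                max_path_length = 1) {
  rep_seeds <- with_local_seed(seed,
    matrix(sample.int(2^31 - 2, length(configs) * n_reps),
           nrow = length(configs)))
  rows <- lapply(seq_along(configs), function(ci) {
    cfg <- configs[[ci]]
    hits <- c(exogenous = 0, hubs = 0, loops = 0, archetypes = 0)
    tots <- c(exogenous = 0, hubs = 0, loops = 0, archetypes = 0)
    for (r in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$seed <- rep_seeds[ci, r]
      gen <- generate_random_cld(cfg_r)
      m <- gen$model; tr <- gen$truth

      exo <- find_exogenous_drivers(m)$exogenous
      tots["exogenous"] <- tots["exogenous"] + length(tr$planted_exogenous)
      hits["exogenous"] <- hits["exogenous"] +
        sum(tr$planted_exogenous %in% exo)

      hubs <- find_hubs(m)$hubs$id
      tots["hubs"] <- tots["hubs"] + nrow(tr$planted_hubs)
      hits["hubs"] <- hits["hubs"] + sum(tr$planted_hubs$id %in% hubs)

      if (length(tr$planted_loops)) {
        loops <- enumerate_feedback_loops(m)
        keys <- vapply(loops, function(lp) cycle_key(lp$variable_cycle),
                       character(1))
        cls <- vapply(loops, `[[`, character(1), "loop_class")
        for (pl in tr$planted_loops) {
          tots["loops"] <- tots["loops"] + 1
          j <- match(cycle_key(pl$cycle), keys)
          if (!is.na(j) && cls[j] == pl$class)
            hits["loops"] <- hits["loops"] + 1
        }
      }

      for (pb in tr$planted_archetype_bindings) {
        tots["archetypes"] <- tots["archetypes"] + 1
        found <- match_template(m, builtin_templates()[[pb$template]],
                                max_path_length = max_path_length)
        bnds <- vapply(found, function(f)
          paste(f$role_binding, collapse = "|"), character(1))
        if (paste(pb$binding, collapse = "|") %in% bnds)
          hits["archetypes"] <- hits["archetypes"] + 1
      }
    }
    frac <- ifelse(tots > 0, hits / tots, NA_real_)
    data.frame(config = ci, n_reps = n_reps,
               exogenous_recovery = frac[["exogenous"]],
               hub_recovery = frac[["hubs"]],
               loop_recovery = frac[["loops"]],
               archetype_recovery = frac[["archetypes"]])
  })
  do.call(rbind, rows)
}
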