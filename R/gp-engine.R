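#' Configuration for the genetic-programming regressor
#'
#' Collects every evolution hyperparameter plus the random seed. The genetic
#' operator probabilities (`p_crossover`, `p_subtree_mutation`,
#' `p_point_mutation`, `p_reproduction`) must sum to 1.
#'
#' @param population_size Number of individuals per generation.
#' @param max_generations Generation budget.
#' @param stopping_threshold Stop early once the best raw fitness (training
#'   R-squared) reaches this value.
#' @param tournament_size Individuals drawn (without replacement) per
#'   tournament.
#' @param p_crossover,p_subtree_mutation,p_point_mutation,p_reproduction
#'   Genetic-operator probabilities; must sum to 1 (within 1e-12).
#' @param constant_range Length-2 interval from which constant leaves are
#'   drawn uniformly.
#' @param init_depth_range Length-2 integer interval of initial tree depths
#'   for ramped half-and-half initialization.
#' @param max_depth Hard depth bound (edges) for every tree in the run.
#' @param parsimony_coefficient Fitness penalty per tree node; selection acts
#'   on `raw_fitness - parsimony_coefficient * node_count`.
#' @param elitism_count Best individuals (by raw fitness) copied unchanged
#'   into the next generation.
#' @param protected_epsilon Protection threshold for division-like operators.
#' @param seed Integer seed; the whole evolution trajectory is reproducible
#'   from it.
#' @param function_set Character vector of allowed symbols (subset of
#'   `names(gp_function_set)`).
#' @param terminal_constants Optional numeric vector: when given, constant
#'   leaves are drawn from this finite set instead of `constant_range`.
#' @return A validated list of class `ga_config`.
#' @export
ga_config <- function(population_size = 500L,
                      max_generations = 100L,
                      stopping_threshold = 0.9999,
                      tournament_size = 5L,
                      p_crossover = 0.70,
                      p_subtree_mutation = 0.15,
                      p_point_mutation = 0.10,
                      p_reproduction = 0.05,
                      constant_range = c(-10, 10),
                      init_depth_range = c(2L, 4L),
                      max_depth = 6L,
                      parsimony_coefficient = 0.001,
                      elitism_count = 1L,
                      protected_epsilon = 1e-6,
                      seed = 1L,
                      function_set = names(gp_function_set),
                      terminal_constants = NULL) {
  cfg <- list(
    population_size = as.integer(population_size),
    max_generations = as.integer(max_generations),
    stopping_threshold = stopping_threshold,
    tournament_size = as.integer(tournament_size),
    p_crossover = p_crossover,
    p_subtree_mutation = p_subtree_mutation,
    p_point_mutation = p_point_mutation,
    p_reproduction = p_reproduction,
    constant_range = as.numeric(constant_range),
    init_depth_range = as.integer(init_depth_range),
    max_depth = as.integer(max_depth),
    parsimony_coefficient = parsimony_coefficient,
    elitism_count = as.integer(elitism_count),
    protected_epsilon = protected_epsilon,
    seed = as.integer(seed),
    function_set = function_set,
    terminal_constants = if (is.null(terminal_constants)) NULL else
      as.numeric(terminal_constants)
  )
  class(cfg) <- "ga_config"
  validate_ga_config(cfg)
  cfg
}

validate_ga_config <- function(cfg) {
  probs <- c(cfg$p_crossover, cfg$p_subtree_mutation,
             cfg$p_point_mutation, cfg$p_reproduction)
  if (any(probs < 0) || any(probs > 1)) {
    stop_validation("operator probabilities must lie in [0, 1]")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop_validation("operator probabilities must sum to 1 (got %.15f)",
                    sum(probs))
  }
  if (cfg$tournament_size < 1L || cfg$population_size < cfg$tournament_size) {
    stop_validation("need population_size >= tournament_size >= 1")
  }
  if (cfg$elitism_count >= cfg$population_size || cfg$elitism_count < 0L) {
    stop_validation("elitism_count must be in [0, population_size)")
  }
  if (length(cfg$constant_range) != 2L ||
      cfg$constant_range[1] > cfg$constant_range[2]) {
    stop_validation("constant_range must be an ordered length-2 interval")
  }
  if (length(cfg$init_depth_range) != 2L ||
      cfg$init_depth_range[1] > cfg$init_depth_range[2] ||
      cfg$init_depth_range[1] < 0L) {
    stop_validation("init_depth_range must be an ordered nonnegative interval")
  }
  if (cfg$init_depth_range[2] > cfg$max_depth) {
    stop_validation("init_depth_range must not exceed max_depth")
  }
  if (cfg$protected_epsilon <= 0) {
    stop_validation("protected_epsilon must be positive")
  }
  if (cfg$parsimony_coefficient < 0) {
    stop_validation("parsimony_coefficient must be nonnegative")
  }
  unknown <- setdiff(cfg$function_set, names(gp_function_set))
  if (length(unknown) > 0L) {
    stop_validation("unknown function symbols: %s",
                    paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# --- random tree construction -----------------------------------------------

random_leaf <- function(config) {
  if (stats::runif(1) < 0.5) {
    gp_var()
  } else if (!is.null(config$terminal_constants)) {
    gp_const(config$terminal_constants[
      sample.int(length(config$terminal_constants), 1L)])
  } else {
    gp_const(stats::runif(1, config$constant_range[1], config$constant_range[2]))
  }
}

random_symbol <- function(config, arity = NULL, exclude = NULL) {
  pool <- config$function_set
  if (!is.null(arity)) pool <- pool[gp_function_set[pool] == arity]
  if (!is.null(exclude) && length(pool) > 1L) pool <- setdiff(pool, exclude)
  pool[sample.int(length(pool), 1L)]
}

#' Generate a random expression tree
#'
#' `method = "full"` places function nodes at every level down to
#' `depth_limit`; `method = "grow"` may terminate branches early with leaves.
#' Ramped half-and-half initialization (used by [evolve()]) cycles both
#' methods over a range of depth limits. Consumes the R random-number stream.
#'
#' @param config A [ga_config()].
#' @param depth_limit Maximum depth (edges); 0 yields a single leaf.
#' @param method `"grow"` or `"full"`.
#' @return An expression tree satisfying the arity and depth invariants.
#' @export
random_tree <- function(config, depth_limit, method = c("grow", "full")) {
  method <- match.arg(method)
  if (depth_limit < 0L) stop_validation("depth_limit must be >= 0")
  build <- function(depth_left) {
    make_internal <- depth_left > 0L &&
      (method == "full" || stats::runif(1) < 0.7)
    if (!make_internal) return(random_leaf(config))
    sym <- random_symbol(config)
    kids <- lapply(seq_len(gp_function_set[[sym]]),
                   function(i) build(depth_left - 1L))
    do.call(gp_call, c(list(sym), kids))
  }
  build(as.integer(depth_limit))
}

# --- subtree indexing (preorder) --------------------------------------------

get_node <- function(tree, index) {
  cnt <- 0L
  found <- NULL
  rec <- function(node) {
    cnt <<- cnt + 1L
    if (cnt == index) {
      found <<- node
      return(TRUE)
    }
    if (node$type == "call") {
      for (k in node$kids) if (rec(k)) return(TRUE)
    }
    FALSE
  }
  rec(tree)
  if (is.null(found)) stop_validation("node index out of range")
  found
}

replace_node <- function(tree, index, subtree) {
  cnt <- 0L
  rec <- function(node) {
    cnt <<- cnt + 1L
    if (cnt == index) return(subtree)
    if (cnt < index && node$type == "call") {
      for (i in seq_along(node$kids)) {
        if (cnt >= index) break
        node$kids[[i]] <- rec(node$kids[[i]])
      }
    }
    node
  }
  rec(tree)
}

# depth (edges from root) of the node at the given preorder index
node_depth_at <- function(tree, index) {
  cnt <- 0L
  found <- NA_integer_
  rec <- function(node, depth) {
    cnt <<- cnt + 1L
    if (cnt == index) {
      found <<- depth
      return(TRUE)
    }
    if (node$type == "call") {
      for (k in node$kids) if (rec(k, depth + 1L)) return(TRUE)
    }
    FALSE
  }
  rec(tree, 0L)
  if (is.na(found)) stop_validation("node index out of range")
  found
}

# --- genetic operators ------------------------------------------------------

#' Subtree crossover
#'
#' Replaces a uniformly chosen subtree of a copy of `parent_a` with a
#' uniformly chosen subtree of `parent_b`. If the child exceeds
#' `config$max_depth` the draw is retried up to 10 times, after which a copy
#' of `parent_a` is returned. Parents are never modified.
#'
#' @param parent_a,parent_b Expression trees.
#' @param config A [ga_config()].
#' @return An expression tree of depth at most `config$max_depth`.
#' @export
crossover <- function(parent_a, parent_b, config) {
  nb <- node_count(parent_b)
  na_ <- node_count(parent_a)
  for (attempt in 1:10) {
    i <- sample.int(na_, 1L)
    j <- sample.int(nb, 1L)
    child <- replace_node(parent_a, i, get_node(parent_b, j))
    if (tree_depth(child) <= config$max_depth) return(child)
  }
  parent_a
}

#' Mutate an expression tree
#'
#' Subtree mutation replaces a uniformly chosen subtree with a fresh random
#' tree grown within the depth budget remaining at that position. Point
#' mutation replaces one internal symbol by another of identical arity, or
#' one leaf by another leaf; a constant leaf is either redrawn uniformly or
#' perturbed by Gaussian creep at one of two scales (sd 0.5 or 0.02,
#' clamped to `constant_range`), with equal probability. With
#' `kind = "auto"` the two mutation kinds are chosen in proportion to
#' `p_subtree_mutation` and `p_point_mutation`.
#'
#' @param tree Expression tree.
#' @param config A [ga_config()].
#' @param kind `"auto"`, `"subtree"` or `"point"`.
#' @return A mutated expression tree satisfying all invariants.
#' @export
mutate <- function(tree, config, kind = c("auto", "subtree", "point")) {
  kind <- match.arg(kind)
  if (kind == "auto") {
    total <- config$p_subtree_mutation + config$p_point_mutation
    kind <- if (total <= 0 || stats::runif(1) <
               config$p_subtree_mutation / total) "subtree" else "point"
  }
  idx <- sample.int(node_count(tree), 1L)
  if (kind == "subtree") {
    budget <- config$max_depth - node_depth_at(tree, idx)
    depth <- min(
      sample(config$init_depth_range[1]:config$init_depth_range[2], 1L),
      budget
    )
    return(replace_node(tree, idx, random_tree(config, max(depth, 0L), "grow")))
  }
  node <- get_node(tree, idx)
  replacement <- if (node$type == "call") {
    sym <- random_symbol(config, arity = gp_function_set[[node$symbol]],
                         exclude = node$symbol)
    do.call(gp_call, c(list(sym), node$kids))
  } else if (node$type == "const" && is.null(config$terminal_constants) &&
             stats::runif(1) < 0.5) {
    # two-scale Gaussian creep: coarse moves to escape, fine moves to refine
    creep_sd <- if (stats::runif(1) < 0.5) 0.5 else 0.02
    gp_const(clamp(node$value + stats::rnorm(1, 0, creep_sd),
                   config$constant_range[1], config$constant_range[2]))
  } else {
    random_leaf(config)
  }
  replace_node(tree, idx, replacement)
}

# --- constant refinement ----------------------------------------------------

# preorder indices of constant leaves
constant_indices <- function(tree) {
  cnt <- 0L
  acc <- integer(0)
  rec <- function(node) {
    cnt <<- cnt + 1L
    if (node$type == "const") {
      acc[length(acc) + 1L] <<- cnt
    } else if (node$type == "call") {
      for (k in node$kids) rec(k)
    }
  }
  rec(tree)
  acc
}

set_constants <- function(tree, indices, values) {
  for (i in seq_along(indices)) {
    tree <- replace_node(tree, indices[i], gp_const(values[i]))
  }
  tree
}

# Lamarckian local search over the constant leaves of one tree: Nelder-Mead
# on the training R^2, constants clamped to the configured range. Returns an
# improved individual or the original one.
refine_constants <- function(ind, times, values, config) {
  idx <- constant_indices(ind$tree)
  if (length(idx) == 0L) return(ind)
  start <- vapply(idx, function(i) get_node(ind$tree, i)$value, numeric(1))
  lo <- config$constant_range[1]
  hi <- config$constant_range[2]
  objective <- function(par) {
    tr <- set_constants(ind$tree, idx, clamp(par, lo, hi))
    -r_squared(values, eval_tree(tr, times, config$protected_epsilon))
  }
  opt <- tryCatch(
    if (length(start) == 1L) {
      stats::optim(start, objective, method = "Brent", lower = lo,
                   upper = hi)
    } else {
      stats::optim(start, objective, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-12))
    },
    error = function(e) NULL
  )
  if (is.null(opt) || -opt$value <= ind$raw_fitness) return(ind)
  new_individual(set_constants(ind$tree, idx, clamp(opt$par, lo, hi)),
                 times, values, config)
}

# --- individuals and selection ----------------------------------------------

new_individual <- function(tree, times, values, config) {
  preds <- eval_tree(tree, times, config$protected_epsilon)
  raw <- r_squared(values, preds)
  n <- node_count(tree)
  list(tree = tree, n_nodes = n, raw_fitness = raw,
       penalized_fitness = raw - config$parsimony_coefficient * n)
}

#' Tournament selection
#'
#' Draws `tournament_size` distinct individuals uniformly without replacement
#' and returns the one with the highest penalized fitness. Ties are broken by
#' lower node count, then by draw order.
#'
#' @param population List of individuals (as produced inside [evolve()]:
#'   each has `tree`, `n_nodes`, `raw_fitness`, `penalized_fitness`).
#' @param config A [ga_config()].
#' @return The selected individual.
#' @export
tournament_select <- function(population, config) {
  n <- length(population)
  if (n == 0L) stop_validation("population is empty")
  if (config$tournament_size > n) {
    stop_validation("tournament_size (%d) exceeds population size (%d)",
                    config$tournament_size, n)
  }
  idx <- sample.int(n, config$tournament_size)
  best <- idx[1L]
  bp <- population[[best]]$penalized_fitness
  bn <- population[[best]]$n_nodes
  for (i in idx[-1L]) {
    p <- population[[i]]$penalized_fitness
    if (p > bp || (p == bp && population[[i]]$n_nodes < bn)) {
      best <- i
      bp <- p
      bn <- population[[i]]$n_nodes
    }
  }
  population[[best]]
}

order_by_raw <- function(population) {
  raw <- vapply(population, `[[`, numeric(1), "raw_fitness")
  nn <- vapply(population, `[[`, numeric(1), "n_nodes")
  order(-raw, nn)
}

# --- main evolutionary loop -------------------------------------------------

#' Evolve a symbolic expression of time fitting the given values
#'
#' Standard generational genetic-programming loop: ramped half-and-half
#' initialization, fitness = training R-squared (raw) with a parsimony
#' penalty applied for selection, tournament selection, subtree crossover,
#' subtree/point mutation and reproduction per the configured probabilities,
#' elitism by raw fitness. Two robustness mechanisms supplement the loop:
#' the constants of each generation's best individual are polished by a
#' bounded Nelder-Mead local search (Lamarckian constant refinement), and
#' after 15 generations without improvement of the best raw fitness the
#' non-elite population is replaced by fresh random individuals (diversity
#' restart). Stops once the best raw fitness reaches
#' `stopping_threshold` or after `max_generations` generations. The entire
#' trajectory is reproducible from `config$seed`; the caller's random-number
#' state is left untouched.
#'
#' @param times Numeric vector of (scaled) time inputs; at least two distinct
#'   values.
#' @param values Numeric vector of observations, same length as `times`.
#' @param config A [ga_config()].
#' @return A list of class `gp_fit`: `best` (individual with the highest raw
#'   fitness reached, ties to fewer nodes), `best_expression` (its text
#'   form), `history` (per-generation data frame of best raw/penalized
#'   fitness and node count) and `generations_run`.
#' @export
evolve <- function(times, values, config = ga_config()) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop_validation("times and values must have equal length")
  }
  if (length(unique(times)) < 2L) {
    stop_validation("need at least 2 distinct timepoints to fit")
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop_validation("times and values must be finite")
  }

  withr::with_seed(config$seed, {
    # ramped half-and-half: cycle depths x {grow, full}
    depths <- config$init_depth_range[1]:config$init_depth_range[2]
    fresh_individual <- function(i) {
      d <- depths[((i - 1L) %/% 2L) %% length(depths) + 1L]
      m <- if (i %% 2L == 0L) "full" else "grow"
      new_individual(random_tree(config, d, m), times, values, config)
    }
    population <- lapply(seq_len(config$population_size), fresh_individual)

    # Lamarckian polish of the current generation's best individual
    polish_best <- function(pop) {
      b_idx <- order_by_raw(pop)[1L]
      refined <- refine_constants(pop[[b_idx]], times, values, config)
      if (refined$raw_fitness > pop[[b_idx]]$raw_fitness) {
        pop[[b_idx]] <- refined
      }
      pop
    }
    population <- polish_best(population)

    best_of <- function(pop) pop[[order_by_raw(pop)[1L]]]
    best <- best_of(population)
    history <- list()
    record <- function(gen, pop) {
      b <- best_of(pop)
      history[[length(history) + 1L]] <<- data.frame(
        generation = gen,
        best_raw = b$raw_fitness,
        best_penalized = b$penalized_fitness,
        best_nodes = b$n_nodes
      )
    }
    record(0L, population)

    gen <- 0L
    stagnant <- 0L
    n_elite <- config$elitism_count
    cum <- cumsum(c(config$p_crossover, config$p_subtree_mutation,
                    config$p_point_mutation))
    while (best$raw_fitness < config$stopping_threshold &&
           gen < config$max_generations) {
      gen <- gen + 1L
      nextpop <- vector("list", config$population_size)
      if (n_elite > 0L) {
        elite_idx <- order_by_raw(population)[seq_len(n_elite)]
        nextpop[seq_len(n_elite)] <- population[elite_idx]
      }
      if (stagnant >= 15L) {
        # diversity restart: replace everything but the elites with fresh
        # random individuals
        for (i in seq.int(n_elite + 1L, config$population_size)) {
          nextpop[[i]] <- fresh_individual(i)
        }
        stagnant <- 0L
      } else {
        for (i in seq.int(n_elite + 1L, config$population_size)) {
          u <- stats::runif(1)
          child_tree <- if (u < cum[1L]) {
            crossover(tournament_select(population, config)$tree,
                      tournament_select(population, config)$tree, config)
          } else if (u < cum[2L]) {
            mutate(tournament_select(population, config)$tree, config,
                   "subtree")
          } else if (u < cum[3L]) {
            mutate(tournament_select(population, config)$tree, config,
                   "point")
          } else {
            tournament_select(population, config)$tree
          }
          nextpop[[i]] <- new_individual(child_tree, times, values, config)
        }
      }
      population <- polish_best(nextpop)
      gen_best <- best_of(population)
      if (gen_best$raw_fitness > best$raw_fitness + 1e-12) {
        best <- gen_best
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (gen_best$raw_fitness > best$raw_fitness ||
            (gen_best$raw_fitness == best$raw_fitness &&
             gen_best$n_nodes < best$n_nodes)) {
          best <- gen_best
        }
      }
      record(gen, population)
    }

    structure(list(
      best = best,
      best_expression = to_infix(best$tree),
      history = do.call(rbind, history),
      generations_run = gen
    ), class = "gp_fit")
  })
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Genetic-programming fit\n")
  cat("  best expression:", x$best_expression, "\n")
  cat(sprintf("  raw fitness (train R^2): %.6f over %d generations\n",
              x$best$raw_fitness, x$generations_run))
  invisible(x)
}
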