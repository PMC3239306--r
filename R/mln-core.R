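# Compact Markov Logic engine.
#
# A ground network holds hidden ground atoms, per-atom "local" factors
# (weight keys whose summed weights give the atom's unit score; the observed
# antecedents of local formulae are already folded in at grounding time) and
# a set of ground clauses in implication normal form: a clause is satisfied
# iff some atom in `pos` is true or some atom in `neg` is false. Soft clauses
# carry a weight key; hard clauses must be satisfied by any MAP assignment.
#
# MAP inference solves the standard 0-1 encoding of this problem exactly:
# one binary variable per hidden atom, one satisfaction indicator per soft
# clause, linear implication rows — here by depth-first branch and bound with
# hard-clause unit propagation, connected-component decomposition and an
# admissible bound, rather than an external integer-programming library.

#' Construct a ground network
#'
#' @param atoms Tibble with columns `name` (unique atom key), `pred` and any
#'   argument columns; row order defines atom ids and the lexicographic
#'   tie-break order.
#' @param local List (aligned with `atoms` rows) of character vectors: the
#'   weight keys of the local factors attached to each atom.
#' @param clauses List of clauses, each `list(neg =, pos =, key =, hard =)`
#'   with `neg`/`pos` integer atom ids, `key` a weight key (`NA` for hard
#'   clauses) and `hard` a flag.
#' @return An `mln_network`.
#' @export
mln_network <- function(atoms, local = NULL, clauses = list()) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (n > 0 && anyDuplicated(atoms$name)) abort("atom names must be unique")
  local <- local %||% rep(list(character()), n)
  for (cl in clauses) {
    ids <- c(cl$neg, cl$pos)
    if (length(ids) == 0 || any(ids < 1 | ids > n)) {
      abort("clause references undeclared atoms")
    }
  }
  structure(list(atoms = atoms, local = local, clauses = clauses,
                 n = n), class = "mln_network")
}

#' @export
print.mln_network <- function(x, ...) {
  nh <- sum(vapply(x$clauses, function(cl) isTRUE(cl$hard), TRUE))
  cat("<mln_network> ", x$n, " hidden atoms, ", length(x$clauses),
      " clauses (", nh, " hard)\n", sep = "")
  invisible(x)
}

wget <- function(weights, keys) {
  if (length(keys) == 0) return(numeric())
  if (is.environment(weights)) {
    unlist(mget(keys, envir = weights, ifnotfound = 0), use.names = FALSE)
  } else {
    v <- unname(weights[keys])
    v[is.na(v)] <- 0
    v
  }
}

atom_scores <- function(network, weights, extra = NULL) {
  s <- numeric(network$n)
  keys <- unlist(network$local, use.names = FALSE)
  if (length(keys) > 0) {
    idx <- rep(seq_len(network$n), lengths(network$local))
    vals <- wget(weights, keys)
    agg <- rowsum(vals, idx)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (!is.null(extra)) s <- s + extra
  s
}

clause_weights <- function(network, weights) {
  vapply(network$clauses, function(cl) {
    if (isTRUE(cl$hard)) Inf else wget(weights, cl$key)
  }, numeric(1))
}

assignment_objective <- function(network, weights, x, extra = NULL) {
  s <- atom_scores(network, weights, extra)
  obj <- sum(s[x])
  for (k in seq_along(network$clauses)) {
    cl <- network$clauses[[k]]
    sat <- any(x[cl$pos]) || any(!x[cl$neg])
    if (isTRUE(cl$hard)) {
      if (!sat) return(-Inf)
    } else if (sat) {
      obj <- obj + wget(weights, cl$key)
    }
  }
  obj
}

# comparator implementing: higher objective; then fewer true atoms; then
# lexicographically smaller assignment (false preferred at the first
# differing atom)
better_assignment <- function(obj, x, best_obj, best_x, tol = 1e-9) {
  if (obj > best_obj + tol) return(TRUE)
  if (obj < best_obj - tol) return(FALSE)
  nt <- sum(x); bt <- sum(best_x)
  if (nt != bt) return(nt < bt)
  d <- which(x != best_x)
  length(d) > 0 && !x[d[1]]
}

#' Exact MAP inference by branch and bound
#'
#' Finds a truth assignment of the hidden atoms maximizing the summed atom
#' scores plus the weights of satisfied soft clauses, subject to every hard
#' clause being satisfied. Among optima, ties are broken toward fewer true
#' atoms, then by lexicographic atom order. Solved exactly: hard-clause unit
#' propagation, decomposition into connected components of the factor graph,
#' then depth-first search with an admissible upper bound (undecided atoms
#' count at `max(score, 0)`; an unfalsified soft clause counts at
#' `max(weight, 0)`).
#'
#' @param network An [mln_network()].
#' @param weights Named numeric vector or environment mapping weight keys to
#'   values.
#' @param extra_scores Optional numeric vector of additional per-atom unit
#'   scores (used for loss-augmented decoding).
#' @return List with `assignment` (named logical), `objective`, and the atom
#'   tibble filtered to true atoms (`true_atoms`).
#' @export
map_infer <- function(network, weights, extra_scores = NULL) {
  n <- network$n
  if (n == 0) {
    return(list(assignment = logical(), objective = 0,
                true_atoms = network$atoms[0, ]))
  }
  s <- atom_scores(network, weights, extra_scores)
  cw <- clause_weights(network, weights)
  x <- rep(NA, n)

  # atoms untouched by any clause are decided by their unit score
  in_clause <- rep(FALSE, n)
  for (cl in network$clauses) in_clause[c(cl$neg, cl$pos)] <- TRUE
  x[!in_clause] <- s[!in_clause] > 0

  # connected components over clause-sharing atoms
  if (any(in_clause)) {
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
    for (cl in network$clauses) {
      ids <- c(cl$neg, cl$pos)
      r <- find(ids[1])
      for (b in ids[-1]) { rb <- find(b); if (rb != r) parent[rb] <- r }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp[in_clause])) {
      members <- which(comp == cid & in_clause)
      sol <- solve_component(network, members, s, cw)
      if (is.null(sol)) {
        abort(paste0("infeasible hard constraints (component containing atom ",
                     network$atoms$name[members[1]], ")"))
      }
      x[members] <- sol
    }
  }
  obj <- assignment_objective(network, weights, x, extra_scores)
  names(x) <- network$atoms$name
  list(assignment = x, objective = obj, true_atoms = network$atoms[x, ])
}

# branch and bound over one component; returns logical assignment for
# `members` (in their order) or NULL if hard constraints are infeasible
solve_component <- function(network, members, s, cw) {
  m <- length(members)
  loc <- integer(max(members))
  loc[members] <- seq_len(m)
  cls <- list()
  for (k in seq_along(network$clauses)) {
    cl <- network$clauses[[k]]
    if (any(c(cl$neg, cl$pos) %in% members)) {
      cls[[length(cls) + 1]] <- list(neg = loc[cl$neg], pos = loc[cl$pos],
                                     w = cw[k])
    }
  }
  sl <- s[members]
  nc <- length(cls)
  # branch order: high-degree atoms first (event-style atoms propagate most)
  deg <- rep(0L, m)
  for (cl in cls) deg[c(cl$neg, cl$pos)] <- deg[c(cl$neg, cl$pos)] + 1L
  ord <- order(-deg, -abs(sl))

  best <- new.env(parent = emptyenv())
  best$obj <- -Inf
  best$x <- NULL

  clause_state <- function(x) {
    sat <- logical(nc); fal <- logical(nc)
    for (k in seq_len(nc)) {
      cl <- cls[[k]]
      lp <- x[cl$pos]; ln <- x[cl$neg]
      sat[k] <- any(lp %in% TRUE) || any(ln %in% FALSE)
      fal[k] <- !sat[k] && !anyNA(lp) && !anyNA(ln)
    }
    list(sat = sat, fal = fal)
  }

  evaluate <- function(x) {
    st <- clause_state(x)
    obj <- sum(sl[x])
    for (k in seq_len(nc)) {
      if (st$fal[k] && is.infinite(cls[[k]]$w)) return()
      if (st$sat[k] && is.finite(cls[[k]]$w)) obj <- obj + cls[[k]]$w
    }
    if (is.null(best$x) || better_assignment(obj, x, best$obj, best$x)) {
      best$obj <- obj
      best$x <- x
    }
  }

  recurse <- function(x) {
    # hard-clause unit propagation (satisfaction checked on the live
    # assignment, since a force earlier in the sweep can satisfy a clause)
    repeat {
      forced <- FALSE
      for (k in seq_len(nc)) {
        cl <- cls[[k]]
        if (!is.infinite(cl$w)) next
        lp <- x[cl$pos]; ln <- x[cl$neg]
        if (any(lp %in% TRUE) || any(ln %in% FALSE)) next  # satisfied
        if (!anyNA(lp) && !anyNA(ln)) return()             # violated
        un_pos <- cl$pos[is.na(lp)]
        un_neg <- cl$neg[is.na(ln)]
        if (length(un_pos) + length(un_neg) == 1) {
          if (length(un_pos) == 1) x[un_pos] <- TRUE else x[un_neg] <- FALSE
          forced <- TRUE
        }
      }
      if (!forced) break
    }
    st <- clause_state(x)
    und <- which(is.na(x))
    # admissible bound
    bound <- sum(sl[which(x %in% TRUE)]) + sum(pmax(sl[und], 0))
    for (k in seq_len(nc)) {
      w <- cls[[k]]$w
      if (is.infinite(w)) next
      if (st$sat[k]) bound <- bound + w
      else if (!st$fal[k] && w > 0) bound <- bound + w
    }
    if (!is.null(best$x) && bound < best$obj - 1e-9) return()
    if (length(und) == 0) { evaluate(x); return() }
    # closure: every pending clause already satisfied -> greedy completion
    pending <- which(!st$sat & !st$fal)
    touches_und <- any(vapply(pending, function(k) {
      anyNA(x[c(cls[[k]]$neg, cls[[k]]$pos)])
    }, TRUE))
    if (length(pending) == 0 || !touches_und) {
      x[und] <- sl[und] > 0
      evaluate(x)
      return()
    }
    b <- ord[which(ord %in% und)[1]]
    x[b] <- FALSE; recurse(x)
    x[b] <- TRUE; recurse(x)
  }
  recurse(rep(NA, m))
  best$x
}

#' Exhaustive MAP oracle
#'
#' Enumerates all `2^n` assignments of a small network and returns the exact
#' optimum under the same tie-break as [map_infer()] (fewer true atoms, then
#' lexicographic atom order). Intended as an independent test oracle.
#'
#' @inheritParams map_infer
#' @param max_atoms Refuse networks larger than this (default 20).
#' @return Same shape as [map_infer()].
#' @export
brute_force_map <- function(network, weights, extra_scores = NULL,
                            max_atoms = 20L) {
  n <- network$n
  if (n > max_atoms) abort(paste0("network too large for enumeration (", n,
                                  " > ", max_atoms, " atoms)"))
  if (n == 0) {
    return(list(assignment = logical(), objective = 0,
                true_atoms = network$atoms[0, ]))
  }
  best_obj <- -Inf; best_x <- NULL
  for (k in 0:(2^n - 1)) {
    x <- as.logical(bitwAnd(bitwShiftR(k, 0:(n - 1)), 1L))
    obj <- assignment_objective(network, weights, x, extra_scores)
    if (is.infinite(obj)) next
    if (is.null(best_x) || better_assignment(obj, x, best_obj, best_x)) {
      best_obj <- obj; best_x <- x
    }
  }
  if (is.null(best_x)) abort("infeasible hard constraints")
  names(best_x) <- network$atoms$name
  list(assignment = best_x, objective = best_obj,
       true_atoms = network$atoms[best_x, ])
}

# feature counts of an assignment: local keys of true atoms + keys of
# satisfied soft clauses, as a named count vector
assignment_features <- function(network, x) {
  keys <- unlist(network$local[which(x)], use.names = FALSE)
  for (cl in network$clauses) {
    if (isTRUE(cl$hard)) next
    if (any(x[cl$pos]) || any(!x[cl$neg])) keys <- c(keys, cl$key)
  }
  if (length(keys) == 0) return(numeric())
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

check_gold_feasible <- function(instances) {
  for (idx in seq_along(instances)) {
    inst <- instances[[idx]]
    for (cl in inst$network$clauses) {
      if (!isTRUE(cl$hard)) next
      if (!(any(inst$gold[cl$pos]) || any(!inst$gold[cl$neg]))) {
        abort(paste0("gold assignment violates a hard constraint in instance ",
                     idx))
      }
    }
  }
}

#' Online max-margin weight learning
#'
#' Learns the weights of soft formulae by averaged passive-aggressive
#' updates: for each training instance, decode with the current weights under
#' a loss-augmented objective (weighted Hamming loss over hidden atoms, role
#' atoms counted double since the role predicate is the primary target); when
#' the decode differs from gold, step the weights toward the gold feature
#' counts with the margin-scaled, clipped passive-aggressive step size.
#' Weights are averaged over all updates, and the instance order is a
#' deterministic permutation per epoch given the seed.
#'
#' @param instances List of `list(network =, gold =)` pairs; `gold` is a
#'   logical assignment that must satisfy every hard clause.
#' @param epochs Number of passes over the data.
#' @param seed Integer seed controlling instance order.
#' @param aggressiveness Clip constant `C` of the passive-aggressive step.
#' @param loss_weight Named vector of per-predicate Hamming loss weights;
#'   predicates absent default to 1.
#' @return An `mln_weights` object (named numeric vector of learned weights,
#'   with update statistics attached).
#' @export
mln_learn <- function(instances, epochs = 3L, seed = 1L, aggressiveness = 1,
                      loss_weight = c(role = 2)) {
  check_gold_feasible(instances)
  w <- new.env(parent = emptyenv())
  wsum <- new.env(parent = emptyenv())
  t_step <- 0L
  n_updates <- 0L
  add <- function(env, keys, vals) {
    for (k in seq_along(keys)) {
      env[[keys[k]]] <- (env[[keys[k]]] %||% 0) + vals[k]
    }
  }
  loss_of <- function(network) {
    lw <- loss_weight[network$atoms$pred]
    lw[is.na(lw)] <- 1
    unname(lw)
  }
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(instances))
    for (ii in ord) {
      inst <- instances[[ii]]
      t_step <- t_step + 1L
      lw <- loss_of(inst$network)
      # loss-augmented decode: + lw for gold-false atoms set true,
      # + lw for gold-true atoms set false (constant dropped)
      extra <- ifelse(inst$gold, -lw, lw)
      pred <- map_infer(inst$network, w, extra_scores = extra)$assignment
      if (all(pred == inst$gold)) next
      phi_g <- assignment_features(inst$network, inst$gold)
      phi_p <- assignment_features(inst$network, pred)
      keys <- union(names(phi_g), names(phi_p))
      delta <- (phi_g[keys] %0% 0) - (phi_p[keys] %0% 0)
      names(delta) <- keys
      delta <- delta[delta != 0]
      loss <- sum(lw[pred != inst$gold])
      sc_g <- sum(wget(w, names(delta)) * delta)
      margin <- loss - sc_g  # score(pred)+loss - score(gold), via delta
      if (margin <= 0 || length(delta) == 0) next
      tau <- min(aggressiveness, margin / sum(delta^2))
      add(w, names(delta), tau * delta)
      add(wsum, names(delta), t_step * tau * delta)
      n_updates <- n_updates + 1L
    }
  }
  keys <- ls(w)
  raw <- vapply(keys, function(k) w[[k]], numeric(1))
  avg <- raw
  if (t_step > 0 && length(keys) > 0) {
    u <- vapply(keys, function(k) wsum[[k]] %||% 0, numeric(1))
    avg <- raw - u / (t_step + 1)
  }
  structure(avg, class = "mln_weights", raw = raw, n_updates = n_updates,
            epochs = epochs, seed = seed)
}

`%0%` <- function(a, b) { a[is.na(a)] <- b; a }

#' @export
print.mln_weights <- function(x, ...) {
  cat("<mln_weights> ", length(x), " weights, ",
      attr(x, "n_updates"), " updates over ", attr(x, "epochs"),
      " epoch(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mln_weights <- function(x, ...) {
  tibble(term = names(x), estimate = as.numeric(x)) %>%
    arrange(dplyr::desc(abs(.data$estimate)))
}

#' @export
glance.mln_weights <- function(x, ...) {
  tibble(n_weights = length(x), n_updates = attr(x, "n_updates"),
         epochs = attr(x, "epochs"))
}
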