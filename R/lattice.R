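#' Witness pool of known pathways
#'
#' A bounded FIFO collection of pathway supports found during previous LP
#' calls.  Every stored support is the support of an actual steady-state
#' flux vector of the *unperturbed* network and hence a lattice element;
#' under a knockout set `K`, the union of all stored supports disjoint
#' from `K` is a free lower bound for the maximal element, which saves LP
#' calls ("warm starts").  Witnesses never change results, only LP counts.
#'
#' @param capacity maximum number of stored supports (default 10000);
#'   beyond it the oldest witness is evicted first.
#' @return An environment of class `witness_pool`.
#' @export
witness_pool <- function(capacity = 10000L) {
  if (capacity < 1) stop("capacity must be at least 1")
  pool <- new.env(parent = emptyenv())
  pool$capacity <- as.integer(capacity)
  pool$supports <- list()
  class(pool) <- "witness_pool"
  pool
}

#' @export
print.witness_pool <- function(x, ...) {
  cat("<witness_pool> ", length(x$supports), " / ", x$capacity,
      " witnesses\n", sep = "")
  invisible(x)
}

#' Number of witnesses currently stored
#' @param pool a [witness_pool()].
#' @return integer.
#' @export
pool_size <- function(pool) length(pool$supports)

pool_add <- function(pool, support) {
  if (is.null(pool)) return(invisible(NULL))
  if (length(pool$supports) >= pool$capacity) {
    pool$supports <- pool$supports[-1L]  # FIFO eviction
  }
  pool$supports <- c(pool$supports, list(support))
  invisible(pool)
}

pool_lower_bound <- function(pool, knockouts) {
  if (is.null(pool) || !length(pool$supports)) return(character())
  ok <- vapply(pool$supports, function(s) !any(s %in% knockouts), logical(1))
  if (!any(ok)) return(character())
  sort_ids(unlist(pool$supports[ok], use.names = FALSE))
}

#' Maximal lattice element under a knockout set
#'
#' Computes the set of reactions that remain unblocked after knocking out
#' the reactions in `knockouts`, i.e. the maximal element of the
#' sub-lattice of supports disjoint from the knockout set.  The algorithm
#' maintains a lower bound `lb` (union of known pathway supports avoiding
#' the knockouts) and an upper bound `ub` (reactions not yet proven
#' blocked) and calls [find_path()] for targets in `ub \ lb` in
#' deterministic (sorted) order: each call either enlarges `lb` by a whole
#' pathway support or removes the target from `ub`, until `lb = ub`.
#'
#' @param net a [metabolic_network()].
#' @param knockouts character vector of reaction ids (may be empty).
#' @param pool optional [witness_pool()]; successful pathways are added to
#'   it and its compatible witnesses seed the lower bound.
#' @param config an [lp_config()].
#' @param known_unblocked optional character vector: the unblocked set of
#'   the unperturbed network, if already known; used to tighten the
#'   initial upper bound (results are unchanged).
#' @return An object of class `maximal_element`: list with `knockouts`,
#'   `unblocked` (sorted reaction ids) and `lp_calls`.
#' @export
max_element <- function(net, knockouts = character(), pool = NULL,
                        config = lp_config(), known_unblocked = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  knockouts <- sort_ids(knockouts)
  check_reaction_ids(net, knockouts, "knockout set")
  ub <- setdiff(net$reactions, knockouts)
  if (!is.null(known_unblocked)) ub <- intersect(ub, known_unblocked)
  ub <- sort_ids(ub)
  lb <- intersect(pool_lower_bound(pool, knockouts), ub)

  res <- with_lp_counter({
    repeat {
      todo <- setdiff(ub, lb)
      if (!length(todo)) break
      t <- todo[1L]
      p <- find_path(net, t, knockouts, config)
      if (is.null(p)) {
        ub <- setdiff(ub, t)
      } else {
        lb <- sort_ids(c(lb, p$support))
        pool_add(pool, p$support)
      }
    }
    ub
  })
  structure(list(knockouts = knockouts, unblocked = res$value,
                 lp_calls = res$lp_calls),
            class = "maximal_element")
}

#' @export
print.maximal_element <- function(x, ...) {
  cat("<maximal_element> knockouts {", paste(x$knockouts, collapse = ", "),
      "}: ", length(x$unblocked), " unblocked (", x$lp_calls,
      " LP calls)\n", sep = "")
  invisible(x)
}

#' Flux coupling analysis
#'
#' Computes the unblocked set `1_L`, then for each unblocked reaction `r`
#' the maximal element after the single knockout `{r}`, from which all
#' directional couplings (`r -> s` iff `s` is blocked by knocking out `r`)
#' and the partial-coupling equivalence classes (mutual coupling) are
#' derived.  Results for partially coupled reactions coincide, so the
#' table stores the knockout results per class representative (the
#' lexicographically smallest member) and answers queries for classmates
#' through the class map.
#'
#' @param net a [metabolic_network()].
#' @param config an [lp_config()].
#' @param pool a [witness_pool()] shared across all knockout computations
#'   and returned for reuse by the double-knockout stage; pass `NULL` to
#'   disable witness reuse.
#' @return An object of class `coupling_table`: list with
#'   `unblocked`, `blocked`, `classes` (named list, representative ->
#'   sorted members), `representatives`, `class_map` (named character:
#'   reaction -> its representative), `max_without` (named list,
#'   representative -> unblocked set after its single knockout),
#'   `lp_calls` (per stage) and `pool`.
#' @export
fca <- function(net, config = lp_config(), pool = witness_pool()) {
  stopifnot(inherits(net, "metabolic_network"))
  full <- max_element(net, character(), pool, config)
  unblocked <- full$unblocked
  blocked <- sort_ids(setdiff(net$reactions, unblocked))

  mw <- list()
  cpl_res <- with_lp_counter({
    for (r in unblocked) {
      mw[[r]] <- max_element(net, r, pool, config,
                             known_unblocked = unblocked)$unblocked
    }
    NULL
  })

  # r -> s  iff  s not in 1_{L \ {r}};  partial coupling = mutual
  class_map <- stats::setNames(character(length(unblocked)), unblocked)
  for (r in unblocked) {
    if (nzchar(class_map[[r]])) next
    class_map[[r]] <- r
    mates <- setdiff(setdiff(unblocked, mw[[r]]), r)
    for (s in mates) {
      if (!nzchar(class_map[[s]]) && !(r %in% mw[[s]])) class_map[[s]] <- r
    }
  }
  reps <- sort_ids(unique(class_map))
  classes <- lapply(stats::setNames(reps, reps),
                    function(rep) sort_ids(names(class_map)[class_map == rep]))

  structure(
    list(unblocked = unblocked, blocked = blocked,
         reactions = net$reactions,
         classes = classes, representatives = reps, class_map = class_map,
         max_without = mw[reps],
         lp_calls = list(blocked = full$lp_calls,
                         couplings = cpl_res$lp_calls),
         config = config, pool = pool),
    class = "coupling_table"
  )
}

#' @export
print.coupling_table <- function(x, ...) {
  cat("<coupling_table> ", length(x$unblocked), " unblocked / ",
      length(x$blocked), " blocked reactions; ",
      length(x$representatives), " partial-coupling classes\n",
      "LP calls: ", x$lp_calls$blocked, " (blocked) + ",
      x$lp_calls$couplings, " (couplings)\n", sep = "")
  invisible(x)
}

#' Unblocked set after a single knockout, via the class table
#' @param table a [fca()] result.
#' @param r an unblocked reaction id.
#' @return sorted character vector `1_{L \ {r}}`.
#' @export
max_without <- function(table, r) {
  stopifnot(inherits(table, "coupling_table"))
  if (!r %in% table$unblocked) stop("'", r, "' is not an unblocked reaction")
  table$max_without[[table$class_map[[r]]]]
}

#' Directional coupling query
#'
#' `r -> s` holds iff every steady-state pathway avoiding `r` also avoids
#' `s`, i.e. `s` is blocked by the knockout of `r`.  Partially coupled
#' reactions (same class) are directionally coupled in both directions.
#'
#' @param table a [fca()] result.
#' @param r,s distinct unblocked reaction ids.
#' @return logical scalar.
#' @export
is_coupled <- function(table, r, s) {
  stopifnot(inherits(table, "coupling_table"))
  if (identical(r, s)) return(FALSE)
  if (!all(c(r, s) %in% table$unblocked)) return(FALSE)
  !(s %in% max_without(table, r))
}

#' All directional couplings as a data frame
#'
#' @param table a [fca()] result.
#' @param level `"reaction"` (default) lists every ordered reaction pair
#'   `r -> s`; `"class"` lists ordered representative pairs only.
#' @return data frame with columns `from`, `to`, `relation`
#'   (`"partial"` for mutually coupled pairs, `"directional"` otherwise;
#'   partial pairs are listed once with `from < to`).
#' @export
coupling_pairs <- function(table, level = c("reaction", "class")) {
  level <- match.arg(level)
  ids <- if (level == "class") table$representatives else table$unblocked
  out <- list()
  for (r in ids) {
    blocked_by_r <- setdiff(setdiff(ids, max_without(table, r)), r)
    for (s in blocked_by_r) {
      mutual <- !(r %in% max_without(table, s))
      if (mutual && r > s) next  # partial pair already listed as s,r
      out[[length(out) + 1L]] <- data.frame(
        from = r, to = s,
        relation = if (mutual) "partial" else "directional",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(from = character(), to = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Partition of the unblocked reactions into partial-coupling classes
#'
#' @param table a [fca()] result.
#' @return An object of class `class_partition`: list with `classes`
#'   (named list representative -> members), `representatives` and
#'   `class_map`.
#' @export
partial_classes <- function(table) {
  stopifnot(inherits(table, "coupling_table"))
  structure(list(classes = table$classes,
                 representatives = table$representatives,
                 class_map = table$class_map),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  cat("<class_partition> ", length(x$representatives), " classes over ",
      length(x$class_map), " unblocked reactions\n", sep = "")
  invisible(x)
}
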