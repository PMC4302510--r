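#' Candidate knockout pairs (order-1 filter)
#'
#' Returns all unordered pairs of class representatives that are not
#' directionally coupled in either direction.  A pair with `r -> s` is
#' redundant: knocking out `{r, s}` has the same effect as knocking out
#' `r` alone, so only uncoupled pairs can carry joint effects.
#'
#' @param partition a [partial_classes()] result.
#' @param table the [fca()] result the partition came from.
#' @return An object of class `candidate_set` with `d = 2`, `m = 1` and
#'   `members`, a list of sorted id pairs in deterministic order.
#' @export
candidate_pairs <- function(partition, table) {
  stopifnot(inherits(partition, "class_partition"),
            inherits(table, "coupling_table"))
  reps <- partition$representatives
  members <- list()
  if (length(reps) >= 2) {
    for (i in seq_len(length(reps) - 1L)) {
      for (j in seq.int(i + 1L, length(reps))) {
        r <- reps[i]; s <- reps[j]
        if (!is_coupled(table, r, s) && !is_coupled(table, s, r)) {
          members[[length(members) + 1L]] <- c(r, s)
        }
      }
    }
  }
  structure(list(d = 2L, m = 1L, members = members), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> d = ", x$d, ", m = ", x$m, ": ", length(x$members),
      " candidate sets\n", sep = "")
  invisible(x)
}

#' Full double-knockout (joint coupling) analysis
#'
#' Runs flux coupling analysis, partitions the unblocked reactions into
#' partial-coupling classes, and for every candidate pair of uncoupled
#' class representatives \{r, s\} computes the maximal element after the
#' double knockout.  The jointly coupled reactions are
#' \deqn{T_{rs} = (1_{L\perp\{r\}} \cap 1_{L\perp\{s\}}) \setminus
#'   1_{L\perp\{r,s\}},}
#' i.e. the reactions blocked by the pair but by neither single knockout.
#' Records with empty targets are retained (flagged
#' `has_joint_effect = FALSE`) so that summary ratios have their
#' denominator.
#'
#' Two degraded variants support benchmarking the algorithmic devices:
#' with `use_representatives = FALSE` the loop runs over all uncoupled
#' pairs of unblocked *reactions* instead of class representatives
#' (variant A); with `use_witnesses = FALSE` additionally no witness pool
#' is kept (variant B).  Both variants change LP counts, never the
#' class-mapped joint couplings.
#'
#' @param net a [metabolic_network()].
#' @param config an [lp_config()].
#' @param use_representatives iterate over class representatives (default)
#'   or over all unblocked reactions.
#' @param use_witnesses share a witness pool across all LP computations.
#' @param pool_capacity capacity of the shared pool.
#' @return An object of class `dko_analysis`: list with `records` (one
#'   `joint_coupling_record` per analysed pair: `pair`, `targets`,
#'   `unblocked_after`, `has_joint_effect`), `table`, `partition`,
#'   `candidates`, `lp_calls` (per stage) and the variant flags.
#' @export
double_knockout_analysis <- function(net, config = lp_config(),
                                     use_representatives = TRUE,
                                     use_witnesses = TRUE,
                                     pool_capacity = 10000L) {
  stopifnot(inherits(net, "metabolic_network"))
  pool <- if (use_witnesses) witness_pool(pool_capacity) else NULL
  table <- fca(net, config, pool)
  partition <- partial_classes(table)

  if (use_representatives) {
    candidates <- candidate_pairs(partition, table)
  } else {
    ub <- table$unblocked
    members <- list()
    if (length(ub) >= 2) {
      for (i in seq_len(length(ub) - 1L)) {
        for (j in seq.int(i + 1L, length(ub))) {
          r <- ub[i]; s <- ub[j]
          if (!is_coupled(table, r, s) && !is_coupled(table, s, r)) {
            members[[length(members) + 1L]] <- c(r, s)
          }
        }
      }
    }
    candidates <- structure(list(d = 2L, m = 1L, members = members),
                            class = "candidate_set")
  }

  records <- vector("list", length(candidates$members))
  dko_res <- with_lp_counter({
    for (i in seq_along(candidates$members)) {
      pr <- candidates$members[[i]]
      r <- pr[1]; s <- pr[2]
      after <- max_element(net, c(r, s), pool, config,
                           known_unblocked = table$unblocked)$unblocked
      targets <- sort_ids(setdiff(
        intersect(max_without(table, r), max_without(table, s)), after))
      records[[i]] <- structure(
        list(pair = pr, targets = targets, unblocked_after = after,
             has_joint_effect = length(targets) > 0),
        class = "joint_coupling_record")
    }
    NULL
  })

  lp <- table$lp_calls
  lp$dko <- dko_res$lp_calls
  lp$total <- lp$blocked + lp$couplings + lp$dko
  structure(list(records = records, table = table, partition = partition,
                 candidates = candidates, lp_calls = lp,
                 use_representatives = use_representatives,
                 use_witnesses = use_witnesses),
            class = "dko_analysis")
}

#' @export
print.dko_analysis <- function(x, ...) {
  n_eff <- sum(vapply(x$records, `[[`, logical(1), "has_joint_effect"))
  cat("<dko_analysis> ", length(x$records), " candidate pairs, ", n_eff,
      " with joint effects\nLP calls: ",
      paste(names(x$lp_calls), unlist(x$lp_calls), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.joint_coupling_record <- function(x, ...) {
  cat("{", paste(x$pair, collapse = ", "), "} -> {",
      paste(x$targets, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# map a record to class level: representative pair -> set of target
# representatives (used to compare analysis variants)
record_class_key <- function(record, table) {
  reps <- sort_ids(table$class_map[record$pair])
  tgt <- sort_ids(unique(table$class_map[record$targets]))
  list(pair = reps, targets = tgt)
}

#' Class-level view of the joint couplings of an analysis
#'
#' Collapses the records of a [double_knockout_analysis()] to the level of
#' partial-coupling classes: each analysed pair is mapped to its pair of
#' class representatives and its targets to target-class representatives.
#' Variants of the analysis (with or without representatives/witnesses)
#' agree exactly on this view.
#'
#' @param dko a `dko_analysis`.
#' @param effective_only keep only records with joint effects.
#' @return data frame with columns `rep_a`, `rep_b`, `targets`
#'   (comma-separated target representatives), sorted by pair.
#' @export
class_level_couplings <- function(dko, effective_only = TRUE) {
  stopifnot(inherits(dko, "dko_analysis"))
  recs <- dko$records
  if (effective_only) {
    recs <- Filter(function(r) r$has_joint_effect, recs)
  }
  if (!length(recs)) {
    return(data.frame(rep_a = character(), rep_b = character(),
                      targets = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(recs, function(rec) {
    k <- record_class_key(rec, dko$table)
    data.frame(rep_a = k$pair[1], rep_b = k$pair[2],
               targets = paste(k$targets, collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$rep_a, df$rep_b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Candidate d-subsets of representatives (order-m filters)
#'
#' Generates all `d`-subsets of class representatives that violate no
#' coupling of order up to `m`: with `m = 1` no member pair is
#' directionally coupled; with `m = 2` additionally no pair inside the
#' subset is jointly coupled to a third member.  Higher-order joint
#' couplings would be needed for `m > 2`.
#'
#' @param d knockout cardinality (at most `max_d`).
#' @param m filter order, 1 or 2 (and `m < d`).
#' @param table a [fca()] result.
#' @param partition the matching [partial_classes()] partition.
#' @param joint a [double_knockout_analysis()] result; required for `m = 2`.
#' @param max_d safety cap on `d` (default 4).
#' @return A `candidate_set` with `members` a list of sorted id vectors.
#' @export
candidate_sets <- function(d, m, table, partition, joint = NULL,
                           max_d = 4L) {
  stopifnot(inherits(table, "coupling_table"),
            inherits(partition, "class_partition"))
  d <- as.integer(d); m <- as.integer(m)
  if (d < 2 || d > max_d) stop("d must be between 2 and ", max_d)
  if (m < 1 || m >= d) stop("m must be in {1, ..., d - 1}")
  if (m > 2) stop("filters of order m > 2 require joint couplings of ",
                  "order > 2, which are not computed")
  if (m >= 2 && is.null(joint)) {
    stop("m = 2 requires double-knockout data (argument 'joint')")
  }

  jmap <- list()
  if (m >= 2) {
    for (rec in joint$records) {
      if (rec$has_joint_effect) {
        jmap[[paste(rec$pair, collapse = "\r")]] <- rec$targets
      }
    }
  }

  reps <- partition$representatives
  members <- list()
  if (length(reps) >= d) {
    combs <- utils::combn(reps, d, simplify = FALSE)
    for (K in combs) {
      K <- sort_ids(K)
      ok <- TRUE
      for (i in seq_len(d - 1L)) {
        for (j in seq.int(i + 1L, d)) {
          if (is_coupled(table, K[i], K[j]) || is_coupled(table, K[j], K[i])) {
            ok <- FALSE; break
          }
        }
        if (!ok) break
      }
      if (ok && m >= 2) {
        prs <- utils::combn(K, 2L, simplify = FALSE)
        for (pr in prs) {
          tgt <- jmap[[paste(sort_ids(pr), collapse = "\r")]]
          if (!is.null(tgt) && any(setdiff(K, pr) %in% tgt)) {
            ok <- FALSE; break
          }
        }
      }
      if (ok) members[[length(members) + 1L]] <- K
    }
  }
  structure(list(d = d, m = m, members = members), class = "candidate_set")
}

#' Multiple-knockout analysis for a fixed knockout set
#'
#' Computes the maximal element after knocking out the (unblocked)
#' reactions in `K`, and optionally the reactions jointly coupled to `K`:
#' \deqn{T_K = \Big(\bigcap_{k \in K} 1_{L\perp(K\setminus\{k\})}\Big)
#'   \setminus 1_{L\perp K},}
#' the reactions blocked by `K` but by no proper subset.  For `|K| = 1`
#' the notion degenerates to directional coupling and the targets are the
#' reactions blocked by the single knockout (excluding `K` itself).
#'
#' @param net a [metabolic_network()].
#' @param K character vector of unblocked reaction ids, `|K| >= 1`.
#' @param config an [lp_config()].
#' @param pool optional shared [witness_pool()].
#' @param compute_targets also compute the jointly coupled reactions
#'   (requires one additional maximal-element computation per member).
#' @return list with `element` (a `maximal_element` for knockout `K`) and
#'   `targets` (sorted ids, or `NULL` if not requested).
#' @export
multi_knockout <- function(net, K, config = lp_config(),
                           pool = witness_pool(), compute_targets = TRUE) {
  stopifnot(inherits(net, "metabolic_network"))
  K <- sort_ids(K)
  if (!length(K)) stop("knockout set must contain at least one reaction")
  check_reaction_ids(net, K, "knockout set")
  full <- max_element(net, character(), pool, config)
  blocked_members <- setdiff(K, full$unblocked)
  if (length(blocked_members)) {
    stop("knockout set contains blocked reactions: ",
         paste(blocked_members, collapse = ", "))
  }
  element <- max_element(net, K, pool, config,
                         known_unblocked = full$unblocked)
  targets <- NULL
  if (compute_targets) {
    if (length(K) == 1L) {
      targets <- sort_ids(setdiff(full$unblocked,
                                  c(element$unblocked, K)))
    } else {
      subs <- lapply(K, function(k) {
        max_element(net, setdiff(K, k), pool, config,
                    known_unblocked = full$unblocked)$unblocked
      })
      targets <- sort_ids(setdiff(Reduce(intersect, subs),
                                  element$unblocked))
    }
  }
  list(element = element, targets = targets)
}
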