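#' Construct an enumerated support lattice from explicit elements
#'
#' Validates that the given family of reaction sets is a lattice: it must
#' contain the empty set and be closed under union (the union of two
#' pathways is again a pathway).  Useful for encoding abstract qualitative
#' models directly, e.g. when testing gene-coupling logic against a
#' hand-specified pathway family.
#'
#' @param elements list of character vectors (reaction sets); the empty
#'   set is added if absent.
#' @param reactions optional universe of reaction ids; defaults to the
#'   union of all elements.
#' @param close take the union-closure of `elements` instead of requiring
#'   closure (default `FALSE`).
#' @return An object of class `enumerated_lattice`: list with `elements`
#'   (each sorted, deduplicated, in deterministic order) and `reactions`.
#' @export
enumerated_lattice <- function(elements, reactions = NULL, close = FALSE) {
  elements <- lapply(elements, sort_ids)
  keys <- vapply(elements, paste, character(1), collapse = "\r")
  elements <- elements[!duplicated(keys)]
  if (!any(vapply(elements, length, integer(1)) == 0L)) {
    elements <- c(list(character()), elements)
  }
  if (close) {
    repeat {
      keys <- vapply(elements, paste, character(1), collapse = "\r")
      added <- FALSE
      for (i in seq_along(elements)) {
        for (j in seq_along(elements)) {
          u <- sort_ids(c(elements[[i]], elements[[j]]))
          k <- paste(u, collapse = "\r")
          if (!k %in% keys) {
            elements <- c(elements, list(u))
            keys <- c(keys, k)
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
  } else {
    keys <- vapply(elements, paste, character(1), collapse = "\r")
    for (i in seq_along(elements)) {
      for (j in seq_along(elements)) {
        u <- paste(sort_ids(c(elements[[i]], elements[[j]])), collapse = "\r")
        if (!u %in% keys) {
          stop("element family is not closed under union: ",
               "{", paste(elements[[i]], collapse = ","), "} ∪ {",
               paste(elements[[j]], collapse = ","), "}")
        }
      }
    }
  }
  if (is.null(reactions)) {
    reactions <- sort_ids(unlist(elements, use.names = FALSE))
  }
  ord <- order(vapply(elements, length, integer(1)),
               vapply(elements, paste, character(1), collapse = "\r"),
               method = "radix")
  structure(list(elements = elements[ord], reactions = sort_ids(reactions)),
            class = "enumerated_lattice")
}

#' @export
print.enumerated_lattice <- function(x, ...) {
  cat("<enumerated_lattice> ", length(x$elements), " elements over ",
      length(x$reactions), " reactions\n", sep = "")
  invisible(x)
}

#' Enumerate the full support lattice of a small network
#'
#' Exact, definition-level reference: for every subset `a` of the
#' reaction set, the maximal support achievable inside the sub-cone
#' `{v | v_i = 0 for i not in a}` is itself a lattice element, and every
#' lattice element arises this way (from `a` equal to itself).  The
#' enumeration therefore collects the maximal elements of all
#' `2^n` sub-cones, sharing a witness pool across subsets so each LP is
#' informative.  Intended as the test oracle for the LP/lattice
#' algorithms; exponential in the number of reactions.
#'
#' @param net a [metabolic_network()].
#' @param max_reactions refuse networks larger than this (default 12).
#' @param config an [lp_config()].
#' @return An [enumerated_lattice()] containing exactly the supports of
#'   steady-state flux vectors.
#' @export
enumerate_lattice <- function(net, max_reactions = 12L,
                              config = lp_config()) {
  stopifnot(inherits(net, "metabolic_network"))
  n <- length(net$reactions)
  if (n > max_reactions) {
    stop("network has ", n, " reactions; the brute-force oracle is capped ",
         "at ", max_reactions)
  }
  rxns <- sort_ids(net$reactions)
  pool <- witness_pool(2L^n + 1L)
  seen <- new.env(parent = emptyenv())
  elements <- list(character())
  assign("k", TRUE, envir = seen)
  for (mask in seq_len(2L^n - 1L)) {
    a <- rxns[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    me <- max_element(net, setdiff(rxns, a), pool, config)$unblocked
    key <- paste0("k", paste(me, collapse = "\r"))
    if (is.null(get0(key, envir = seen))) {
      assign(key, TRUE, envir = seen)
      elements <- c(elements, list(me))
    }
  }
  enumerated_lattice(elements, reactions = rxns)
}

#' Maximal element of an enumerated lattice under a knockout
#' @param lat an [enumerated_lattice()].
#' @param K character vector of knocked-out reaction ids.
#' @return sorted union of all lattice elements disjoint from `K`.
#' @export
oracle_max_without <- function(lat, K) {
  stopifnot(inherits(lat, "enumerated_lattice"))
  ok <- vapply(lat$elements, function(a) !any(a %in% K), logical(1))
  sort_ids(unlist(lat$elements[ok], use.names = FALSE))
}

#' Definition-level coupling analysis of an enumerated lattice
#'
#' Derives every coupling notion by exhaustive iteration over the lattice
#' elements, with no LP calls: blocked reactions (absent from every
#' element), directional couplings (`r -> s` iff every element avoiding
#' `r` avoids `s`), partial-coupling classes (mutual coupling) with
#' lexicographically smallest representatives, and the joint couplings of
#' every uncoupled representative pair evaluated directly from the
#' definition (`t` blocked whenever both pair members are absent, while
#' neither member alone couples to `t`).
#'
#' @param lat an [enumerated_lattice()].
#' @return An object of class `oracle_analysis`: list with `lattice`,
#'   `unblocked`, `blocked`, `coupling` (named list: `r` -> reactions
#'   directionally coupled to `r`, classmates included), `classes`,
#'   `representatives`, `class_map`, and `joint_records` (per uncoupled
#'   representative pair: `pair`, `targets`, `unblocked_after`,
#'   `has_joint_effect`).
#' @export
oracle_analysis <- function(lat) {
  stopifnot(inherits(lat, "enumerated_lattice"))
  unblocked <- sort_ids(unlist(lat$elements, use.names = FALSE))
  blocked <- sort_ids(setdiff(lat$reactions, unblocked))

  coupling <- list()
  for (r in unblocked) {
    avoid_r <- oracle_max_without(lat, r)
    coupling[[r]] <- sort_ids(setdiff(setdiff(unblocked, avoid_r), r))
  }

  class_map <- stats::setNames(character(length(unblocked)), unblocked)
  for (r in unblocked) {
    if (nzchar(class_map[[r]])) next
    class_map[[r]] <- r
    for (s in coupling[[r]]) {
      if (!nzchar(class_map[[s]]) && r %in% coupling[[s]]) {
        class_map[[s]] <- r
      }
    }
  }
  reps <- sort_ids(unique(class_map))
  classes <- lapply(stats::setNames(reps, reps),
                    function(rep) sort_ids(names(class_map)[class_map == rep]))

  joint_records <- list()
  if (length(reps) >= 2) {
    for (i in seq_len(length(reps) - 1L)) {
      for (j in seq.int(i + 1L, length(reps))) {
        r <- reps[i]; s <- reps[j]
        if (s %in% coupling[[r]] || r %in% coupling[[s]]) next
        after <- oracle_max_without(lat, c(r, s))
        cand <- setdiff(unblocked, c(r, s))
        targets <- sort_ids(Filter(function(t) {
          if (t %in% coupling[[r]] || t %in% coupling[[s]]) return(FALSE)
          !(t %in% after)
        }, cand))
        joint_records[[length(joint_records) + 1L]] <- structure(
          list(pair = c(r, s), targets = targets, unblocked_after = after,
               has_joint_effect = length(targets) > 0),
          class = "joint_coupling_record")
      }
    }
  }

  structure(list(lattice = lat, unblocked = unblocked, blocked = blocked,
                 coupling = coupling, classes = classes,
                 representatives = reps, class_map = class_map,
                 joint_records = joint_records),
            class = "oracle_analysis")
}

#' @export
print.oracle_analysis <- function(x, ...) {
  cat("<oracle_analysis> ", length(x$unblocked), " unblocked / ",
      length(x$blocked), " blocked; ", length(x$representatives),
      " classes; ", length(x$joint_records),
      " uncoupled representative pairs\n", sep = "")
  invisible(x)
}

#' Definition-level multiple-knockout answers from an enumerated lattice
#'
#' Evaluates joint coupling of a set `K` directly from its definition:
#' `t` is jointly coupled to `K` iff every lattice element disjoint from
#' `K` avoids `t` and no nonempty proper subset of `K` is already jointly
#' coupled to `t` (minimality is checked recursively).
#'
#' @param lat an [enumerated_lattice()].
#' @param K character vector of unblocked reaction ids.
#' @return list with `unblocked` (after knocking out `K`) and `targets`.
#' @export
oracle_multi_knockout <- function(lat, K) {
  stopifnot(inherits(lat, "enumerated_lattice"))
  K <- sort_ids(K)
  unblocked <- sort_ids(unlist(lat$elements, use.names = FALSE))
  after <- oracle_max_without(lat, K)
  is_jointly_coupled <- function(K, t) {
    if (t %in% K) return(FALSE)
    if (t %in% oracle_max_without(lat, K)) return(FALSE)
    if (length(K) > 1L) {
      subs <- unlist(lapply(seq_len(length(K) - 1L), function(sz) {
        utils::combn(K, sz, simplify = FALSE)
      }), recursive = FALSE)
      for (Kp in subs) {
        if (is_jointly_coupled(Kp, t)) return(FALSE)
      }
    }
    TRUE
  }
  targets <- sort_ids(Filter(function(t) is_jointly_coupled(K, t),
                             setdiff(unblocked, K)))
  list(unblocked = after, targets = targets)
}
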