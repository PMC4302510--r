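#' LP oracle configuration
#'
#' Tolerances and bounds for the feasibility oracle.  The flux cone is
#' scale-invariant, so the box bound `big_m` does not change which
#' supports are achievable; it only keeps the LPs bounded.  The decision
#' tolerance (is the target flux nonzero?) is deliberately looser than the
#' support-extraction tolerance: a spurious support member is harmless
#' (any feasible support is a lattice element) while a missed nonzero
#' target would misclassify a reaction as blocked.
#'
#' @param zero_tolerance entries with absolute flux at or below this value
#'   are treated as zero when extracting supports (default `1e-9`).
#' @param decision_tolerance minimum optimal `|v_target|` for a reaction to
#'   count as unblocked (default `1e-6`).
#' @param big_m box bound `M`: fluxes are constrained to `[-M, M]`
#'   (`[0, M]` for irreversible reactions); default 1000.
#' @param solver LP backend: `"bland"` (default; the package's dense
#'   simplex with Bland's anti-cycling rule, deterministic and
#'   single-threaded) or `"pracma"` (`pracma::linprog`).  Both solve the
#'   identical formulation; the alternative backend exists mainly for
#'   cross-checking.
#' @return A list of class `lp_config`.
#' @export
lp_config <- function(zero_tolerance = 1e-9, decision_tolerance = 1e-6,
                      big_m = 1000, solver = "bland") {
  if (!(zero_tolerance > 0 && zero_tolerance < 1)) {
    stop("zero_tolerance must be in (0, 1)")
  }
  if (!(decision_tolerance > 0 && decision_tolerance < 1)) {
    stop("decision_tolerance must be in (0, 1)")
  }
  if (big_m < 1) stop("big_m must be at least 1")
  solver <- match.arg(solver, c("bland", "pracma"))
  structure(list(zero_tolerance = zero_tolerance,
                 decision_tolerance = decision_tolerance,
                 big_m = big_m, solver = solver),
            class = "lp_config")
}

# Solve max/min v_target over {v | Sv = 0, v_Irr >= 0, v_K = 0, |v| <= M}.
# Reversible reactions are split into forward/backward parts; in a simplex
# vertex at most one of the two (linearly dependent) columns is basic, so
# supports read off the vertex are not inflated by cancelling pairs.
solve_cone_lp <- function(net, target, knockouts, maximize, config) {
  active <- setdiff(net$reactions, knockouts)
  rev <- !(active %in% net$irreversible)
  nv <- length(active) + sum(rev)
  # column layout: one column per active reaction, plus one extra negated
  # column per reversible active reaction (appended in order)
  S <- as.matrix(net$stoich[, active, drop = FALSE])
  Sx <- cbind(S, -S[, rev, drop = FALSE])
  keep_rows <- rowSums(abs(Sx)) > 0
  Sx <- Sx[keep_rows, , drop = FALSE]
  obj <- numeric(nv)
  ti <- match(target, active)
  sgn <- if (maximize) 1 else -1
  obj[ti] <- sgn
  if (rev[ti]) obj[length(active) + sum(rev[seq_len(ti)])] <- -sgn

  if (config$solver == "pracma") {
    res <- tryCatch(
      pracma::linprog(cc = obj, A = diag(nv), b = rep(config$big_m, nv),
                      Aeq = if (nrow(Sx)) Sx else NULL,
                      beq = rep(0, nrow(Sx)), maximize = TRUE,
                      maxiter = 200L * (nv + nrow(Sx) + 10L)),
      error = function(e) NULL)
    if (is.null(res) || res$errno != 1) {
      stop("LP oracle failure (pracma backend) for target '", target,
           "' with ", length(knockouts), " knockouts")
    }
    x <- as.numeric(res$x)
  } else {
    res <- solve_bounded_lp(obj, Sx, config$big_m)
    x <- res$x
  }
  v <- x[seq_along(active)]
  v[rev] <- v[rev] - x[length(active) + seq_len(sum(rev))]
  flux <- stats::setNames(numeric(length(net$reactions)), net$reactions)
  flux[active] <- v
  list(value = sgn * sum(obj * x), flux = flux)
}

#' Find a steady-state pathway through a target reaction
#'
#' The FindPath primitive: given a target reaction and a knockout set `K`,
#' search for a flux vector `v` with `Sv = 0`, `v_r >= 0` for irreversible
#' `r`, `v_k = 0` for every `k` in `K`, and `v_target != 0`.  Realized by
#' solving `max v_target` (and, for a reversible target whose maximum is
#' zero, `min v_target`) over the box-truncated cone.
#'
#' @param net a [metabolic_network()].
#' @param target reaction id; must not be in `knockouts`.
#' @param knockouts character vector of reaction ids forced to zero flux.
#' @param config an [lp_config()].
#' @return A `pathway` object (list with `support`, a sorted character
#'   vector of active reactions, and `values`, the witness flux vector), or
#'   `NULL` if the target is blocked under the knockout.
#' @export
find_path <- function(net, target, knockouts = character(),
                      config = lp_config()) {
  stopifnot(inherits(net, "metabolic_network"))
  check_reaction_ids(net, target, "target")
  check_reaction_ids(net, knockouts, "knockout set")
  if (target %in% knockouts) {
    stop("target '", target, "' is in the knockout set")
  }
  cnt <- lp_counter_peek()
  sol <- solve_cone_lp(net, target, knockouts, maximize = TRUE, config)
  if (!is.null(cnt)) cnt$n <- cnt$n + 1L
  if (sol$value <= config$decision_tolerance && is_reversible(net, target)) {
    sol <- solve_cone_lp(net, target, knockouts, maximize = FALSE, config)
    if (!is.null(cnt)) cnt$n <- cnt$n + 1L
    if (sol$value >= -config$decision_tolerance) return(NULL)
  } else if (sol$value <= config$decision_tolerance) {
    return(NULL)
  }
  support <- sort_ids(names(sol$flux)[abs(sol$flux) > config$zero_tolerance])
  structure(list(support = support, values = sol$flux), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> support {", paste(x$support, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Scoped LP call counter: max_element and friends install a counter so
# that every solver invocation (including both phases of a two-sided
# find_path) is counted exactly once.
lp_counter_env <- new.env(parent = emptyenv())
lp_counter_env$stack <- list()

lp_counter_peek <- function() {
  n <- length(lp_counter_env$stack)
  if (n) lp_counter_env$stack[[n]] else NULL
}

with_lp_counter <- function(expr) {
  cnt <- new.env(parent = emptyenv())
  cnt$n <- 0L
  lp_counter_env$stack <- c(lp_counter_env$stack, list(cnt))
  on.exit({
    k <- length(lp_counter_env$stack)
    lp_counter_env$stack <- lp_counter_env$stack[-k]
    outer <- lp_counter_peek()
    if (!is.null(outer)) outer$n <- outer$n + cnt$n
  })
  val <- force(expr)
  list(value = val, lp_calls = cnt$n)
}

#' Check whether a reaction set is a support-lattice element
#'
#' A set `a` belongs to the support lattice `L` iff the maximal support
#' achievable inside the sub-cone `{v | v_i = 0 for all i not in a}`
#' equals `a` itself.  The maximal achievable support is computed with
#' [max_element()] under the complementary knockout set.
#'
#' @param net a [metabolic_network()].
#' @param support character vector of reaction ids.
#' @param config an [lp_config()].
#' @return `TRUE` iff `support` is the support of some steady-state flux
#'   vector.  The empty set is always a lattice element (`v = 0`).
#' @export
verify_support <- function(net, support, config = lp_config()) {
  stopifnot(inherits(net, "metabolic_network"))
  check_reaction_ids(net, support, "support")
  support <- sort_ids(support)
  if (!length(support)) return(TRUE)
  me <- max_element(net, setdiff(net$reactions, support), config = config)
  setequal(me$unblocked, support)
}
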