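#' Reactions associated to a gene knockout
#'
#' The association map \eqn{\alpha : 2^G \to 2^R}: a reaction belongs to
#' \eqn{K_\Gamma} iff it carries a GPR rule and the rule evaluates to
#' `FALSE` under the assignment that switches off exactly the genes in
#' `genes`.  Reactions without a GPR rule are never removable by gene
#' knockouts.  Because rules may contain negation, the map is not
#' necessarily monotone: a reaction can be associated to a single-gene
#' knockout but not to a larger one (e.g. rule `g1 or not g2`).
#'
#' @param net a [metabolic_network()] with GPR rules.
#' @param genes character vector of gene ids to switch off (may be empty).
#' @return sorted character vector of associated reaction ids.
#' @export
associated_reactions <- function(net, genes) {
  stopifnot(inherits(net, "metabolic_network"))
  genes <- sort_ids(genes)
  bad <- setdiff(genes, net$genes)
  if (length(bad)) {
    stop("unknown gene ids: ", paste(bad, collapse = ", "))
  }
  if (!length(net$gpr)) return(character())
  assignment <- stats::setNames(!(net$genes %in% genes), net$genes)
  off <- vapply(net$gpr, function(rule) !eval_gene_rule(rule, assignment),
                logical(1))
  sort_ids(names(net$gpr)[off])
}

#' Reactions coupled to a gene knockout
#'
#' A reaction `r` is coupled to the gene set `Gamma` iff `r` is absent
#' from the maximal lattice element after knocking out the associated
#' reactions \eqn{K_\Gamma}.  Reactions of \eqn{K_\Gamma} that are already
#' blocked in the unperturbed network are dropped before the lattice
#' computation (they are absent from every lattice element anyway).
#' Unlike joint reaction coupling, gene coupling does *not* exclude
#' reactions already coupled to smaller gene sets: with negated rules a
#' reaction may be associated to a subset of `Gamma` but not to `Gamma`
#' itself, so each gene set is judged on its own associated reactions.
#'
#' @param net a [metabolic_network()].
#' @param genes character vector of gene ids.
#' @param pool optional shared [witness_pool()].
#' @param config an [lp_config()].
#' @param unblocked the unblocked set `1_L` if already known (saves its
#'   recomputation).
#' @return An object of class `gene_knockout_record`: list with `genes`,
#'   `associated` (\eqn{K_\Gamma}), `coupled`
#'   (\eqn{\{r \in 1_L \mid r \notin 1_{L\perp K_\Gamma}\}}) and
#'   `unblocked_after`.
#' @export
gene_coupling <- function(net, genes, pool = NULL, config = lp_config(),
                          unblocked = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(unblocked)) {
    unblocked <- max_element(net, character(), pool, config)$unblocked
  }
  associated <- associated_reactions(net, genes)
  K <- intersect(associated, unblocked)
  after <- if (length(K)) {
    max_element(net, K, pool, config, known_unblocked = unblocked)$unblocked
  } else {
    unblocked
  }
  structure(list(genes = sort_ids(genes), associated = associated,
                 coupled = sort_ids(setdiff(unblocked, after)),
                 unblocked_after = after),
            class = "gene_knockout_record")
}

#' @export
print.gene_knockout_record <- function(x, ...) {
  cat("{", paste(x$genes, collapse = ", "), "}: ", length(x$associated),
      " associated, ", length(x$coupled), " coupled reactions\n", sep = "")
  invisible(x)
}

#' All single or double gene knockouts
#'
#' Iterates over all genes (`order = 1`) or all unordered gene pairs
#' (`order = 2`) in deterministic (sorted) order, sharing one witness
#' pool.  Unlike reaction knockouts, gene knockouts admit no
#' representative compression (distinct genes are distinct experiments);
#' instead, results are memoized by the associated reaction set
#' \eqn{K_\Gamma}: gene sets inducing identical reaction knockouts are
#' solved once.  Genes absent from every rule are still iterated and
#' produce empty records, so the number of records is exactly `|G|` resp.
#' `|G| (|G| - 1) / 2`.
#'
#' @param net a [metabolic_network()] with GPR rules.
#' @param order 1 (single knockouts) or 2 (all gene pairs).
#' @param config an [lp_config()].
#' @param pool a shared [witness_pool()].
#' @return list of [gene_coupling()] records, with attributes
#'   `n_lattice_computations` (distinct associated sets solved) and
#'   `lp_calls`.
#' @export
all_gene_knockouts <- function(net, order = 1L, config = lp_config(),
                               pool = witness_pool()) {
  stopifnot(inherits(net, "metabolic_network"))
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  genes <- sort_ids(net$genes)
  sets <- if (order == 1L) {
    lapply(genes, identity)
  } else if (length(genes) >= 2L) {
    utils::combn(genes, 2L, simplify = FALSE)
  } else {
    list()
  }

  memo <- new.env(parent = emptyenv())
  n_solved <- 0L
  res <- with_lp_counter({
    unblocked <- max_element(net, character(), pool, config)$unblocked
    records <- vector("list", length(sets))
    for (i in seq_along(sets)) {
      gs <- sets[[i]]
      associated <- associated_reactions(net, gs)
      key <- paste0("k", paste(associated, collapse = "\r"))
      hit <- get0(key, envir = memo)
      if (is.null(hit)) {
        K <- intersect(associated, unblocked)
        after <- if (length(K)) {
          max_element(net, K, pool, config,
                      known_unblocked = unblocked)$unblocked
        } else {
          unblocked
        }
        hit <- list(coupled = sort_ids(setdiff(unblocked, after)),
                    after = after)
        assign(key, hit, envir = memo)
        n_solved <- n_solved + 1L
      }
      records[[i]] <- structure(
        list(genes = gs, associated = associated, coupled = hit$coupled,
             unblocked_after = hit$after),
        class = "gene_knockout_record")
    }
    records
  })
  structure(res$value, n_lattice_computations = n_solved,
            lp_calls = res$lp_calls)
}
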