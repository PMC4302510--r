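#' Construct a metabolic network
#'
#' A metabolic network is given by its stoichiometric matrix `S` (rows are
#' metabolites, columns are reactions), a set of irreversible reactions and,
#' optionally, gene-protein-reaction (GPR) rules.  All analyses in this
#' package work on the steady-state flux cone
#' \deqn{C = \{ v \mid S v = 0,\; v_r \ge 0 \ \forall r \in \mathrm{Irr} \},}
#' i.e. bounds beyond reaction orientation play no role (cone semantics).
#'
#' @param metabolites character vector of unique metabolite identifiers.
#' @param reactions character vector of unique reaction identifiers.
#' @param stoich numeric matrix (or `Matrix::sparseMatrix`) with
#'   `length(metabolites)` rows and `length(reactions)` columns.  Dimnames,
#'   if present, must agree with `metabolites` / `reactions`.
#' @param irreversible character vector, subset of `reactions`, whose flux is
#'   constrained to be non-negative.
#' @param genes character vector of gene identifiers (may be empty).
#' @param gpr named list mapping reaction ids to GPR rules; each entry is
#'   either a rule string (parsed with [parse_gene_rule()]) or a `gene_rule`
#'   object.  Reactions without an entry have no gene association and can
#'   never be removed by a gene knockout.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `metabolites`, `reactions`, `stoich` (a sparse `dgCMatrix`),
#'   `irreversible`, `genes`, `gpr`.
#' @seealso [example_network()], [random_network()], [load_network()]
#' @export
metabolic_network <- function(metabolites, reactions, stoich,
                              irreversible = character(),
                              genes = character(), gpr = list()) {
  metabolites <- as.character(metabolites)
  reactions <- as.character(reactions)
  if (anyDuplicated(metabolites)) {
    stop("duplicate metabolite identifiers: ",
         paste(unique(metabolites[duplicated(metabolites)]), collapse = ", "))
  }
  if (anyDuplicated(reactions)) {
    stop("duplicate reaction identifiers: ",
         paste(unique(reactions[duplicated(reactions)]), collapse = ", "))
  }
  S <- Matrix::Matrix(stoich, sparse = TRUE)
  if (nrow(S) != length(metabolites) || ncol(S) != length(reactions)) {
    stop("stoichiometric matrix must be ", length(metabolites), " x ",
         length(reactions), ", got ", nrow(S), " x ", ncol(S))
  }
  if (!is.null(rownames(S)) && !identical(rownames(S), metabolites)) {
    stop("row names of stoichiometric matrix disagree with metabolite ids")
  }
  if (!is.null(colnames(S)) && !identical(colnames(S), reactions)) {
    stop("column names of stoichiometric matrix disagree with reaction ids")
  }
  dimnames(S) <- list(metabolites, reactions)
  irreversible <- as.character(irreversible)
  bad <- setdiff(irreversible, reactions)
  if (length(bad)) {
    stop("irreversible set contains unknown reactions: ",
         paste(bad, collapse = ", "))
  }
  genes <- sort_ids(as.character(genes))
  if (length(gpr)) {
    if (is.null(names(gpr)) || any(!nzchar(names(gpr)))) {
      stop("gpr must be a named list keyed by reaction id")
    }
    bad <- setdiff(names(gpr), reactions)
    if (length(bad)) {
      stop("gpr rules reference unknown reactions: ", paste(bad, collapse = ", "))
    }
    gpr <- lapply(gpr, function(x) {
      if (inherits(x, "gene_rule")) x else parse_gene_rule(as.character(x))
    })
    used <- sort_ids(unlist(lapply(gpr, rule_genes), use.names = FALSE))
    undeclared <- setdiff(used, genes)
    if (length(undeclared)) {
      warning("GPR rules reference undeclared genes (declared on the fly): ",
              paste(undeclared, collapse = ", "))
      genes <- sort_ids(c(genes, undeclared))
    }
  }
  zero_cols <- reactions[Matrix::colSums(abs(S)) == 0]
  if (length(zero_cols)) {
    warning("reactions with all-zero stoichiometry (free exchanges): ",
            paste(zero_cols, collapse = ", "))
  }
  structure(
    list(metabolites = metabolites, reactions = reactions, stoich = S,
         irreversible = sort_ids(irreversible), genes = genes, gpr = gpr),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions (", length(x$irreversible),
      " irreversible), ", length(x$genes), " genes, ",
      length(x$gpr), " GPR rules\n", sep = "")
  invisible(x)
}

# locale-independent deterministic ordering for identifier vectors
sort_ids <- function(x) sort(unique(as.character(x)), method = "radix")

is_reversible <- function(net, r) !(r %in% net$irreversible)

check_reaction_ids <- function(net, ids, what = "reaction set") {
  bad <- setdiff(ids, net$reactions)
  if (length(bad)) {
    stop(what, " contains unknown reaction ids: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Six-reaction worked-example network
#'
#' A small network on metabolites A, B, C, D with six reactions:
#' `r1`: \eqn{\emptyset \leftrightarrow A} (the only reversible reaction),
#' `r2`: \eqn{A \to B + C}, `r3`: \eqn{B + C \to D}, `r4`: \eqn{D \to
#' \emptyset}, `r5`: \eqn{\emptyset \to C}, `r6`: \eqn{C \to A + D}.
#' All stoichiometric coefficients are in \{-1, 0, +1\}.
#'
#' Its support lattice has exactly five elements:
#' \eqn{\emptyset}, \{r1,r2,r3,r4\}, \{r1,r4,r5,r6\}, \{r2,r3,r4,r5,r6\} and
#' the maximal element \{r1,...,r6\}; there are no blocked reactions, the
#' partial-coupling classes are \{r1\}, \{r2,r3\}, \{r4\}, \{r5,r6\}, and
#' knocking out r4 blocks the entire network.  This makes the fixture a
#' compact ground truth for every coupling notion in the package.
#'
#' @param gpr optional named list of GPR rule strings to attach (e.g.
#'   `list(r2 = "gA", r3 = "gA or gB")`).
#' @return A [metabolic_network()].
#' @export
example_network <- function(gpr = list()) {
  mets <- c("A", "B", "C", "D")
  rxns <- paste0("r", 1:6)
  S <- matrix(0, 4, 6, dimnames = list(mets, rxns))
  S["A", "r1"] <- 1
  S["A", "r2"] <- -1; S["B", "r2"] <- 1; S["C", "r2"] <- 1
  S["B", "r3"] <- -1; S["C", "r3"] <- -1; S["D", "r3"] <- 1
  S["D", "r4"] <- -1
  S["C", "r5"] <- 1
  S["C", "r6"] <- -1; S["A", "r6"] <- 1; S["D", "r6"] <- 1
  gpr <- lapply(gpr, function(x) {
    if (inherits(x, "gene_rule")) x else parse_gene_rule(as.character(x))
  })
  genes <- sort_ids(unlist(lapply(gpr, rule_genes), use.names = FALSE))
  metabolic_network(mets, rxns, S, irreversible = paste0("r", 2:6),
                    genes = genes, gpr = gpr)
}

#' Generate a random metabolic network
#'
#' Draws a sparse random stoichiometric matrix with coefficients in
#' \{-1, +1\} and appends single-metabolite exchange reactions so the
#' network can exchange matter with the environment and carry non-trivial
#' steady-state flux.  Intended as a test-fixture generator: the resulting
#' networks are small enough for the exact brute-force oracle
#' ([enumerate_lattice()]) and exhibit a realistic mix of blocked,
#' coupled and independent reactions.
#'
#' @param n_metabolites,n_reactions number of internal metabolites and
#'   internal (non-exchange) reactions; both at least 1.
#' @param reversible_fraction probability in \[0, 1\] that a reaction
#'   (internal or exchange) is reversible.
#' @param density probability in (0, 1\] of a nonzero coefficient per
#'   (metabolite, reaction) entry; every internal reaction is guaranteed at
#'   least one nonzero coefficient.
#' @param seed integer seed; the same seed always yields the same network.
#' @param n_exchange number of exchange reactions (single-metabolite export
#'   columns, coefficient -1) appended after the internal reactions.
#' @return A [metabolic_network()] with reaction ids `r01`, `r02`, ... for
#'   internal reactions and `x01`, ... for exchanges.
#' @export
random_network <- function(n_metabolites, n_reactions,
                           reversible_fraction = 0.3, density = 0.4,
                           seed = 1L, n_exchange = 2L) {
  if (n_metabolites < 1 || n_reactions < 1) {
    stop("n_metabolites and n_reactions must be at least 1")
  }
  if (reversible_fraction < 0 || reversible_fraction > 1) {
    stop("reversible_fraction must be in [0, 1]")
  }
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (n_exchange < 0) stop("n_exchange must be non-negative")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  mets <- sprintf("m%02d", seq_len(n_metabolites))
  rxns <- sprintf("r%02d", seq_len(n_reactions))
  S <- matrix(0, n_metabolites, n_reactions, dimnames = list(mets, rxns))
  for (j in seq_len(n_reactions)) {
    nz <- which(stats::runif(n_metabolites) < density)
    if (!length(nz)) nz <- sample.int(n_metabolites, 1L)
    S[nz, j] <- sample(c(-1, 1), length(nz), replace = TRUE)
  }
  if (n_exchange > 0) {
    ex_ids <- sprintf("x%02d", seq_len(n_exchange))
    ex_mets <- sample(mets, n_exchange, replace = n_exchange > n_metabolites)
    E <- matrix(0, n_metabolites, n_exchange, dimnames = list(mets, ex_ids))
    for (j in seq_len(n_exchange)) E[ex_mets[j], j] <- -1
    S <- cbind(S, E)
    rxns <- c(rxns, ex_ids)
  }
  rev <- stats::runif(length(rxns)) < reversible_fraction
  metabolic_network(mets, rxns, S, irreversible = rxns[!rev])
}
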