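test_that("worked-example fixture has the documented stoichiometry", {
  net <- example_network()
  expect_identical(net$metabolites, c("A", "B", "C", "D"))
  expect_identical(net$reactions, paste0("r", 1:6))
  S <- as.matrix(net$stoich)
  expect_equal(unname(S[, "r2"]), c(-1, 1, 1, 0))
  expect_identical(net$irreversible, paste0("r", 2:6))
  # the printed steady-state flux vector balances and respects signs
  v <- c(0, 1, 1, 2, 1, 1)
  expect_equal(unname(as.numeric(S %*% v)), rep(0, 4))
  expect_true(all(v[match(net$irreversible, net$reactions)] >= 0))
})

test_that("fixture flux space is two-dimensional with the expected kernel", {
  S <- as.matrix(example_network()$stoich)
  b1 <- c(1, 1, 1, 1, 0, 0)
  b2 <- c(-1, 0, 0, 1, 1, 1)
  expect_equal(unname(as.numeric(S %*% b1)), rep(0, 4))
  expect_equal(unname(as.numeric(S %*% b2)), rep(0, 4))
  expect_equal(qr(S)$rank, 4)          # kernel dimension = 6 - 4 = 2
  expect_equal(qr(cbind(b1, b2))$rank, 2)
})

test_that("network constructor validates its invariants", {
  S <- matrix(1, 1, 2, dimnames = list("M", c("a", "b")))
  expect_error(metabolic_network("M", c("a", "a"), S), "duplicate reaction")
  expect_error(metabolic_network(c("M", "M"), c("a", "b"), S),
               "duplicate metabolite")
  expect_error(metabolic_network("M", c("a", "b"), S, irreversible = "zz"),
               "unknown reactions")
  expect_error(metabolic_network("M", "a", S), "must be 1 x 1")
  expect_warning(
    metabolic_network("M", c("a", "b"),
                      matrix(c(1, 0), 1, 2,
                             dimnames = list("M", c("a", "b")))),
    "all-zero")
  expect_warning(
    metabolic_network("M", c("a", "b"), S, gpr = list(a = "g1")),
    "undeclared genes")
  expect_error(
    metabolic_network("M", c("a", "b"), S, gpr = list(zz = "g1")),
    "unknown reactions")
})

test_that("random networks are deterministic and satisfy the invariants", {
  n1 <- random_network(4, 8, reversible_fraction = 0.25, density = 0.5,
                       seed = 7)
  n2 <- random_network(4, 8, reversible_fraction = 0.25, density = 0.5,
                       seed = 7)
  expect_identical(as.matrix(n1$stoich), as.matrix(n2$stoich))
  expect_identical(n1$irreversible, n2$irreversible)
  n3 <- random_network(4, 8, reversible_fraction = 0.25, density = 0.5,
                       seed = 8)
  expect_false(identical(as.matrix(n1$stoich), as.matrix(n3$stoich)))

  expect_true(all(Matrix::colSums(abs(n1$stoich)) >= 1))
  expect_true(all(n1$irreversible %in% n1$reactions))

  all_irr <- random_network(3, 5, reversible_fraction = 0, seed = 11)
  expect_identical(all_irr$irreversible, all_irr$reactions)

  expect_error(random_network(0, 3), "at least 1")
  expect_error(random_network(3, 3, density = 0), "density")
  expect_error(random_network(3, 3, reversible_fraction = 2),
               "reversible_fraction")
})

test_that("random_network does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- stats::runif(1)
  set.seed(123)
  invisible(random_network(3, 4, seed = 99))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("JSON dialect round-trips a network exactly", {
  net <- example_network(gpr = example_gpr())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, tmp)
  back <- read_network_json(tmp)
  expect_identical(as.matrix(back$stoich), as.matrix(net$stoich))
  expect_identical(back$irreversible, net$irreversible)
  expect_identical(back$genes, net$genes)
  expect_identical(lapply(back$gpr, format), lapply(net$gpr, format))
  # serialize -> load -> serialize is byte-identical
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_network_json(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("SBML reader reproduces the fixture, bounds and GPR trees", {
  path <- system.file("extdata", "example.xml", package = "fluxlattice")
  net <- load_network(path)
  ref <- example_network(gpr = example_gpr())
  expect_identical(as.matrix(net$stoich), as.matrix(ref$stoich))
  expect_identical(net$irreversible, ref$irreversible)
  expect_identical(net$genes, c("gA", "gB", "gC"))
  expect_identical(format(net$gpr$r3), "gA or gB")
})

test_that("minimal SBML model parses; backward reactions are re-oriented", {
  path <- system.file("extdata", "minimal_backward.xml",
                      package = "fluxlattice")
  expect_message(
    suppressWarnings(net <- load_network(path, format = "sbml")),
    "column negated")
  expect_identical(net$metabolites, "M")  # boundary species dropped
  expect_identical(net$reactions, c("uptake", "sink"))
  S <- as.matrix(net$stoich)
  expect_equal(unname(S["M", ]), c(1, -1))  # sink flipped to consume M
  expect_setequal_ids(net$irreversible, c("uptake", "sink"))
  expect_identical(format(net$gpr$uptake), "gU1 or gU2")  # notes fallback
})

test_that("load_network rejects missing files and unknown formats", {
  expect_error(load_network("no/such/file.json"), "not found")
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", tmp)
  expect_error(load_network(tmp), "cannot infer")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_network(bad), "failed to parse")
})

test_that("GPR parsing respects precedence not > and > or", {
  r <- parse_gene_rule("g1 or g2")
  expect_true(eval_gene_rule(r, c(g1 = FALSE, g2 = TRUE)))
  r <- parse_gene_rule("g1 or not g2")
  expect_false(eval_gene_rule(r, c(g1 = FALSE, g2 = TRUE)))
  expect_true(eval_gene_rule(r, c(g1 = FALSE, g2 = FALSE)))
  r <- parse_gene_rule("(a and b) or c")
  expect_false(eval_gene_rule(r, c(a = TRUE, b = FALSE, c = FALSE)))
  expect_true(eval_gene_rule(r, c(a = TRUE, b = TRUE, c = FALSE)))
  # without parentheses, and binds tighter than or
  r <- parse_gene_rule("a or b and c")
  expect_true(eval_gene_rule(r, c(a = TRUE, b = TRUE, c = FALSE)))
  expect_false(eval_gene_rule(r, c(a = FALSE, b = TRUE, c = FALSE)))
  # not binds tighter than and
  r <- parse_gene_rule("not a and b")
  expect_true(eval_gene_rule(r, c(a = FALSE, b = TRUE)))
  expect_false(eval_gene_rule(r, c(a = FALSE, b = FALSE)))
  # symbol synonyms
  r <- parse_gene_rule("x & !y | z")
  expect_true(eval_gene_rule(r, c(x = TRUE, y = FALSE, z = FALSE)))
  expect_identical(rule_genes(r), c("x", "y", "z"))
})

test_that("GPR syntax errors report a position", {
  expect_error(parse_gene_rule("(g1 or g2"), "position")
  expect_error(parse_gene_rule("g1 or"), "position 6")
  expect_error(parse_gene_rule("g1 ) g2"), "position 4")
  expect_error(parse_gene_rule("and g1"), "position 1")
  expect_error(parse_gene_rule("g1 + g2"), "position 4")
  expect_error(eval_gene_rule(parse_gene_rule("g1 and g2"), c(g1 = TRUE)),
               "missing genes")
})

test_that("rules survive a format/parse round trip", {
  for (txt in c("g1", "not g2", "g1 and (g2 or not g3)",
                "(a or b) and (c or d)", "not (a and b)")) {
    r <- parse_gene_rule(txt)
    r2 <- parse_gene_rule(format(r))
    for (i in 1:8) {
      bits <- as.logical(bitwAnd(i, c(1L, 2L, 4L)) > 0)
      asg <- stats::setNames(bits[seq_along(rule_genes(r))], rule_genes(r))
      expect_identical(eval_gene_rule(r, asg), eval_gene_rule(r2, asg))
    }
  }
})
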