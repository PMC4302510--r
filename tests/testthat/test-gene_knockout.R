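test_that("associated reactions follow the GPR rules", {
  # r_a needs g1; r_b is catalyzed by g1 or g2
  S <- matrix(c(1, -1), 1, 2, dimnames = list("M", c("r_a", "r_b")))
  net <- metabolic_network("M", c("r_a", "r_b"), S,
                           irreversible = c("r_a", "r_b"),
                           genes = c("g1", "g2"),
                           gpr = list(r_a = "g1", r_b = "g1 or g2"))
  expect_identical(associated_reactions(net, "g1"), "r_a")
  expect_identical(associated_reactions(net, "g2"), character(0))
  expect_identical(associated_reactions(net, c("g1", "g2")),
                   c("r_a", "r_b"))
  expect_identical(associated_reactions(net, character()), character(0))
  expect_error(associated_reactions(net, "g9"), "unknown gene")
})

test_that("negated rules make the association map non-monotone", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("M", c("rin", "rout")))
  net <- metabolic_network("M", c("rin", "rout"), S,
                           irreversible = c("rin", "rout"),
                           genes = c("g1", "g2"),
                           gpr = list(rin = "g1 or not g2"))
  # rin is associated to the single knockout of g1 (g2 still on)...
  expect_identical(associated_reactions(net, "g1"), "rin")
  # ...but NOT to the double knockout {g1, g2}: not-g2 rescues the rule
  expect_identical(associated_reactions(net, c("g1", "g2")), character(0))
  # and the double gene knockout therefore couples nothing
  rec2 <- gene_coupling(net, c("g1", "g2"))
  expect_identical(rec2$coupled, character(0))
  rec1 <- gene_coupling(net, "g1")
  expect_setequal_ids(rec1$coupled, c("rin", "rout"))
})

test_that("gene couplings on the fixture propagate through reaction couplings", {
  net <- example_network(gpr = example_gpr())
  singles <- all_gene_knockouts(net, order = 1)
  expect_length(singles, 3)
  by_gene <- stats::setNames(singles,
                             vapply(singles, `[[`, character(1), "genes"))
  # gA removes r2; the knockout drags classmate r3 along
  expect_identical(by_gene[["gA"]]$associated, "r2")
  expect_identical(by_gene[["gA"]]$coupled, c("r2", "r3"))
  # gB alone removes nothing (r3 still has gA)
  expect_identical(by_gene[["gB"]]$associated, character(0))
  expect_identical(by_gene[["gB"]]$coupled, character(0))
  expect_identical(by_gene[["gC"]]$associated, c("r5", "r6"))
  expect_identical(by_gene[["gC"]]$coupled, c("r5", "r6"))

  pairs <- all_gene_knockouts(net, order = 2)
  expect_length(pairs, 3)
  key <- vapply(pairs, function(r) paste(r$genes, collapse = "+"),
                character(1))
  # {gA, gC} removes {r2, r5, r6}; the joint coupling {r2,r5} -> {r1,r4}
  # already takes down the whole network
  rec <- pairs[[which(key == "gA+gC")]]
  expect_identical(rec$associated, c("r2", "r5", "r6"))
  expect_identical(rec$coupled, paste0("r", 1:6))
  # {gA, gB} kills r3's rule as well
  rec <- pairs[[which(key == "gA+gB")]]
  expect_identical(rec$associated, c("r2", "r3"))
  expect_identical(rec$coupled, c("r2", "r3"))
})

test_that("gene coupling equals the definitional identity", {
  net <- example_network(gpr = example_gpr())
  unblocked <- max_element(net)$unblocked
  for (gs in list("gA", "gC", c("gA", "gB"), c("gB", "gC"))) {
    rec <- gene_coupling(net, gs)
    K <- intersect(associated_reactions(net, gs), unblocked)
    direct <- if (length(K)) max_element(net, K)$unblocked else unblocked
    expect_identical(rec$coupled,
                     sort(setdiff(unblocked, direct), method = "radix"))
    expect_true(all(intersect(rec$associated, unblocked) %in% rec$coupled))
  }
})

test_that("blocked associated reactions are dropped before the lattice call", {
  net <- dead_end_network()
  net$genes <- "gX"
  net$gpr <- list(dead = parse_gene_rule("gX"))
  rec <- gene_coupling(net, "gX")
  # 'dead' is blocked already, so the knockout set handed to the lattice
  # is empty and nothing unblocked is coupled
  expect_identical(rec$associated, "dead")
  expect_identical(rec$coupled, character(0))
})

test_that("monotone (negation-free) rules give monotone couplings", {
  net <- example_network(gpr = example_gpr())
  sets <- list(character(), "gA", c("gA", "gB"), c("gA", "gB", "gC"))
  prev <- NULL
  for (gs in sets) {
    K <- associated_reactions(net, gs)
    rec <- gene_coupling(net, gs)
    if (!is.null(prev)) {
      expect_true(all(prev$K %in% K))
      expect_true(all(prev$coupled %in% rec$coupled))
    }
    prev <- list(K = K, coupled = rec$coupled)
  }
})

test_that("gene sets with identical associated reactions are solved once", {
  # gC appears in two rules; g_dup duplicates gC's rule structure; gFree
  # sits in no rule at all but still yields a record
  net <- example_network(gpr = list(r2 = "gA", r3 = "gA or gB",
                                    r5 = "gC", r6 = "gC or gA"))
  S <- as.matrix(net$stoich)
  net2 <- metabolic_network(net$metabolites, net$reactions, S,
                            irreversible = net$irreversible,
                            genes = c("gA", "gB", "gC", "gFree"),
                            gpr = net$gpr)
  singles <- all_gene_knockouts(net2, order = 1)
  expect_length(singles, 4)
  # gB and gFree both induce the empty knockout -> memoized together
  expect_lt(attr(singles, "n_lattice_computations"), length(singles) + 1L)
  rec_free <- singles[[which(vapply(singles, `[[`, character(1),
                                    "genes") == "gFree")]]
  expect_identical(rec_free$associated, character(0))
  expect_identical(rec_free$coupled, character(0))

  pairs <- all_gene_knockouts(net2, order = 2)
  expect_length(pairs, choose(4, 2))
})

test_that("abstract lattice reproduces the two-gene bookkeeping example", {
  # Abstract qualitative model: gene g1 catalyzes reactions 1 and 3; the
  # coupling structure provides 3 -> 4 and {1,3} -> 6, so switching off
  # g1 must silence 4 reactions in total: 1, 3, 4 and 6.
  lat <- enumerated_lattice(list(
    c("1", "2", "6"), c("2", "3", "4"), c("2", "5"), c("3", "6")
  ), reactions = as.character(1:6), close = TRUE)
  ana <- oracle_analysis(lat)
  expect_identical(ana$blocked, character(0))
  # stated premises hold in this lattice
  expect_true("4" %in% ana$coupling[["3"]])              # 3 -> 4
  expect_false("6" %in% ana$coupling[["1"]])             # not 1 -> 6
  expect_false("6" %in% ana$coupling[["3"]])             # not 3 -> 6
  expect_false("6" %in% oracle_max_without(lat, c("1", "3")))  # {1,3} -> 6
  # Definition of gene coupling: drop K_gamma = {1, 3}, collect the lost
  K_gamma <- c("1", "3")
  after <- oracle_max_without(lat, K_gamma)
  coupled <- setdiff(ana$unblocked, after)
  expect_setequal_ids(coupled, c("1", "3", "4", "6"))
  expect_length(coupled, 4)
})
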