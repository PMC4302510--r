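# Shared fixtures for the test suite.  All expected values for the
# six-reaction worked-example network were cross-checked against the
# brute-force lattice oracle (see test-bruteforce_oracle.R).

# The five support-lattice elements of example_network()
example_lattice_elements <- function() {
  list(character(0),
       c("r1", "r2", "r3", "r4"),
       c("r1", "r4", "r5", "r6"),
       c("r2", "r3", "r4", "r5", "r6"),
       paste0("r", 1:6))
}

example_gpr <- function() {
  list(r2 = "gA", r3 = "gA or gB", r5 = "gC", r6 = "gC")
}

# Small-network battery for oracle-equivalence properties: at most
# 6 internal + 2 exchange = 8 reactions and 6 metabolites, mixed
# reversibility, fixed seeds.
battery_network <- function(i) {
  random_network(n_metabolites = 3L + i %% 4L,
                 n_reactions = 4L + i %% 3L,
                 reversible_fraction = c(0, 0.3, 0.6)[1L + i %% 3L],
                 density = 0.4,
                 seed = 2000L + i,
                 n_exchange = 2L)
}

# a network with one blocked reaction ("dead" consumes a metabolite
# nobody produces) next to an unblocked in/out pair on a second metabolite
dead_end_network <- function() {
  S <- matrix(c(-1, 0, 0,
                0, 1, -1), 2, 3, byrow = TRUE,
              dimnames = list(c("P", "Q"), c("dead", "inQ", "outQ")))
  metabolic_network(c("P", "Q"), c("dead", "inQ", "outQ"), S,
                    irreversible = c("dead", "outQ"))
}

expect_setequal_ids <- function(object, expected) {
  expect_identical(sort(object, method = "radix"),
                   sort(expected, method = "radix"))
}

record_signature <- function(records) {
  sig <- vapply(records, function(r) {
    paste(c(sort(r$pair, method = "radix"), "->",
            sort(r$targets, method = "radix")), collapse = " ")
  }, character(1))
  sort(sig, method = "radix")
}
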