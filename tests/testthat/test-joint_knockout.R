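example_dko <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- double_knockout_analysis(example_network())
    val
  }
})

test_that("candidate pairs exclude coupled representatives", {
  dko <- example_dko()
  cp <- candidate_pairs(dko$partition, dko$table)
  expect_identical(cp$members,
                   list(c("r1", "r2"), c("r1", "r5"), c("r2", "r5")))
  # r4 blocks everything, so no candidate pair contains it; r3 and r6 are
  # not representatives and never appear
  flat <- unlist(cp$members)
  expect_false(any(c("r3", "r4", "r6") %in% flat))
})

test_that("double knockout analysis finds the worked-example joint couplings", {
  dko <- example_dko()
  expect_length(dko$records, 3)
  sig <- record_signature(dko$records)
  expect_identical(sig, c("r1 r2 -> r4 r5 r6",
                          "r1 r5 -> r2 r3 r4",
                          "r2 r5 -> r1 r4"))
  for (rec in dko$records) {
    expect_true(rec$has_joint_effect)
    expect_identical(rec$unblocked_after, character(0))
  }
})

test_that("joint targets satisfy the lattice characterization", {
  nets <- c(list(example_network()), lapply(c(1, 7, 12), battery_network))
  for (net in nets) {
    dko <- double_knockout_analysis(net)
    tab <- dko$table
    for (rec in dko$records) {
      r <- rec$pair[1]; s <- rec$pair[2]
      both_survive <- intersect(max_without(tab, r), max_without(tab, s))
      expect_true(all(rec$targets %in% both_survive))
      expect_length(intersect(rec$targets, rec$unblocked_after), 0)
      expect_length(intersect(rec$targets, rec$pair), 0)
      # no target is singly coupled to either pair member
      for (t in rec$targets) {
        expect_false(is_coupled(tab, r, t))
        expect_false(is_coupled(tab, s, t))
      }
    }
  }
})

test_that("analysis variants agree at class level and witnesses save LPs", {
  net <- example_network()
  standard <- example_dko()
  variant_a <- double_knockout_analysis(net, use_representatives = FALSE)
  variant_b <- double_knockout_analysis(net, use_representatives = FALSE,
                                        use_witnesses = FALSE)
  cc <- class_level_couplings(standard)
  expect_identical(class_level_couplings(variant_a), cc)
  expect_identical(class_level_couplings(variant_b), cc)
  expect_lte(variant_a$lp_calls$total, variant_b$lp_calls$total)
  expect_lte(standard$lp_calls$dko, variant_a$lp_calls$dko)
})

test_that("candidate d-subsets honor the order-m filters", {
  dko <- example_dko()
  tab <- dko$table; part <- dko$partition
  k31 <- candidate_sets(3, 1, tab, part)
  expect_identical(k31$members, list(c("r1", "r2", "r5")))
  # {r2, r5} -> r1 removes the only triple once joint data is used
  k32 <- candidate_sets(3, 2, tab, part, joint = dko)
  expect_identical(k32$members, list())
  k21 <- candidate_sets(2, 1, tab, part)
  expect_identical(k21$members, candidate_pairs(part, tab)$members)
  expect_error(candidate_sets(3, 2, tab, part), "requires double-knockout")
  expect_error(candidate_sets(5, 1, tab, part), "between 2 and 4")
  expect_error(candidate_sets(3, 3, tab, part, dko), "m must be")
})

test_that("multi_knockout handles singletons, pairs and triples", {
  net <- example_network()
  # singleton: degenerates to directional coupling
  mk <- multi_knockout(net, "r4")
  expect_identical(mk$element$unblocked, character(0))
  expect_identical(mk$targets, c("r1", "r2", "r3", "r5", "r6"))
  # pair, matching the double-knockout record
  mk <- multi_knockout(net, c("r2", "r5"))
  expect_identical(mk$targets, c("r1", "r4"))
  # order of K does not matter
  mk2 <- multi_knockout(net, c("r5", "r2"))
  expect_identical(mk2$targets, mk$targets)
  # triple: every 2-subset already empties the lattice, so no targets
  mk <- multi_knockout(net, c("r1", "r2", "r5"))
  expect_identical(mk$element$unblocked, character(0))
  expect_identical(mk$targets, character(0))
})

test_that("multi_knockout rejects blocked or empty knockout sets", {
  net <- dead_end_network()
  expect_error(multi_knockout(net, "dead"), "blocked")
  expect_error(multi_knockout(net, character()), "at least one")
  expect_error(multi_knockout(net, "zz"), "unknown reaction")
})

test_that("multi_knockout agrees with the recursive definition on triples", {
  for (i in c(5, 11)) {
    net <- battery_network(i)
    lat <- enumerate_lattice(net)
    ana <- oracle_analysis(lat)
    reps <- ana$representatives
    if (length(reps) < 3) next
    combs <- utils::combn(reps, 3, simplify = FALSE)
    for (K in combs[seq_len(min(5, length(combs)))]) {
      got <- multi_knockout(net, K)
      want <- oracle_multi_knockout(lat, K)
      expect_identical(got$element$unblocked, want$unblocked)
      expect_identical(got$targets, want$targets)
    }
  }
})

test_that("record serialization round-trips through JSON lines", {
  dko <- example_dko()
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_joint_records(dko, jsonl, tsv)
  back <- read_joint_records(jsonl)
  expect_identical(record_signature(back), record_signature(dko$records))
  expect_identical(vapply(back, `[[`, logical(1), "has_joint_effect"),
                   vapply(dko$records, `[[`, logical(1), "has_joint_effect"))
  df <- utils::read.delim(tsv)
  expect_equal(nrow(df), length(dko$records))
  expect_identical(df$n_target_classes, c(2L, 2L, 2L))
  expect_identical(df$n_target_reactions, c(3L, 3L, 2L))
})
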