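rxn <- function(...) notchwnt:::rx(...)
cv <- function(...) notchwnt:::cvec(...)

## brute-force references for small networks
brute_conservative <- function(S, kmax = 6) {
  ns <- nrow(S)
  grid <- do.call(expand.grid, rep(list(seq_len(kmax)), ns))
  for (i in seq_len(nrow(grid))) {
    m <- as.numeric(grid[i, ])
    if (all(abs(t(S) %*% m) < 1e-9)) return(TRUE)
  }
  FALSE
}
brute_weakly_reversible <- function(net) {
  key <- notchwnt:::complex_string
  from <- vapply(net$reactions, function(r) key(r$reactants), "")
  to <- vapply(net$reactions, function(r) key(r$products), "")
  nodes <- unique(c(from, to))
  reach <- function(a, b) {  # DFS: path a -> b?
    seen <- a; stack <- a
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      nxt <- setdiff(to[from == x], seen)
      if (b %in% c(x, nxt)) return(TRUE)
      seen <- c(seen, nxt); stack <- c(stack, nxt)
    }
    b %in% seen
  }
  # weakly reversible iff every arc lies on a directed cycle
  all(vapply(seq_along(from), function(i) reach(to[i], from[i]), TRUE))
}

test_that("reaction_network validates its inputs", {
  expect_s3_class(reaction_network("A", list(rxn(products = cv(A = 1)))),
                  "reaction_network")
  expect_error(reaction_network("A", list(rxn(products = cv(B = 1)))),
               "declared")
  expect_error(reaction_network("A", list(rxn(products = c(1)))),
               "named")
  expect_error(reaction_network("A", list(rxn(products = cv(A = 1.5)))),
               "positive integers")
  expect_error(reaction_network("A", list(rxn(products = cv(A = -1)))),
               "positive integers")
  expect_error(reaction_network("A", list(rxn(products = cv(A = 1),
                                              promoters = "Z"))),
               "declared")
})

test_that("stoichiometric matrix on textbook examples", {
  n1 <- reaction_network(c("A", "B"),
                         list(rxn(cv(A = 1), cv(B = 1), label = "a2b")))
  S1 <- stoichiometric_matrix(n1)
  expect_equal(unname(S1[, "a2b"]), c(-1L, 1L))
  n2 <- reaction_network(c("A", "C"),
                         list(rxn(cv(A = 2), cv(C = 1), label = "dim")))
  S2 <- stoichiometric_matrix(n2)
  expect_equal(unname(S2[, "dim"]), c(-2L, 1L))
  expect_error(stoichiometric_matrix(reaction_network("A", list())),
               "no reactions")
})

test_that("conservativity: closed interconversions yes, flows/growth no", {
  ab <- reaction_network(c("A", "B"),
                         list(rxn(cv(A = 1), cv(B = 1), label = "f"),
                              rxn(cv(B = 1), cv(A = 1), label = "r")))
  expect_true(is_conservative(ab))
  inflow <- reaction_network("A", list(rxn(products = cv(A = 1),
                                           label = "in")))
  expect_false(is_conservative(inflow))
  growth <- reaction_network("A", list(rxn(cv(A = 1), cv(A = 2),
                                           label = "g")))
  expect_false(is_conservative(growth))
  # GSK pool subnetwork: G <-> C, C <-> I2 (beta-catenin external)
  gsk <- reaction_network(c("G", "C", "I2"),
                          list(rxn(cv(G = 1), cv(C = 1), label = "asm"),
                               rxn(cv(C = 1), cv(G = 1), label = "rev"),
                               rxn(cv(C = 1), cv(I2 = 1), label = "bind"),
                               rxn(cv(I2 = 1), cv(C = 1), label = "rel")))
  expect_true(is_conservative(gsk))
  # weighted pool: 2A -> C needs m = (1, 2)
  dimer <- reaction_network(c("A", "C"),
                            list(rxn(cv(A = 2), cv(C = 1), label = "f"),
                                 rxn(cv(C = 1), cv(A = 2), label = "r")))
  expect_true(is_conservative(dimer))
})

test_that("weak reversibility on textbook examples", {
  cyc <- reaction_network(c("A", "B", "C"),
                          list(rxn(cv(A = 1), cv(B = 1), label = "1"),
                               rxn(cv(B = 1), cv(C = 1), label = "2"),
                               rxn(cv(C = 1), cv(A = 1), label = "3")))
  expect_true(is_weakly_reversible(cyc))
  oneway <- reaction_network(c("A", "B"),
                             list(rxn(cv(A = 1), cv(B = 1), label = "1")))
  expect_false(is_weakly_reversible(oneway))
  # inflow/outflow through the pseudo-complex closes a cycle
  flow <- reaction_network("A", list(rxn(products = cv(A = 1), label = "in"),
                                     rxn(cv(A = 1), label = "out")))
  expect_true(is_weakly_reversible(flow))
})

test_that("checks agree with brute force on small networks", {
  nets <- list(
    reaction_network(c("A", "B"),
                     list(rxn(cv(A = 1), cv(B = 1), label = "1"),
                          rxn(cv(B = 1), cv(A = 1), label = "2"))),
    reaction_network(c("A", "B"),
                     list(rxn(cv(A = 1), cv(B = 1), label = "1"))),
    reaction_network("A", list(rxn(products = cv(A = 1), label = "in"),
                               rxn(cv(A = 1), label = "out"))),
    reaction_network("A", list(rxn(cv(A = 1), cv(A = 2), label = "g"))),
    reaction_network(c("A", "B", "C"),
                     list(rxn(cv(A = 1), cv(B = 1), label = "1"),
                          rxn(cv(B = 1), cv(C = 1), label = "2"),
                          rxn(cv(C = 1), cv(A = 1), label = "3"))),
    reaction_network(c("A", "C"),
                     list(rxn(cv(A = 2), cv(C = 1), label = "f"),
                          rxn(cv(C = 1), cv(A = 2), label = "r"))),
    reaction_network(c("G", "C", "I2", "B"),
                     list(rxn(cv(G = 1), cv(C = 1), label = "asm"),
                          rxn(cv(C = 1), cv(G = 1), label = "rev"),
                          rxn(cv(C = 1, B = 1), cv(I2 = 1), label = "bind"),
                          rxn(cv(I2 = 1), cv(C = 1), label = "rel")))
  )
  for (net in nets) {
    S <- stoichiometric_matrix(net)
    expect_identical(is_conservative(net), brute_conservative(S))
    expect_identical(is_weakly_reversible(net),
                     brute_weakly_reversible(net))
  }
})

test_that("build_network variants have the documented structure", {
  full_off <- build_network("full", "step4_and_14", "off")
  expect_length(full_off$species, 12)
  labels <- vapply(full_off$reactions, function(r) r$label, "")
  steps <- c("notch_production", "notch_cleavage", "nicd_bcat_binding",
             "hes1_transcription_notch", "hes1_transcription_wnt",
             "hath1_production", "ngn3_production", "delta_production",
             "bcat_basal_production", "axin_production", "complex_assembly",
             "complex_release", "complex_bcat_binding", "i2_release")
  expect_true(all(steps %in% labels))
  expect_equal(sum(startsWith(labels, "decay_")), 9)
  # step4_only drops the direct beta-catenin transcription reaction
  l4 <- vapply(build_network("full", "step4_only", "off")$reactions,
               function(r) r$label, "")
  expect_false("hes1_transcription_wnt" %in% l4)
  # Wnt ON adds the stimulus species and its influences
  full_on <- build_network("full", "step4_and_14", "on")
  expect_true("Wnt" %in% full_on$species)
  tr <- Filter(function(r) r$label == "hes1_transcription_notch",
               full_on$reactions)[[1]]
  expect_true("Wnt" %in% tr$inhibitors)
  # notch_only keeps B as a full reactant with its own inflow and outflow
  no <- build_network("notch_only", "step4_and_14", "off")
  ln <- vapply(no$reactions, function(r) r$label, "")
  expect_true(all(c("bcat_inflow", "bcat_outflow") %in% ln))
  expect_true("B" %in% no$species)
  expect_error(build_network("wnt_only", coupling = "step4_only"),
               "inapplicable")
})

test_that("export emits the documented dialect", {
  net <- reaction_network(c("A", "B", "H"),
                          list(rxn(products = cv(H = 1), promoters = "A",
                                   inhibitors = "H", label = "tx"),
                               rxn(cv(A = 2, B = 1), cv(H = 1),
                                   label = "bind")))
  doc <- export_crn_toolbox(net)
  expect_equal(doc[1], "# species: A, B, H")
  expect_equal(doc[2], "# labels: tx, bind")
  expect_equal(doc[3], "0 {+A, -H} -> H")
  expect_equal(doc[4], "2A + B -> H")
  bad <- reaction_network("A B", list(rxn(products = cv(`A B` = 1))))
  expect_error(export_crn_toolbox(bad), "reserved")
})

test_that("export / parse round-trips every shipped network", {
  combos <- list(
    list("full", "step4_and_14", "on"), list("full", "step4_and_14", "off"),
    list("full", "step4_only", "on"), list("full", "step4_only", "off"),
    list("notch_only", "step4_and_14", "on"),
    list("notch_only", "step4_and_14", "off"),
    list("notch_only", "step4_only", "on"),
    list("notch_only", "step4_only", "off"),
    list("wnt_only", NULL, "on"), list("wnt_only", NULL, "off"))
  for (cb in combos) {
    net <- if (is.null(cb[[2]])) build_network(cb[[1]], wnt = cb[[3]]) else
      build_network(cb[[1]], cb[[2]], cb[[3]])
    doc <- export_crn_toolbox(net)
    back <- parse_crn_toolbox(doc)
    expect_identical(back$species, net$species)
    expect_identical(export_crn_toolbox(back), doc)
    S1 <- stoichiometric_matrix(net)
    S2 <- stoichiometric_matrix(back)
    expect_equal(S2[rownames(S1), colnames(S1)], S1)
    expect_identical(
      lapply(back$reactions, function(r) sort(r$promoters)),
      lapply(net$reactions, function(r) sort(r$promoters)))
    expect_identical(
      lapply(back$reactions, function(r) sort(r$inhibitors)),
      lapply(net$reactions, function(r) sort(r$inhibitors)))
  }
  # file round trip
  f <- tempfile(fileext = ".txt")
  net <- build_network("wnt_only", wnt = "on")
  export_crn_toolbox(net, f)
  expect_identical(export_crn_toolbox(parse_crn_toolbox(f)),
                   export_crn_toolbox(net))
  unlink(f)
})

test_that("multistability_probe reports its evidence structure", {
  expect_error(multistability_probe("wnt_only", wnt = "on",
                                    n_parameter_draws = 0), ">= 1")
  pr <- multistability_probe("wnt_only", wnt = "on",
                             n_parameter_draws = 2, n_starts = 4, seed = 42)
  expect_true(pr$verdict %in% c("monostable", "multistable"))
  expect_length(pr$n_states_per_draw, 2)
  if (pr$verdict == "monostable") {
    expect_match(pr$caveat, "not a proof")
    expect_null(pr$witness)
  } else {
    expect_equal(pr$witness$draw, which(pr$n_states_per_draw >= 2)[1])
  }
})
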