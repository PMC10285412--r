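test_that("contact tiers are nested and assigned by smallest cutoff", {
  expect_equal(contact_tier(2.9), "hbond")
  expect_equal(contact_tier(3.9), "packing")
  expect_equal(contact_tier(5.5), "proximity")
  expect_equal(contact_tier(12.0), "neighborhood")
  expect_equal(contact_tier(15.0), "neighborhood")
  expect_equal(contact_tier(15.1), "none")
  expect_error(contact_tier(-1), "negative")
  # nesting: anything within a tight tier is within every looser one
  for (d in c(0.5, 3.7, 4.4, 5.9, 14.9)) {
    t <- contact_tier(d)
    expect_true(tier_within(t, "neighborhood"))
  }
  expect_error(tier_params(hbond = 5, packing = 4))
})

test_that("bridge membership distinguishes member, neighborhood and none", {
  bridges <- data.frame(bridge = c("mB7", "B7a"),
                        component = c("12S", "12S"),
                        positions = c("334,335", "354"),
                        stringsAsFactors = FALSE)
  expect_equal(bridge_membership(334, bridges)$status, "member")
  expect_equal(bridge_membership(354, bridges)$bridge, "B7a")
  expect_equal(bridge_membership(100, bridges)$status, "none")
  # structural neighborhood: adjacent residue within the proximity cutoff
  sp <- duplex_spec(c("G", "C", "A"), c("C", "G", "U"), rep("WC", 3),
                    resno1 = 334:336, resno2 = 420:418)
  d <- build_duplex(sp)
  br <- data.frame(bridge = "mB7", component = "12S", positions = "334",
                   stringsAsFactors = FALSE)
  got <- bridge_membership(335, br, model = d$model,
                           chain_map = c("12S" = "R"))
  expect_equal(got$status, "neighborhood")
})

test_that("atom retention tracks base chemistry across substitutions", {
  expect_true(atom_retained("O2'", "U", "C"))   # backbone untouched
  expect_true(atom_retained("OP1", "G", "A"))
  expect_true(atom_retained("O2", "U", "C"))    # shared acceptor
  expect_false(atom_retained("O4", "U", "C"))   # O4 absent in C
  expect_false(atom_retained("N2", "G", "A"))   # N2 absent in A
  expect_false(atom_retained("N1", "G", "A"))   # donor in G, acceptor in A
  expect_true(atom_retained("N7", "A", "G"))    # Hoogsteen acceptor kept
  expect_false(atom_retained("N6", "A", "G"))
})

test_that("evidence is a pure function of its inputs", {
  sc <- make_scenario("wc_disruption")
  ev1 <- collect_evidence(sc$variants$label[1], sc$model, sc$registries,
                          sc$map, annotations = as.list(sc$variants[1, ]))
  ev2 <- collect_evidence(sc$variants$label[1], sc$model, sc$registries,
                          sc$map, annotations = as.list(sc$variants[1, ]))
  expect_identical(ev1, ev2)
  expect_equal(ev1$pairing$disruption, "disruptive")
  expect_true(ev1$pairing_in_map)
})

test_that("probe-chain proximity reaches evidence at the planted tier", {
  # WC-disrupting variant with a flagged probe protein placed at 3.5 A
  sc <- make_scenario("wc_disruption")
  model <- attach_probe(sc$model, "R:152", 3.5)
  reg <- sc$registries
  reg$chain_map <- c("12S" = "R", "PROBE" = "P")
  reg$proteins <- data.frame(name = "PROBE", fidelity_protein = 0L,
                             early_binding = 1L,
                             harbors_pathogenic_mutations = 0L,
                             notable_residues = "", stringsAsFactors = FALSE)
  ev <- collect_evidence(sc$variants$label[1], model, reg, sc$map,
                         annotations = as.list(sc$variants[1, ]))
  expect_true(ev$quat_altered)      # packing-tier contact
  expect_true(ev$prox)
  # attribution includes the pair partner and sequence neighbors, so the
  # reported contact can only be as close or closer than the planted gap
  ctc <- ev$contacts[ev$contacts$name == "PROBE", ]
  expect_lte(ctc$distance, 3.51)
  expect_true(tier_within(ctc$tier, "packing"))
  vd <- decide_verdict(ev)
  expect_equal(vd$verdict, "non_silent")
  expect_setequal(vd$categories, c("SEC", "QUAT", "PROX"))
})

test_that("unmodeled variant positions yield disorder evidence", {
  sc <- make_scenario("wc_disruption")
  ev <- collect_evidence("m.810A>G", sc$model, sc$registries, sc$map)
  expect_true(ev$annotations$disorder)
  expect_null(ev$pairing)
  expect_equal(ev$ter_direct, 0L)
})

test_that("removing a registry entry does not change other entries' evidence", {
  sc <- make_scenario("ligand_contact")
  model <- attach_probe(sc$model, "R:151", 5.0)
  reg <- sc$registries
  reg$chain_map <- c(reg$chain_map, PROBE = "P")
  reg$proteins <- data.frame(name = "PROBE", fidelity_protein = 0L,
                             early_binding = 1L,
                             harbors_pathogenic_mutations = 0L,
                             notable_residues = "", stringsAsFactors = FALSE)
  ev_full <- collect_evidence(sc$variants$label[1], model, reg, sc$map,
                              annotations = as.list(sc$variants[1, ]))
  reg2 <- reg
  reg2$ligands <- reg$ligands[0, , drop = FALSE]
  ev_cut <- collect_evidence(sc$variants$label[1], model, reg2, sc$map,
                             annotations = as.list(sc$variants[1, ]))
  probe_full <- ev_full$contacts[ev_full$contacts$name == "PROBE", ]
  probe_cut <- ev_cut$contacts[ev_cut$contacts$name == "PROBE", ]
  expect_equal(probe_cut$distance, probe_full$distance)
  expect_equal(probe_cut$tier, probe_full$tier)
})
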