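mk_variant <- function(label = "m.1557A>C") {
  v <- parse_variant_label(label)
  gc <- genome_to_gene(v$position)
  list(label = dual_label(v), gene = gc$gene, gene_pos = gc$position,
       genomic_pos = v$position, ref = v$ref, alt = v$alt,
       subunit = if (gc$gene == "MT-RNR1") "SSU" else "LSU")
}

test_that("category codes follow the evidence, and may co-occur", {
  v <- mk_variant("m.669U>C")
  sec_only <- structural_evidence(
    v, pairing = predict_substitution(22, "U", "C", "A"),
    pairing_in_map = TRUE)
  expect_equal(assign_categories(sec_only), "SEC")

  both <- structural_evidence(
    v, pairing = predict_substitution(22, "U", "C", "A"),
    pairing_in_map = TRUE, prox = TRUE)
  expect_setequal(assign_categories(both), c("SEC", "PROX"))

  empty <- structural_evidence(mk_variant("m.801A>G"))
  expect_equal(assign_categories(empty), character(0))

  # disrupted pair absent from the secondary map counts as tertiary
  tert_pair <- structural_evidence(
    v, pairing = predict_substitution(579, "C", "G", "G"),
    pairing_in_map = FALSE)
  expect_equal(assign_categories(tert_pair), "TER")
})

test_that("verdict rules fire in precedence order with auditable traces", {
  # decoding-site ligand contact: non-silent
  lig <- structural_evidence(mk_variant("m.1557A>C"), lig_affected = TRUE)
  v1 <- decide_verdict(lig)
  expect_equal(v1$verdict, "non_silent")
  expect_match(paste(v1$rationale, collapse = " "), "ligand")

  # water-mediated base interaction only + heterologous equivalent: silent
  wat <- structural_evidence(mk_variant("m.710U>C"), ter_water = 1L,
                             annotations = list(heterologous_tolerated = TRUE))
  expect_equal(decide_verdict(wat)$verdict, "silent")

  # no base hydrogen bonds + heterologous equivalent: silent
  none <- structural_evidence(mk_variant("m.1193U>C"),
                              annotations = list(heterologous_tolerated = TRUE))
  expect_equal(decide_verdict(none)$verdict, "silent")

  # disordered position with no other evidence: unclear
  dis <- structural_evidence(mk_variant("m.1118A>G"),
                             annotations = list(disorder = TRUE))
  expect_equal(decide_verdict(dis)$verdict, "unclear")

  # disorder with hard evidence: the evidence wins
  dis2 <- structural_evidence(mk_variant("m.930G>A"), quat_base = 1L,
                              prox = TRUE,
                              annotations = list(disorder = TRUE))
  expect_equal(decide_verdict(dis2)$verdict, "non_silent")

  # bridge membership alone is non-silent; neighborhood alone is not
  br <- structural_evidence(mk_variant("m.1503G>A"),
                            bridge_status = "member", bridge_name = "mB5")
  expect_equal(decide_verdict(br)$verdict, "non_silent")
  brn <- structural_evidence(mk_variant("m.1537C>U"),
                             bridge_status = "neighborhood",
                             bridge_name = "mB5")
  expect_equal(decide_verdict(brn)$verdict, "unclear")
  # ... unless a pairing change sits inside the bridge region
  brp <- structural_evidence(
    mk_variant("m.1008A>G"),
    pairing = predict_substitution(361, "A", "G", "U"),
    pairing_in_map = TRUE, bridge_status = "neighborhood",
    bridge_name = "mB7")
  expect_equal(decide_verdict(brp)$verdict, "non_silent")
})

test_that("adding disruptive evidence never keeps a silent variant silent", {
  base <- structural_evidence(mk_variant("m.1452U>C"),
                              pairing = predict_substitution(
                                805, "U", "C", "G", old_class = "wobble"),
                              pairing_in_map = TRUE)
  expect_equal(decide_verdict(base)$verdict, "silent")
  for (field in c("ter_direct", "quat_base")) {
    ev <- base; ev[[field]] <- 1L
    expect_equal(decide_verdict(ev)$verdict, "non_silent", info = field)
  }
  ev <- base; ev$lig_affected <- TRUE
  expect_equal(decide_verdict(ev)$verdict, "non_silent")
  ev <- base; ev$bridge_status <- "member"; ev$bridge_name <- "mB5"
  expect_equal(decide_verdict(ev)$verdict, "non_silent")
})

test_that("curated table carries the documented cohort composition", {
  tab <- curated_variants()
  expect_equal(nrow(tab), 92L)
  expect_equal(sum(tab$subunit == "SSU"), 83L)
  expect_equal(sum(tab$subunit == "LSU"), 9L)
  ssu <- tab[tab$subunit == "SSU", ]
  expect_equal(sum(ssu$source == "literature"), 80L)
  expect_equal(sum(ssu$source == "MITOMAP"), 2L)
  expect_equal(sum(ssu$source == "this_work"), 1L)
  expect_equal(length(unique(tab$study[tab$source == "literature"])), 35L)
  expect_true(all(tab$provenance %in% c("text", "inferred")))
  # all labels parse and map into the right gene
  for (k in seq_len(nrow(tab))) {
    gc <- genome_to_gene(parse_variant_label(tab$genomic_label[k])$position)
    expect_equal(if (gc$gene == "MT-RNR1") "SSU" else "LSU",
                 tab$subunit[k], info = tab$genomic_label[k])
  }
})

test_that("replay reproduces every curated verdict row-for-row", {
  rp <- replay_pipeline()
  expect_equal(rp$verdict, rp$table_verdict)
  # non-silent rows always carry at least one category code
  ns <- rp[rp$verdict == "non_silent", ]
  expect_true(all(nzchar(ns$categories)))
  s <- summarize_verdicts(rp)
  expect_equal(s$non_silent + s$silent + s$unclear, s$n)
})

test_that("pipeline reports are deterministic and error rows do not abort runs", {
  sc <- make_scenario("wc_disruption")
  variants <- rbind(sc$variants,
                    .scenario_variant_row <- data.frame(
                      label = "m.5000A>G", haplotype_marker = 0L,
                      frequency_count = NA_integer_,
                      frequency_total = NA_integer_,
                      heterologous_equiv_base = NA_character_,
                      disorder_flag = 0L, stringsAsFactors = FALSE))
  res <- run_pipeline(variants, sc$model, sc$registries, sc$map)
  expect_equal(nrow(res$verdicts), 1L)
  expect_equal(nrow(res$errors), 1L)
  expect_match(res$errors$error[1], "rRNA")

  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  write_triage_report(res, d1)
  write_triage_report(run_pipeline(variants, sc$model, sc$registries,
                                   sc$map), d2)
  expect_identical(readLines(file.path(d1, "verdicts.tsv")),
                   readLines(file.path(d2, "verdicts.tsv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
})
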