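test_that("pair classification follows base identity and bond count", {
  expect_equal(classify_pair("G", "C", 3L), "watson_crick")
  expect_equal(classify_pair("A", "U", 2L), "watson_crick")
  expect_equal(classify_pair("G", "U", 2L), "wobble")
  expect_equal(classify_pair("U", "G", 1L), "wobble")
  expect_equal(classify_pair("C", "A", 1L), "mismatch")
  expect_equal(classify_pair("C", "A", 2L), "non_canonical")
  expect_equal(classify_pair("G", "C", 1L), "mismatch")
  expect_error(classify_pair("G", "X", 2L))
})

test_that("detection recovers exactly the planted pairing of every duplex", {
  set.seed(5)
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (trial in 1:10) {
    n <- sample(4:7, 1)
    s1 <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    s2 <- unname(comp[s1]); pt <- rep("WC", n)
    k <- which(s1 %in% c("G", "U"))[1]
    if (!is.na(k)) {
      s2[k] <- ifelse(s1[k] == "G", "U", "G"); pt[k] <- "wobble"
    }
    d <- build_duplex(duplex_spec(s1, s2, pt, resno1 = 100 + 1:n,
                                  resno2 = 300 - 1:n + 1))
    pr <- detect_base_pairs(d$model, "R")
    truth <- d$truth
    expect_equal(nrow(pr), nrow(truth))
    got <- paste(pr$resno_i, pr$resno_j, pr$class)
    want <- paste(truth$resno_i, truth$resno_j, truth$class)
    expect_setequal(got, want)
  }
})

test_that("single-stranded chains and non-RNA chains are handled", {
  sp <- duplex_spec(c("G", "A", "U"), c(NA, NA, NA), rep("unpaired", 3))
  d <- build_duplex(sp)
  expect_equal(nrow(detect_base_pairs(d$model, "R")), 0L)
  m <- attach_probe(d$model, "R:2", 6)
  expect_error(detect_base_pairs(m, "P"), "non-RNA")
})

test_that("substitution effects follow the isostericity rules", {
  # Watson-Crick -> mismatch is disruptive
  e <- predict_substitution(22, "U", "C", "A")
  expect_equal(e$old_class, "watson_crick")
  expect_equal(e$new_class, "mismatch")
  expect_equal(e$disruption, "disruptive")

  # WC -> wobble internal tolerated, terminal disruptive
  expect_equal(predict_substitution(145, "C", "U", "G")$disruption,
               "tolerated")
  expect_equal(predict_substitution(145, "C", "U", "G",
                                    terminal = TRUE)$disruption,
               "disruptive")

  # wobble -> mismatch disruptive; wobble -> WC tolerated
  expect_equal(predict_substitution(533, "U", "G", "G",
                                    old_class = "wobble")$disruption,
               "disruptive")
  expect_equal(predict_substitution(791, "G", "A", "U",
                                    old_class = "wobble")$disruption,
               "tolerated")

  # tandem wobble: disruptive next to an adjacent wobble, context-dependent
  # when the adjacent pair's state depends on the haplotype allele
  tl <- predict_substitution(806, "A", "G", "U",
                             neighbor_classes = c("805" = "wobble"))
  expect_equal(tl$disruption, "disruptive")
  expect_match(tl$notes, "tandem")
  ctx <- predict_substitution(806, "A", "G", "U",
                              neighbor_classes = c("805" = "wobble"),
                              neighbor_alt_classes = c("805" = "watson_crick"))
  expect_equal(ctx$disruption, "context_dependent")
  expect_equal(ctx$resolved, "disruptive")

  # native mismatch stabilized into a canonical pair is disruptive
  oto <- predict_substitution(847, "C", "U", "A", old_class = "mismatch")
  expect_equal(oto$new_class, "watson_crick")
  expect_equal(oto$disruption, "disruptive")

  # unpaired positions defer to the tertiary-bond machinery
  expect_equal(predict_substitution(400, "A", "G", NA)$old_class, "none")
})

test_that("double substitution restores the original pair class", {
  bases <- c("A", "C", "G", "U")
  for (ref in bases) for (alt in setdiff(bases, ref))
    for (partner in bases) {
      fwd <- predict_substitution(1, ref, alt, partner)
      back <- predict_substitution(1, alt, ref, partner,
                                   old_class = fwd$new_class)
      expect_equal(back$new_class, fwd$old_class,
                   info = paste(ref, alt, partner))
    }
})

test_that("secondary/tertiary partition is exhaustive, disjoint and map-driven", {
  d <- build_duplex(fix_duplex_mixed())
  pr <- detect_base_pairs(d$model, "R")
  map <- data.frame(i = c(101, 102, 103), j = c(206, 205, 204),
                    helix = "h1", terminal = 0L)
  part <- partition_interactions(pr, hbonds = NULL, map = map)
  expect_equal(nrow(part$secondary) + nrow(part$tertiary), nrow(pr))
  expect_true(all(part$secondary$resno_i %in% map$i))
  expect_true(all(!(part$tertiary$resno_i %in% map$i)))
  # all pairs in the map: empty tertiary set
  full_map <- data.frame(i = d$truth$resno_i, j = d$truth$resno_j,
                         helix = "h1", terminal = 0L)
  expect_equal(nrow(partition_interactions(pr, map = full_map)$tertiary), 0L)
})

test_that("GNRA consensus matches G-N-R-A exactly", {
  expect_true(is_gnra("GCAA"))
  expect_true(is_gnra(c("G", "U", "G", "A")))
  expect_false(is_gnra("ACAA"))   # G position broken
  expect_false(is_gnra("GCCA"))   # R position pyrimidine
  expect_false(is_gnra("GCAG"))
  expect_error(is_gnra("GCA"), "4 bases")
})

test_that("secondary map files read in both dialects", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("i\tj\thelix\tterminal", "5\t20\th1\t1", "6\t19\th1\t0"), tsv)
  m1 <- read_secondary_map(tsv)
  expect_equal(nrow(m1), 2L)
  expect_equal(m1$terminal, c(1L, 0L))

  ct <- tempfile(fileext = ".ct")
  writeLines(c("6 synthetic",
               "1 G 0 2 6 1", "2 C 1 3 5 2", "3 A 2 4 0 3",
               "4 U 3 5 0 4", "5 G 4 6 2 5", "6 C 5 0 1 6"), ct)
  m2 <- read_secondary_map(ct)
  expect_equal(nrow(m2), 2L)
  expect_setequal(paste(m2$i, m2$j), c("1 6", "2 5"))

  expect_null(map_pair_of(m1, 7))
  expect_equal(map_pair_of(m1, 20)$i, 5)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("i\tj", "5\t20", "5\t21"), dup)
  expect_error(read_secondary_map(dup), "more than one")
})
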