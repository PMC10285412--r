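test_that("donor/acceptor chemistry tables are as expected", {
  g <- donors_acceptors("G", c("N1", "N2", "N3", "N7", "O6", "C2", "C6",
                               "C1'", "O2'"))
  expect_true(all(c("O6", "N3", "N7") %in% g$acceptors))
  expect_true(all(c("N1", "N2") %in% names(g$donors)))
  expect_false("N1" %in% g$acceptors)

  w <- donors_acceptors("HOH", "O")
  expect_true("O" %in% names(w$donors))
  expect_true("O" %in% w$acceptors)
  expect_true(is.na(w$donors[["O"]]))    # no antecedent: angle test skipped

  r <- donors_acceptors("ARG", c("N", "CA", "C", "O", "NE", "NH1", "NH2",
                                 "CZ", "CD"))
  expect_true(all(c("NE", "NH1", "NH2") %in% names(r$donors)))
  expect_identical(setdiff(r$acceptors, c("O", "OXT")), character(0))

  expect_warning(donors_acceptors("XYZ", c("C1", "C2")), "no hydrogen-bond")
})

test_that("ideal pairs present exactly their canonical bond inventories", {
  d <- build_duplex(fix_duplex_mixed())
  hb <- find_hbonds(d$model)
  count_pair <- function(i, j) {
    n <- 0L
    for (k in seq_len(nrow(hb))) {
      dd <- parse_address(hb$donor[k]); aa <- parse_address(hb$acceptor[k])
      if (setequal(c(dd$resno, aa$resno), c(i, j)) &&
          is_base_atom(d$model, hb$donor[k]) &&
          is_base_atom(d$model, hb$acceptor[k])) n <- n + 1L
    }
    n
  }
  expect_equal(count_pair(101, 206), 3L)  # G:C
  expect_equal(count_pair(102, 205), 2L)  # A:U
  expect_equal(count_pair(105, 202), 2L)  # G-U wobble
  expect_equal(count_pair(106, 201), 2L)  # U-G wobble
  # and nothing beyond the planted inventory anywhere in the duplex
  planted <- vapply(seq_len(nrow(hb)), function(k) {
    dd <- parse_address(hb$donor[k]); aa <- parse_address(hb$acceptor[k])
    any(d$truth$resno_i == min(dd$resno, aa$resno) &
          d$truth$resno_j == max(dd$resno, aa$resno))
  }, logical(1))
  expect_true(all(planted))
})

test_that("planted mismatches present at most one base-base bond", {
  sp <- duplex_spec(c("G", "C", "A", "C"), c("C", "G", "U", "A"),
                    c("WC", "WC", "WC", "mismatch"),
                    resno1 = 1:4, resno2 = 8:5)
  d <- build_duplex(sp)
  expect_equal(d$truth$n_bonds[d$truth$class == "mismatch"], 0L)
})

test_that("detection is monotone in both tolerances", {
  d <- build_duplex(fix_duplex_mixed())
  key <- function(hb) paste(hb$donor, hb$acceptor)
  tight_d <- find_hbonds(d$model, params = hbond_params(distance_slop = 0.2))
  loose_d <- find_hbonds(d$model, params = hbond_params(distance_slop = 0.4))
  expect_true(all(key(tight_d) %in% key(loose_d)))
  tight_a <- find_hbonds(d$model, params = hbond_params(angle_slop = 5))
  loose_a <- find_hbonds(d$model, params = hbond_params(angle_slop = 20))
  expect_true(all(key(tight_a) %in% key(loose_a)))
  wider <- find_hbonds(d$model, params = hbond_params(distance_slop = 0.8,
                                                      angle_slop = 40))
  expect_true(all(key(loose_d) %in% key(wider)))
})

test_that("bond inventory is invariant under rigid motion of the model", {
  d <- build_duplex(fix_duplex_mixed())
  hb1 <- find_hbonds(d$model)
  hb2 <- find_hbonds(rigid_move(d$model, 123, "x", c(20, 5, -9)))
  expect_equal(nrow(hb2), nrow(hb1))
  expect_equal(hb2$donor, hb1$donor)
  expect_equal(hb2$distance, hb1$distance, tolerance = 1e-9)
})

test_that("water bridges are reported iff a water reaches both partners", {
  d <- build_duplex(fix_duplex_gc4())
  # no waters: empty
  expect_equal(nrow(find_water_bridges(d$model)), 0L)
  # planted bridge between two base nitrogens of different residues
  m <- add_bridging_water(d$model, "R:1:N7", "R:2:N7", dist = 3.3)
  wb <- find_water_bridges(m)
  expect_gte(nrow(wb), 1L)
  hit <- any(grepl("R:1:N7", paste(wb$donor, wb$acceptor)) &
               grepl("R:2:N7", paste(wb$donor, wb$acceptor)))
  expect_true(hit)
  expect_true(all(wb$kind == "water_mediated"))
  # water within range of one partner only: no bridge between the pair
  at <- d$model$atom
  i <- which(at$atom == "OP1" & at$resno == 4L)
  lone <- rbind(at, data.frame(chain = "W", resno = 1L, resid = "HOH",
                               atom = "O", element = "O",
                               x = at$x[i] + 2.6, y = at$y[i], z = at$z[i],
                               occ = 1, stringsAsFactors = FALSE))
  wb2 <- find_water_bridges(structure_model(lone))
  expect_false(any(grepl("R:4:OP1", paste(wb2$donor, wb2$acceptor)) &
                     grepl("R:1:", paste(wb2$donor, wb2$acceptor))))
  expect_error(add_bridging_water(d$model, "R:1:N7", "R:4:OP1", 2.8),
               "cannot both")
})
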