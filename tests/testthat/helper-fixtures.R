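# Shared fixture builders: everything is generated in code at test time.

fix_duplex_mixed <- function(jitter = 0, seed = 1L) {
  duplex_spec(c("G", "A", "U", "C", "G", "U"),
              c("C", "U", "A", "G", "U", "G"),
              pair_types = c("WC", "WC", "WC", "WC", "wobble", "wobble"),
              resno1 = 101:106, resno2 = 206:201,
              seed = seed, jitter = jitter)
}

fix_duplex_gc4 <- function() {
  duplex_spec(c("G", "G", "C", "C"), c("C", "C", "G", "G"),
              rep("WC", 4), resno1 = 1:4, resno2 = 8:5)
}

# independently coded closed-form Kabsch oracle (quaternion-free SVD route,
# written against the textbook formulation, separate from the package code)
oracle_kabsch_rmsd <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  s <- svd(t(Q0) %*% P0)
  d <- sign(det(s$u %*% t(s$v)))
  lam <- s$d; lam[3] <- lam[3] * d
  e0 <- sum(P0^2) + sum(Q0^2)
  sqrt(max(0, (e0 - 2 * sum(lam)) / nrow(P)))
}

# brute-force minimum heavy-atom distance oracle (double loop)
oracle_min_dist <- function(model, chain_a, resno_a, chain_b) {
  at <- model$atom
  A <- at[at$chain == chain_a & at$resno == resno_a &
            toupper(at$element) != "H", , drop = FALSE]
  B <- at[at$chain == chain_b & toupper(at$element) != "H" &
            at$resid != "HOH", , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
    if (d < best) best <- d
  }
  best
}

rigid_move <- function(model, angle_deg = 90, axis = "z",
                       shift = c(5, -3, 2)) {
  a <- angle_deg * pi / 180
  R <- switch(axis,
              z = matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3),
              x = matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3))
  xyz <- as.matrix(model$atom[, c("x", "y", "z")]) %*% R
  out <- model
  out$atom$x <- xyz[, 1] + shift[1]
  out$atom$y <- xyz[, 2] + shift[2]
  out$atom$z <- xyz[, 3] + shift[3]
  out
}
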