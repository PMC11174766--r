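# Small fixture builders; everything is generated in code at test time.

# fixed-width ATOM lines for a CA trace with given B-factors
ca_pdb_lines <- function(coords, b, resname = "ALA", chain = "A",
                         resno = seq_len(nrow(coords)), occ = rep(1, nrow(coords))) {
  sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          seq_len(nrow(coords)), resname, chain, resno,
          coords[, 1], coords[, 2], coords[, 3], occ, b)
}

# evenly spaced straight-ish CA trace (3.8 A steps along x with a small kink
# in y so it is not collinear)
test_trace <- function(L) {
  cbind(3.8 * seq_len(L), 0.5 * sin(seq_len(L)), 0.3 * cos(2 * seq_len(L)))
}

# quick synthetic structure: a seeded small fold
quick_structure <- function(id, L = 40, seed = 1) {
  seg <- data.frame(type = c("helix", "coil", "helix"),
                    length = c(ceiling(L * 0.4), ceiling(L * 0.2),
                               L - ceiling(L * 0.4) - ceiling(L * 0.2)))
  protein_structure(id, make_fold(seg, seed))
}

random_proper_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_copy <- function(coords, seed) {
  set.seed(seed)
  R <- random_proper_rotation(seed)
  sweep(coords %*% t(R), 2, -runif(3, -15, 15))
}
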