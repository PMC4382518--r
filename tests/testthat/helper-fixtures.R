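# Shared fixtures, built in code at test time.

toy_kturn <- function()
  parse_kturn("GGCGAAGAACC", "GGUGAUCGCC", loop_start = 3, name = "toy")

# Minimal Stockholm alignment: rows are b strand + n strand of the Kt-7
# template with the 3b/3n columns carrying the stated pairs.
write_toy_stockholm <- function(path, pairs = c("AG", "GC", "CG")) {
  kts <- lapply(seq_along(pairs), function(i) {
    k <- substitute_pair(kt7_kturn(), substr(pairs[i], 1, 1),
                         substr(pairs[i], 2, 2))
    k$name <- sprintf("row%d", i)
    k
  })
  write_cohort_stockholm(kts, path)
  invisible(kts)
}

# Chi-square goodness of fit with cells of expectation < 5 pooled into the
# smallest adequate cell (classical validity rule for the approximation).
pooled_chisq_p <- function(obs, probs, n) {
  expected <- probs * n
  keep <- expected >= 5
  if (any(!keep)) {
    sink_cell <- which(keep)[which.min(expected[keep])]
    obs[sink_cell] <- obs[sink_cell] + sum(obs[!keep])
    probs[sink_cell] <- probs[sink_cell] + sum(probs[!keep])
    obs <- obs[keep]; probs <- probs[keep]
  }
  stats::chisq.test(obs, p = probs)$p.value
}

# Random rigid-body transform (proper rotation + translation).
random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = stats::rnorm(3, sd = 20))
}

apply_rigid <- function(atoms, tf) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(tf$R)
  atoms$x <- xyz[, 1] + tf$t[1]
  atoms$y <- xyz[, 2] + tf$t[2]
  atoms$z <- xyz[, 3] + tf$t[3]
  atoms
}
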