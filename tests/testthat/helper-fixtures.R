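# Shared helpers for the test suite.  Everything is generated in code;
# no binary fixtures.

# A small hand-written variant table (already parsed form).
tinyVariants <- function() {
  mk <- function(sample, gene, label, iso, source = "cohort",
                 stage = "MIBC") {
    ch <- parseProteinChange(label, iso)
    data.frame(sample_id = sample, cohort = "TST", stage = stage,
               gene = gene, ref_aa = ch$ref_aa, position = ch$position,
               alt_aa = ch$alt_aa, isoform = iso, label = ch$label,
               source = source, stringsAsFactors = FALSE)
  }
  rbind(mk("s1", "PPARG", "T475M", "PPARG2"),
        mk("s2", "PPARG", "T475M", "PPARG2"),
        mk("s3", "PPARG", "T475M", "PPARG2", stage = "NMIBC"),
        mk("s4", "PPARG", "T475M", "PPARG2"),
        mk("s5", "PPARG", "E3K", "PPARG2"),
        mk("db1", "PPARG", "E3K", "PPARG2", source = "external_db",
           stage = "unknown"),
        mk("s6", "PPARG", "M280I", "PPARG2"))
}

# Random admissible 2x2 tables with total at most n_max.
rand2x2 <- function(n_max = 40) {
  repeat {
    cells <- as.integer(rmultinom(1, sample.int(n_max, 1), rep(0.25, 4)))
    return(matrix(cells, 2))
  }
}

# Brute-force interface oracle: plain double loops over atom pairs,
# sharing no code with the package implementation.
bruteInterfaceSets <- function(model, chain_a, chain_b, cutoff) {
  a <- atomTable(model)
  pa <- a[a$chain == chain_a & !a$het, , drop = FALSE]
  pb <- a[a$chain == chain_b & !a$het, , drop = FALSE]
  set_a <- integer(); set_b <- integer()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      d <- sqrt((pa$x[i] - pb$x[j])^2 + (pa$y[i] - pb$y[j])^2 +
                (pa$z[i] - pb$z[j])^2)
      if (d <= cutoff) {
        set_a <- union(set_a, pa$resno[i])
        set_b <- union(set_b, pb$resno[j])
      }
    }
  }
  list(a = sort(set_a), b = sort(set_b))
}

# Brute-force residue-residue minimum distance oracle.
bruteMinDist <- function(model, chain_a, res_a, chain_b, res_b) {
  a <- atomTable(model)
  pa <- a[a$chain == chain_a & a$resno == res_a & !a$het, , drop = FALSE]
  pb <- a[a$chain == chain_b & a$resno == res_b & !a$het, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(pa)))
    for (j in seq_len(nrow(pb)))
      best <- min(best, sqrt((pa$x[i] - pb$x[j])^2 +
                             (pa$y[i] - pb$y[j])^2 +
                             (pa$z[i] - pb$z[j])^2))
  best
}

# Apply a random rigid-body transform (rotation + translation).
rigidTransform <- function(model, seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t <- rnorm(3, sd = 20)
  a <- atomTable(model)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + t[1]; a$y <- xyz[, 2] + t[2]; a$z <- xyz[, 3] + t[3]
  structureModel(a, source = "transformed")
}
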