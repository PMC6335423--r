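#' @importFrom stats rnorm rbinom runif
NULL

#' Specification for a synthetic tumor cohort
#'
#' Defaults mirror the magnitudes of the bladder-tumor series the
#' analysis targets: 359 tumors, a 55/45 NMIBC/MIBC split, a PPARG
#' point-mutation rate around 4%, amplification around 7%, a luminal-like
#' subgroup of 45% and strong enrichment of alterations in it (odds
#' ratio 8).
#'
#' @param n_samples number of tumors.
#' @param stage_fractions named fractions over NMIBC/MIBC (must sum to 1).
#' @param background_mutation_rate named per-gene rate of non-hotspot
#'   (singleton) mutations.
#' @param recurrent_positions data.frame `gene`, `label`, `isoform`,
#'   `count`: hotspot changes planted at exactly `count` samples each.
#' @param amplification_rate fraction of samples with the focal
#'   amplification.
#' @param subgroup_fraction fraction of samples in the subgroup
#'   (e.g. luminal / activation-high).
#' @param alteration_subgroup_odds_ratio conditional odds ratio coupling
#'   alteration status to subgroup membership.
#' @param protein_length named per-gene protein length used when drawing
#'   background positions.
#' @param seed RNG seed.
#' @return validated spec (list, class `CohortSimSpec`).
#' @export
cohortSimSpec <- function(n_samples = 359L,
                          stage_fractions = c(NMIBC = 0.55, MIBC = 0.45),
                          background_mutation_rate = c(PPARG = 0.02),
                          recurrent_positions = data.frame(
                            gene = "PPARG", label = "T475M",
                            isoform = "PPARG2", count = 4L),
                          amplification_rate = 0.07,
                          subgroup_fraction = 0.45,
                          alteration_subgroup_odds_ratio = 8,
                          protein_length = c(PPARG = 505L, RXRA = 462L),
                          seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               stage_fractions = stage_fractions,
               background_mutation_rate = background_mutation_rate,
               recurrent_positions = recurrent_positions,
               amplification_rate = amplification_rate,
               subgroup_fraction = subgroup_fraction,
               alteration_subgroup_odds_ratio = alteration_subgroup_odds_ratio,
               protein_length = protein_length,
               seed = as.integer(seed))
  class(spec) <- "CohortSimSpec"
  if (spec$n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  if (abs(sum(stage_fractions) - 1) > 1e-8)
    stop("stage_fractions must sum to 1", call. = FALSE)
  rates <- c(background_mutation_rate, amplification_rate,
             subgroup_fraction)
  if (any(rates < 0) || any(rates > 1))
    stop("rates and fractions must lie in [0, 1]", call. = FALSE)
  if (alteration_subgroup_odds_ratio <= 0)
    stop("odds ratio must be positive", call. = FALSE)
  if (nrow(recurrent_positions)) {
    tot <- tapply(recurrent_positions$count, recurrent_positions$gene, sum)
    if (any(tot > spec$n_samples))
      stop("recurrent target counts exceed n_samples", call. = FALSE)
  }
  spec
}

# Solve the two Bernoulli rates (subgroup p1, rest p0) from the overall
# alteration rate r, subgroup fraction f and odds ratio psi:
#   f*p1 + (1-f)*p0 = r,   p1/(1-p1) = psi * p0/(1-p0)
# Substituting gives the quadratic
#   (1-f)(psi-1) p0^2 + [f*psi + (1-f) + r(1-psi)] p0 - r = 0
# whose root in (0,1) is taken; psi = 1 collapses to p0 = p1 = r.
solveCoupledRates <- function(r, f, psi) {
  stopifnot(r >= 0, r <= 1, f > 0, f < 1, psi > 0)
  if (r == 0) return(c(p_subgroup = 0, p_rest = 0))
  if (abs(psi - 1) < 1e-12) return(c(p_subgroup = r, p_rest = r))
  A <- (1 - f) * (psi - 1)
  B <- f * psi + (1 - f) + r * (1 - psi)
  C <- -r
  disc <- B^2 - 4 * A * C
  p0 <- (-B + sqrt(disc)) / (2 * A)
  if (p0 < 0 || p0 > 1) p0 <- (-B - sqrt(disc)) / (2 * A)
  p1 <- psi * p0 / (1 - p0 + psi * p0)
  c(p_subgroup = p1, p_rest = p0)
}

# Draw the number of altered samples falling in the subgroup from
# Fisher's noncentral hypergeometric distribution (fixed margins, odds
# ratio `odds`): the exact conditional model behind the 2x2 test.
.rNoncentralHyper <- function(m_sub, m_rest, n_draw, odds) {
  if (n_draw == 0L) return(0L)
  k <- max(0L, n_draw - m_rest):min(n_draw, m_sub)
  if (length(k) == 1L) return(k)
  logw <- lchoose(m_sub, k) + lchoose(m_rest, n_draw - k) + k * log(odds)
  w <- exp(logw - max(logw))
  sample(k, 1L, prob = w)
}

.randomChange <- function(n, protein_len, forbid = integer()) {
  pos <- integer(0)
  while (length(pos) < n) {
    cand <- sample.int(protein_len, n - length(pos), replace = TRUE)
    pos <- c(pos, cand[!cand %in% forbid])
  }
  ref <- sample(.AA1, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.AA1, r), 1L), character(1))
  paste0(ref, pos, alt)
}

#' Simulate a tumor cohort with planted hotspots and subgroup coupling
#'
#' Per gene, the altered sample set has size equal to the planted hotspot
#' counts plus a binomial number of background (singleton) mutations; how
#' many altered samples fall inside the subgroup is drawn from Fisher's
#' noncentral hypergeometric distribution at the spec's odds ratio, so
#' the expected alteration-vs-subgroup log odds ratio equals the spec
#' value (exactly zero-centered at odds ratio 1).  Hotspot changes
#' receive exactly their target counts.  Amplified samples are drawn with
#' the same subgroup coupling.
#'
#' @param spec a [cohortSimSpec()].
#' @return list with `mutations` (variant data.frame), `amplifications`
#'   (`sample_id`, `gene`), `samples` (`sample_id`, `cohort`, `stage`,
#'   `subgroup`), and `truth` (latent assignments: subgroup members,
#'   altered and amplified samples per gene, coupling parameters).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSimSpec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ids <- sprintf("SIM%04d", seq_len(n))
  n_stage <- round(spec$stage_fractions * n)
  n_stage[1] <- n - sum(n_stage[-1])
  stage <- sample(rep(names(spec$stage_fractions), n_stage))
  n_sub <- round(spec$subgroup_fraction * n)
  subgroup <- sample(ids, n_sub)
  psi <- spec$alteration_subgroup_odds_ratio

  genes <- union(names(spec$background_mutation_rate),
                 unique(spec$recurrent_positions$gene))
  mut_rows <- list()
  truth_altered <- list()
  for (g in genes) {
    recs <- spec$recurrent_positions[spec$recurrent_positions$gene == g, ,
                                     drop = FALSE]
    n_rec <- if (nrow(recs)) sum(recs$count) else 0L
    bgr <- spec$background_mutation_rate[[g]]
    if (is.null(bgr)) bgr <- 0
    n_bg <- rbinom(1L, n - n_rec, bgr)
    n_alt <- n_rec + n_bg
    k_sub <- .rNoncentralHyper(n_sub, n - n_sub, n_alt, psi)
    altered <- c(sample(subgroup, k_sub),
                 sample(setdiff(ids, subgroup), n_alt - k_sub))
    altered <- altered[sample.int(length(altered))]  # shuffle before labels
    labels <- character(0)
    iso <- "PPARG2"
    if (nrow(recs)) {
      labels <- rep(recs$label, recs$count)
      iso <- recs$isoform[1]
    }
    plen <- spec$protein_length[[g]]
    if (is.null(plen)) plen <- 505L
    forbid <- if (nrow(recs))
      parseProteinChange(recs$label, iso)$position else integer()
    labels <- c(labels, .randomChange(n_bg, plen, forbid))
    if (n_alt > 0L) {
      ch <- parseProteinChange(labels, iso)
      # one mutation per altered sample; parseProteinChange keeps order
      mut_rows[[g]] <- data.frame(
        sample_id = altered, cohort = "SIM",
        stage = stage[match(altered, ids)], gene = g,
        ref_aa = ch$ref_aa, position = ch$position, alt_aa = ch$alt_aa,
        isoform = ch$isoform, label = ch$label, source = "cohort",
        stringsAsFactors = FALSE)
    }
    truth_altered[[g]] <- altered
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows)
               else data.frame()
  rownames(mutations) <- NULL

  n_amp <- rbinom(1L, n, spec$amplification_rate)
  k_amp_sub <- .rNoncentralHyper(n_sub, n - n_sub, n_amp, psi)
  amplified <- c(sample(subgroup, k_amp_sub),
                 sample(setdiff(ids, subgroup), n_amp - k_amp_sub))
  amp_gene <- genes[1]
  amplifications <- data.frame(sample_id = amplified,
                               gene = rep(amp_gene, length(amplified)),
                               stringsAsFactors = FALSE)

  samples <- data.frame(sample_id = ids, cohort = "SIM", stage = stage,
                        subgroup = ids %in% subgroup,
                        stringsAsFactors = FALSE)
  rates <- solveCoupledRates(
    r = max(1e-9, mean(samples$sample_id %in% unlist(truth_altered))),
    f = spec$subgroup_fraction, psi = psi)
  list(mutations = mutations, amplifications = amplifications,
       samples = samples,
       truth = list(subgroup = sort(subgroup),
                    altered = lapply(truth_altered, sort),
                    amplified = sort(amplified),
                    coupled_rates = rates, odds_ratio = psi,
                    seed = spec$seed))
}

#' Specification for a synthetic expression matrix
#'
#' Log-scale expression: every gene is i.i.d. normal noise per sample;
#' signature genes gain `effect_size * noise_sd` in activation-high
#' samples; an anchor gene (default `"PPARG"`) is shifted by
#' `anchor_coupling * noise_sd` in the same samples so that ranking by
#' anchor expression recovers the high group, emulating
#' receptor-expression-driven pathway activation.
#'
#' @param n_genes number of background genes (the anchor is added on top).
#' @param n_samples number of samples.
#' @param n_signature_genes number of genes carrying the activation shift.
#' @param effect_size shift in SD units (default 2).
#' @param activation_high_fraction fraction of activation-high samples.
#' @param noise_sd per-gene noise SD on the log scale (default 1).
#' @param anchor_coupling anchor shift in SD units (default 3).
#' @param anchor_gene anchor gene id.
#' @param seed RNG seed.
#' @return validated spec (list, class `ExpressionSimSpec`).
#' @export
expressionSimSpec <- function(n_genes = 500L, n_samples = 200L,
                              n_signature_genes = 10L, effect_size = 2,
                              activation_high_fraction = 0.25,
                              noise_sd = 1, anchor_coupling = 3,
                              anchor_gene = "PPARG", seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               n_signature_genes = as.integer(n_signature_genes),
               effect_size = effect_size,
               activation_high_fraction = activation_high_fraction,
               noise_sd = noise_sd, anchor_coupling = anchor_coupling,
               anchor_gene = anchor_gene, seed = as.integer(seed))
  class(spec) <- "ExpressionSimSpec"
  if (spec$n_signature_genes > spec$n_genes)
    stop("n_signature_genes exceeds n_genes", call. = FALSE)
  if (spec$effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (spec$activation_high_fraction <= 0 ||
      spec$activation_high_fraction >= 1)
    stop("activation_high_fraction must lie in (0, 1)", call. = FALSE)
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  spec
}

#' Simulate an expression matrix with a planted activation signature
#'
#' @param spec an [expressionSimSpec()].
#' @return list with `expr` (matrix, genes x samples, anchor gene
#'   included as last row) and `truth` (signature genes, activation-high
#'   samples, spec echo).
#' @export
simulateExpression <- function(spec) {
  stopifnot(inherits(spec, "ExpressionSimSpec"))
  set.seed(spec$seed)
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  n_high <- round(spec$activation_high_fraction * spec$n_samples)
  high <- sort(sample(samples, n_high))
  sig <- sort(sample(genes, spec$n_signature_genes))
  m <- matrix(rnorm(spec$n_genes * spec$n_samples, sd = spec$noise_sd),
              nrow = spec$n_genes, dimnames = list(genes, samples))
  shift <- spec$effect_size * spec$noise_sd
  m[sig, high] <- m[sig, high] + shift
  anchor <- rnorm(spec$n_samples, sd = spec$noise_sd) +
    spec$anchor_coupling * spec$noise_sd * (samples %in% high)
  expr <- rbind(m, matrix(anchor, nrow = 1,
                          dimnames = list(spec$anchor_gene, samples)))
  list(expr = expr,
       truth = list(signature_genes = sig, high_samples = high,
                    spec = spec))
}

# Ideal helix coordinates: rise 1.5 A and 100 degrees per residue on a
# 2.3 A radius, the textbook alpha-helix geometry.
.helixCoords <- function(n_res, radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(n_res) - 1L
  ang <- i * twist * pi / 180
  cbind(x = radius * cos(ang), y = radius * sin(ang), z = i * rise)
}

#' Build a toy two-chain helical heterodimer with a known interface
#'
#' Two ideal poly-alanine helices (CA and CB atoms) run parallel along z,
#' chain B offset along x so that the closest heavy-atom approach between
#' the chains is about `inter_chain_gap`.  The ground-truth interface set
#' is computed at construction by brute-force double loop over all
#' heavy-atom pairs, so downstream interface code can be checked against
#' an object whose answer is known by construction.
#'
#' @param n_residues_per_chain residues per helix (default 20).
#' @param inter_chain_gap closest approach between the chains, Angstrom.
#' @param seed RNG seed for the optional coordinate jitter.
#' @param jitter_sd SD of Gaussian coordinate noise (default 0, ideal
#'   geometry).
#' @param truth_cutoff cutoff used for the stored truth interface
#'   (default 5.0 A).
#' @return list with `model` ([StructureModel-class]) and `truth`
#'   (interface residue numbers per chain at `truth_cutoff`).
#' @export
makeToyHeterodimer <- function(n_residues_per_chain = 20L,
                               inter_chain_gap = 4, seed = 1L,
                               jitter_sd = 0, truth_cutoff = 5.0) {
  if (inter_chain_gap <= 0)
    stop("inter_chain_gap must be positive", call. = FALSE)
  if (n_residues_per_chain < 1L)
    stop("need at least one residue per chain", call. = FALSE)
  set.seed(seed)
  radius <- 2.3
  ca <- .helixCoords(n_residues_per_chain, radius = radius)
  # CB 1.5 A further out along the radial direction
  cb <- ca
  scale <- (radius + 1.5) / radius
  cb[, "x"] <- ca[, "x"] * scale
  cb[, "y"] <- ca[, "y"] * scale
  mk_chain <- function(coords_ca, coords_cb, chain) {
    n <- nrow(coords_ca)
    data.frame(
      chain = chain,
      resno = rep(seq_len(n), each = 2L),
      insert = "", resid = "ALA",
      elety = rep(c("CA", "CB"), n),
      element = "C",
      x = as.vector(rbind(coords_ca[, 1], coords_cb[, 1])),
      y = as.vector(rbind(coords_ca[, 2], coords_cb[, 2])),
      z = as.vector(rbind(coords_ca[, 3], coords_cb[, 3])),
      het = FALSE, stringsAsFactors = FALSE)
  }
  a <- mk_chain(ca, cb, "A")
  # chain B mirrored in x and shifted so the CB shells face each other
  sep <- inter_chain_gap + 2 * (radius + 1.5)
  cab <- ca; cbb <- cb
  cab[, "x"] <- -cab[, "x"] + sep
  cbb[, "x"] <- -cbb[, "x"] + sep
  b <- mk_chain(cab, cbb, "B")
  atoms <- rbind(a, b)
  if (jitter_sd > 0) {
    atoms$x <- atoms$x + rnorm(nrow(atoms), sd = jitter_sd)
    atoms$y <- atoms$y + rnorm(nrow(atoms), sd = jitter_sd)
    atoms$z <- atoms$z + rnorm(nrow(atoms), sd = jitter_sd)
  }
  model <- .newStructureModel(atoms, source = "toy_heterodimer")
  # brute-force truth: plain double loop over residue pairs
  truth_a <- integer(); truth_b <- integer()
  for (ra in seq_len(n_residues_per_chain)) {
    for (rb in seq_len(n_residues_per_chain)) {
      pa <- atoms[atoms$chain == "A" & atoms$resno == ra, c("x", "y", "z")]
      pb <- atoms[atoms$chain == "B" & atoms$resno == rb, c("x", "y", "z")]
      dmin <- Inf
      for (i in seq_len(nrow(pa)))
        for (j in seq_len(nrow(pb)))
          dmin <- min(dmin, sqrt(sum((pa[i, ] - pb[j, ])^2)))
      if (dmin <= truth_cutoff) {
        truth_a <- union(truth_a, ra)
        truth_b <- union(truth_b, rb)
      }
    }
  }
  list(model = model,
       truth = list(chain_a = sort(truth_a), chain_b = sort(truth_b),
                    cutoff = truth_cutoff))
}
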