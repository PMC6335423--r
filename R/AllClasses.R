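#' @import methods
NULL

#' IsoformMap: translate residue numbering between protein isoforms
#'
#' A signed-offset map between two numbering frames of the same protein,
#' e.g. PPARG1 -> PPARG2 with offset +28 (the gamma-2 isoform carries 28
#' extra N-terminal residues).  Positions that would fall below
#' `min_valid_target` after shifting are isoform-specific and reported as
#' unmappable, never clamped.
#'
#' @slot from_isoform,to_isoform identifiers of the source and target
#'   numbering frames.
#' @slot offset signed residue offset added to source positions.
#' @slot min_valid_target lowest mappable target position (default 1).
#' @export
setClass("IsoformMap",
  representation(
    from_isoform = "character",
    to_isoform = "character",
    offset = "integer",
    min_valid_target = "integer"
  ),
  prototype(min_valid_target = 1L)
)

setValidity("IsoformMap", function(object) {
  msg <- character()
  if (length(object@from_isoform) != 1L || !nzchar(object@from_isoform))
    msg <- c(msg, "'from_isoform' must be a single non-empty string")
  if (length(object@to_isoform) != 1L || !nzchar(object@to_isoform))
    msg <- c(msg, "'to_isoform' must be a single non-empty string")
  if (length(object@offset) != 1L || is.na(object@offset))
    msg <- c(msg, "'offset' must be a single integer")
  if (length(object@min_valid_target) != 1L || is.na(object@min_valid_target) ||
      object@min_valid_target < 1L)
    msg <- c(msg, "'min_valid_target' must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' DomainMap: protein domain architecture in one numbering frame
#'
#' Ordered, non-overlapping domain spans (1-based inclusive residue
#' coordinates) plus point landmarks (e.g. phosphorylation sites) for one
#' gene/isoform, used to annotate mutated positions.
#'
#' @slot gene gene symbol.
#' @slot isoform numbering frame the coordinates refer to.
#' @slot domains data.frame with columns `name`, `start`, `end`.
#' @slot landmarks data.frame with columns `name`, `position`.
#' @slot protein_length total protein length in this frame.
#' @export
setClass("DomainMap",
  representation(
    gene = "character",
    isoform = "character",
    domains = "data.frame",
    landmarks = "data.frame",
    protein_length = "integer"
  )
)

setValidity("DomainMap", function(object) {
  msg <- character()
  d <- object@domains
  if (!all(c("name", "start", "end") %in% names(d)))
    msg <- c(msg, "'domains' needs columns name, start, end")
  else {
    if (any(d$start > d$end)) msg <- c(msg, "domain start must be <= end")
    if (any(d$start < 1L)) msg <- c(msg, "domain coordinates are 1-based")
    if (nrow(d) > 1L) {
      o <- order(d$start)
      if (any(d$end[o][-nrow(d)] >= d$start[o][-1L]))
        msg <- c(msg, "domains must not overlap")
    }
    if (length(object@protein_length) == 1L && nrow(d) &&
        max(d$end) > object@protein_length)
      msg <- c(msg, "domain extends beyond protein length")
  }
  l <- object@landmarks
  if (!all(c("name", "position") %in% names(l)))
    msg <- c(msg, "'landmarks' needs columns name, position")
  else if (nrow(l) && length(object@protein_length) == 1L &&
           (any(l$position < 1L) || any(l$position > object@protein_length)))
    msg <- c(msg, "landmark positions must lie inside the protein")
  if (length(object@protein_length) != 1L || is.na(object@protein_length) ||
      object@protein_length < 1L)
    msg <- c(msg, "'protein_length' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' AssociationResult: a 2x2 exact-test result
#'
#' Holds the contingency table (rows: alteration present/absent; columns:
#' group member/non-member), the two-sided exact p-value obtained by
#' hypergeometric enumeration, the raw cross-product odds ratio and a
#' direction call.  Zero-cell odds ratios are reported as 0 or Inf with
#' `zero_cell = TRUE`; no continuity correction is ever applied.
#'
#' @slot table 2x2 integer matrix of counts.
#' @slot p_two_sided two-sided exact p-value in (0, 1].
#' @slot odds_ratio (a*d)/(b*c); may be 0, Inf or NaN (flagged).
#' @slot direction one of "co_occurrence", "exclusivity", "none".
#' @slot zero_cell TRUE when the odds ratio involved a zero cell.
#' @slot degenerate TRUE when a margin was all zero (p fixed at 1).
#' @export
setClass("AssociationResult",
  representation(
    table = "matrix",
    p_two_sided = "numeric",
    odds_ratio = "numeric",
    direction = "character",
    zero_cell = "logical",
    degenerate = "logical"
  )
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (!identical(dim(object@table), c(2L, 2L)))
    msg <- c(msg, "'table' must be 2x2")
  if (any(object@table < 0)) msg <- c(msg, "counts must be non-negative")
  p <- object@p_two_sided
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1 + 1e-12)
    msg <- c(msg, "'p_two_sided' must lie in (0, 1]")
  if (!object@direction %in% c("co_occurrence", "exclusivity", "none"))
    msg <- c(msg, "invalid 'direction'")
  if (length(msg)) msg else TRUE
})

#' SignatureDefinition: a refined activation-signature gene set
#'
#' Result of the quartile-contrast refinement: the seed genes, the subset
#' retained after a one-sided differential test between anchor-high and
#' anchor-low sample bins with Benjamini-Hochberg correction, seed genes
#' absent from the matrix, and the parameters used.
#'
#' @slot seed_genes,refined_genes,missing_genes character vectors.
#' @slot stats per-gene data.frame: gene, p, adj_p, retained.
#' @slot anchor_gene gene whose expression ranks the samples.
#' @slot quartile fraction of samples in each contrast bin.
#' @slot alpha BH-adjusted significance level.
#' @slot test "wilcoxon" or "welch".
#' @export
setClass("SignatureDefinition",
  representation(
    seed_genes = "character",
    refined_genes = "character",
    missing_genes = "character",
    stats = "data.frame",
    anchor_gene = "character",
    quartile = "numeric",
    alpha = "numeric",
    test = "character"
  )
)

setValidity("SignatureDefinition", function(object) {
  msg <- character()
  if (!all(object@refined_genes %in% object@seed_genes))
    msg <- c(msg, "'refined_genes' must be a subset of 'seed_genes'")
  if (length(object@quartile) != 1L || object@quartile <= 0 ||
      object@quartile > 0.5)
    msg <- c(msg, "'quartile' must lie in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' SignatureScoreResult: per-sample activation scores
#'
#' Per-sample activation score (mean over the signature genes of their
#' centered log expression) together with the signature and centering used.
#'
#' @slot scores named numeric, one score per sample.
#' @slot centering "gene_mean" or "gene_median".
#' @slot signature_genes genes averaged into the score.
#' @slot signature the `SignatureDefinition` behind the gene set (may be
#'   an empty placeholder when a plain gene vector was scored).
#' @export
setClass("SignatureScoreResult",
  representation(
    scores = "numeric",
    centering = "character",
    signature_genes = "character",
    signature = "SignatureDefinition"
  )
)

setValidity("SignatureScoreResult", function(object) {
  msg <- character()
  if (is.null(names(object@scores)) || anyNA(object@scores))
    msg <- c(msg, "'scores' must be a named numeric vector without NA")
  if (!object@centering %in% c("gene_mean", "gene_median"))
    msg <- c(msg, "'centering' must be gene_mean or gene_median")
  if (length(msg)) msg else TRUE
})

#' StructureModel: chains, residues and heavy-atom coordinates
#'
#' A light container for one model of a protein structure: an atom table
#' with chain, residue number/insertion code, residue and atom names and
#' Cartesian coordinates in Angstrom.  Hydrogens and waters are removed at
#' construction; HETATM ligand atoms are retained but flagged (`het`) and
#' excluded from residue distance queries unless requested.
#'
#' @slot atoms data.frame: chain, resno, insert, resid, elety, element,
#'   x, y, z, het.
#' @slot source file of origin (may be empty for generated models).
#' @slot model_index which MODEL of the source file this is.
#' @export
setClass("StructureModel",
  representation(
    atoms = "data.frame",
    source = "character",
    model_index = "integer"
  )
)

setValidity("StructureModel", function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "het")
  if (!all(need %in% names(a)))
    msg <- c(msg, paste("'atoms' needs columns:", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msg <- c(msg, "coordinates must be finite")
    poly <- a[!a$het, , drop = FALSE]
    if (nrow(poly) == 0L)
      msg <- c(msg, "no polymer residues")
  }
  if (length(msg)) msg else TRUE
})

#' InterfaceReport: residues at a two-chain interface
#'
#' Residues of each chain whose minimum heavy-atom distance to the partner
#' chain does not exceed the cutoff.
#'
#' @slot chain_a,chain_b the chain pair.
#' @slot cutoff distance cutoff in Angstrom.
#' @slot residues_a,residues_b data.frames: resno, insert, resid, min_dist.
#' @export
setClass("InterfaceReport",
  representation(
    chain_a = "character",
    chain_b = "character",
    cutoff = "numeric",
    residues_a = "data.frame",
    residues_b = "data.frame"
  )
)

setValidity("InterfaceReport", function(object) {
  msg <- character()
  if (object@cutoff <= 0) msg <- c(msg, "'cutoff' must be positive")
  for (s in c("residues_a", "residues_b")) {
    d <- slot(object, s)
    if (nrow(d) && any(d$min_dist > object@cutoff + 1e-9))
      msg <- c(msg, sprintf("'%s' contains residues beyond the cutoff", s))
  }
  if (length(msg)) msg else TRUE
})
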