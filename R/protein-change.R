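#' @importFrom stats setNames
NULL

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse protein-change labels such as "T475M"
#'
#' Parses one or more mutation labels written in the conventional
#' `<ref><position><alt>` protein notation (e.g. `"T475M"`).  Multi-allele
#' hotspot labels such as `"S427F/Y"` expand into one row per alternate
#' allele.  Positions are 1-based residue indices in the stated isoform
#' numbering frame.
#'
#' @param label character vector of labels.
#' @param isoform identifier of the numbering frame the labels use
#'   (e.g. `"PPARG2"`).
#' @return data.frame with columns `ref_aa`, `position`, `alt_aa`,
#'   `isoform`, `label` (one row per allele).
#' @examples
#' parseProteinChange("T475M", "PPARG2")
#' parseProteinChange("S427F/Y", "RXRA")
#' @export
parseProteinChange <- function(label, isoform) {
  stopifnot(is.character(label), length(label) >= 1L,
            is.character(isoform), length(isoform) == 1L, nzchar(isoform))
  out <- lapply(label, function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z])([0-9]+)([A-Za-z](?:/[A-Za-z])*)$",
                                 lab))[[1]]
    if (length(m) == 0L)
      stop("malformed protein-change label: '", lab, "'", call. = FALSE)
    ref <- toupper(m[2])
    pos <- as.integer(m[3])
    alts <- toupper(strsplit(m[4], "/", fixed = TRUE)[[1]])
    bad <- setdiff(c(ref, alts), .AA1)
    if (length(bad))
      stop("invalid amino-acid code '", bad[1], "' in label '", lab, "'",
           call. = FALSE)
    if (pos < 1L)
      stop("position must be >= 1 in label '", lab, "'", call. = FALSE)
    if (any(alts == ref))
      stop("reference and alternate residues are identical in '", lab, "'",
           call. = FALSE)
    data.frame(ref_aa = ref, position = pos, alt_aa = alts,
               isoform = isoform,
               label = paste0(ref, pos, alts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render parsed protein changes back to labels
#'
#' Inverse of [parseProteinChange()]: `parseProteinChange(renderProteinChange(x),
#' iso)` reproduces `x` row for row.
#'
#' @param change data.frame as returned by [parseProteinChange()].
#' @return character vector of labels.
#' @export
renderProteinChange <- function(change) {
  stopifnot(all(c("ref_aa", "position", "alt_aa") %in% names(change)))
  paste0(change$ref_aa, change$position, change$alt_aa)
}

#' Construct an isoform numbering map
#'
#' @param from_isoform,to_isoform frame identifiers.
#' @param offset signed residue offset added when mapping from -> to.
#' @param min_valid_target lowest position that exists in the target frame;
#'   shifted positions below it are isoform-specific and unmappable.
#' @return an [IsoformMap-class] object.
#' @examples
#' isoformMap("PPARG1", "PPARG2", offset = 28)
#' @export
isoformMap <- function(from_isoform, to_isoform, offset,
                       min_valid_target = 1L) {
  new("IsoformMap", from_isoform = from_isoform, to_isoform = to_isoform,
      offset = as.integer(offset),
      min_valid_target = as.integer(min_valid_target))
}

#' Invert an isoform map
#'
#' @param map an [IsoformMap-class].
#' @param min_valid_target lowest valid position of the new target frame
#'   (default 1).
#' @return the reversed map (offset negated).
#' @export
invertIsoformMap <- function(map, min_valid_target = 1L) {
  isoformMap(map@to_isoform, map@from_isoform, -map@offset, min_valid_target)
}

#' Harmonize protein changes into another isoform numbering frame
#'
#' Shifts positions by the map offset.  Changes whose shifted position
#' falls below `min_valid_target` of the target frame (residues that do
#' not exist in the shorter isoform, e.g. PPARG2 E3K viewed from PPARG1)
#' are returned with `mappable = FALSE` and reason `"isoform_specific"`;
#' they are never clamped or dropped.
#'
#' @param change data.frame of changes (from [parseProteinChange()]); all
#'   rows must be in the map's source frame.
#' @param map an [IsoformMap-class].
#' @return the input with `position`, `isoform` and `label` rewritten in
#'   the target frame plus columns `mappable` (logical) and `reason`
#'   (`NA` or `"isoform_specific"`).  Unmappable rows keep `position = NA`.
#' @examples
#' g1 <- parseProteinChange("T447M", "PPARG1")
#' harmonizeIsoform(g1, isoformMap("PPARG1", "PPARG2", 28))
#' @export
harmonizeIsoform <- function(change, map) {
  stopifnot(is(map, "IsoformMap"))
  if (!all(change$isoform == map@from_isoform))
    stop("isoform frame mismatch: changes are not in frame '",
         map@from_isoform, "'", call. = FALSE)
  newpos <- change$position + map@offset
  ok <- newpos >= map@min_valid_target
  out <- change
  out$position <- ifelse(ok, newpos, NA_integer_)
  out$isoform <- map@to_isoform
  out$mappable <- ok
  out$reason <- ifelse(ok, NA_character_, "isoform_specific")
  out$label[ok] <- paste0(out$ref_aa[ok], out$position[ok], out$alt_aa[ok])
  out$label[!ok] <- paste0(change$label[!ok], ":", map@from_isoform,
                           "_specific")
  out
}

#' Construct a domain map
#'
#' @param gene gene symbol.
#' @param isoform numbering frame of the coordinates.
#' @param domains data.frame `name`, `start`, `end` (1-based inclusive,
#'   non-overlapping).
#' @param landmarks optional data.frame `name`, `position`.
#' @param protein_length protein length in this frame.
#' @return a [DomainMap-class].
#' @export
domainMap <- function(gene, isoform, domains,
                      landmarks = data.frame(name = character(),
                                             position = integer()),
                      protein_length) {
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (nrow(landmarks)) landmarks$position <- as.integer(landmarks$position)
  new("DomainMap", gene = gene, isoform = isoform, domains = domains,
      landmarks = landmarks, protein_length = as.integer(protein_length))
}

#' Built-in domain architecture of human PPARgamma (gamma-2 numbering)
#'
#' Domain spans for the 505-residue PPARgamma-2 protein.  The
#' ligand-binding domain span (231-505) corresponds to the commonly used
#' LBD construct; the N-terminal (A/B) and DNA-binding domain boundaries
#' follow standard nuclear-receptor annotation and can be overridden with
#' a user-supplied [domainMap()] or YAML config (see
#' [readDomainConfig()]).  Landmarks mark the MAPK phosphosite S112 and
#' the CDK5 phosphosite S273.
#'
#' @return a [DomainMap-class] for gene PPARG, isoform PPARG2.
#' @export
ppargDomainMap <- function() {
  domainMap(
    gene = "PPARG", isoform = "PPARG2",
    domains = data.frame(
      name = c("A/B", "DBD", "LBD"),
      start = c(1L, 136L, 231L),
      end = c(135L, 206L, 505L)),
    landmarks = data.frame(name = c("S112", "S273"),
                           position = c(112L, 273L)),
    protein_length = 505L)
}

#' Built-in domain architecture of human RXRalpha
#'
#' Standard nuclear-receptor annotation for the 462-residue RXRalpha
#' protein; overridable like [ppargDomainMap()].
#'
#' @return a [DomainMap-class] for gene RXRA.
#' @export
rxraDomainMap <- function() {
  domainMap(
    gene = "RXRA", isoform = "RXRA",
    domains = data.frame(
      name = c("A/B", "DBD", "LBD"),
      start = c(1L, 135L, 225L),
      end = c(134L, 200L, 462L)),
    landmarks = data.frame(name = character(), position = integer()),
    protein_length = 462L)
}

#' Read domain maps from a YAML config
#'
#' The config is a list of entries with fields `gene`, `isoform`,
#' `protein_length`, `domains` (each `name`/`start`/`end`) and optional
#' `landmarks` (each `name`/`position`).  See
#' `system.file("extdata", "domains.yaml", package = "ppargmut")`.
#'
#' @param path YAML file.
#' @return named list of [DomainMap-class] objects, keyed by gene.
#' @export
readDomainConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  maps <- lapply(cfg, function(e) {
    dom <- do.call(rbind, lapply(e$domains, function(d)
      data.frame(name = d$name, start = d$start, end = d$end,
                 stringsAsFactors = FALSE)))
    lm <- if (is.null(e$landmarks))
      data.frame(name = character(), position = integer())
    else do.call(rbind, lapply(e$landmarks, function(d)
      data.frame(name = d$name, position = d$position,
                 stringsAsFactors = FALSE)))
    domainMap(e$gene, e$isoform, dom, lm, e$protein_length)
  })
  setNames(maps, vapply(maps, function(m) m@gene, character(1)))
}

#' Annotate positions with their protein domain
#'
#' Returns, for each position, the unique domain whose inclusive span
#' contains it, or `"linker"` for inter-domain positions.
#'
#' @param position integer vector of 1-based residue positions, or a
#'   change data.frame with a `position` column (its `isoform` must match
#'   the map's).
#' @param dm a [DomainMap-class].
#' @return character vector of domain names.
#' @examples
#' annotateDomain(c(3, 164, 475), ppargDomainMap())
#' @export
annotateDomain <- function(position, dm) {
  stopifnot(is(dm, "DomainMap"))
  if (is.data.frame(position)) {
    if ("isoform" %in% names(position) &&
        !all(position$isoform == dm@isoform))
      stop("changes are not in the domain map's isoform frame '",
           dm@isoform, "'", call. = FALSE)
    position <- position$position
  }
  position <- as.integer(position)
  if (anyNA(position))
    stop("cannot annotate NA positions (unmappable changes?)", call. = FALSE)
  if (any(position < 1L) || any(position > dm@protein_length))
    stop("position outside protein length (1-", dm@protein_length, ")",
         call. = FALSE)
  d <- dm@domains
  vapply(position, function(p) {
    hit <- which(d$start <= p & p <= d$end)
    if (length(hit)) d$name[hit] else "linker"
  }, character(1))
}
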