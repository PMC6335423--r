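.WATERS <- c("HOH", "WAT", "DOD", "H2O")

# Is an atom a hydrogen?  Prefer the element symbol; fall back to the
# PDB atom-name convention (H*, or digit followed by H).
.isHydrogen <- function(element, elety) {
  el <- toupper(trimws(element))
  byel <- el %in% c("H", "D")
  noel <- !nzchar(el)
  nm <- toupper(trimws(elety))
  byname <- grepl("^[0-9]?[HD]", nm)
  ifelse(noel, byname, byel)
}

.newStructureModel <- function(atoms, source = "", model_index = 1L) {
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, source = source,
      model_index = as.integer(model_index))
}

#' Build a structure model from an atom table
#'
#' Programmatic constructor, mainly for generated or hand-specified
#' coordinates.  Missing `insert`/`element`/`het` columns are filled
#' with defaults.
#'
#' @param atoms data.frame with at least `chain`, `resno`, `resid`,
#'   `elety`, `x`, `y`, `z`.
#' @param source free-text provenance tag.
#' @return a [StructureModel-class].
#' @export
structureModel <- function(atoms, source = "constructed") {
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$element)) atoms$element <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  .newStructureModel(atoms[c("chain", "resno", "insert", "resid", "elety",
                             "element", "x", "y", "z", "het")],
                     source = source)
}

#' Read a structure model from a PDB file
#'
#' Loads one MODEL of a PDB-format file (via bio3d) into a
#' [StructureModel-class].  Hydrogens and waters are dropped; alternate
#' locations are resolved to the highest-occupancy conformer (ties go to
#' altloc "A"); HETATM ligand atoms are kept but flagged `het` and
#' excluded from residue distance queries unless requested.
#'
#' @param path PDB file.
#' @param model_index which MODEL to load (default 1, the first).
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, model_index = 1L) {
  if (!file.exists(path))
    stop("cannot read PDB file: ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not parseable as PDB: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod)) nmod <- 1L
  if (model_index < 1L || model_index > nmod)
    stop("model index ", model_index, " absent (file has ", nmod,
         " model(s))", call. = FALSE)
  at <- pdb$atom
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = ifelse(is.na(at$elesy), "", at$elesy),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    het = at$type == "HETATM",
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  atoms <- atoms[!atoms$resid %in% .WATERS, , drop = FALSE]
  atoms <- atoms[!.isHydrogen(atoms$element, atoms$elety), , drop = FALSE]
  # altloc: keep highest occupancy per (chain, residue, atom name); tie -> 'A'
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 sep = "\r")
    ord <- order(key, -atoms$occ, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  }
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert), , drop = FALSE]
  if (!any(!atoms$het))
    stop("no polymer residues in ", path, call. = FALSE)
  .newStructureModel(atoms[c("chain", "resno", "insert", "resid", "elety",
                             "element", "x", "y", "z", "het")],
                     source = path, model_index = model_index)
}

#' Write a structure model as a PDB-format file
#'
#' Plain fixed-width ATOM/HETATM records with chain breaks marked by TER;
#' coordinates are written at the format's 3-decimal precision.
#'
#' @param model a [StructureModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStructurePdb <- function(model, path) {
  a <- atomTable(model)
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character()
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- a[a$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      serial <- serial + 1L
      rec <- if (rows$het[i]) "HETATM" else "ATOM  "
      nm <- rows$elety[i]
      nm <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "%s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial, nm, "", rows$resid[i], ch, rows$resno[i],
        substr(paste0(rows$insert[i], " "), 1, 1),
        rows$x[i], rows$y[i], rows$z[i], 1, 0,
        toupper(rows$element[i])))
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Heavy atoms of one residue; errors name the chain and residue number.
.resAtoms <- function(model, chain, resno, insert = "") {
  a <- atomTable(model)
  sel <- a$chain == chain & a$resno == resno & a$insert == insert & !a$het
  if (!any(sel))
    stop("residue ", resno, if (nzchar(insert)) insert,
         " not found in chain ", chain, call. = FALSE)
  a[sel, , drop = FALSE]
}

.coords <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# All pairwise Euclidean distances between two coordinate sets.
.crossDist <- function(p, q) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * tcrossprod(p, q)
  sqrt(pmax(d2, 0))
}

#' Minimum heavy-atom distance between two residues
#'
#' @param model a [StructureModel-class].
#' @param chain_a,res_a,chain_b,res_b the two residues (chain id plus
#'   residue number; insertion codes via `insert_a`/`insert_b`).
#' @param insert_a,insert_b insertion codes (default none).
#' @return distance in Angstrom.  Comparing a residue with itself
#'   returns 0 with attribute `self = TRUE`.
#' @export
residueMinDistance <- function(model, chain_a, res_a, chain_b, res_b,
                               insert_a = "", insert_b = "") {
  if (chain_a == chain_b && res_a == res_b && insert_a == insert_b) {
    .resAtoms(model, chain_a, res_a, insert_a)  # existence check
    return(structure(0, self = TRUE))
  }
  pa <- .coords(.resAtoms(model, chain_a, res_a, insert_a))
  pb <- .coords(.resAtoms(model, chain_b, res_b, insert_b))
  min(.crossDist(pa, pb))
}

# Per-residue index vector for fast residue-level aggregation.
.residueIndex <- function(atoms) {
  key <- paste(atoms$resno, atoms$insert, sep = "\r")
  u <- unique(key)
  list(idx = match(key, u),
       table = data.frame(
         resno = atoms$resno[match(u, key)],
         insert = atoms$insert[match(u, key)],
         resid = atoms$resid[match(u, key)],
         stringsAsFactors = FALSE))
}

#' Residues at the interface between two chains
#'
#' A residue of one chain is an interface residue when its minimum
#' heavy-atom distance to any residue of the partner chain does not
#' exceed the cutoff (default 5 A, a standard interface criterion).
#'
#' @param model a [StructureModel-class].
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return an [InterfaceReport-class].
#' @export
interfaceResidues <- function(model, chain_a, chain_b, cutoff = 5.0) {
  a <- atomTable(model)
  pa <- a[a$chain == chain_a & !a$het, , drop = FALSE]
  pb <- a[a$chain == chain_b & !a$het, , drop = FALSE]
  if (nrow(pa) == 0L) stop("chain ", chain_a, " not found", call. = FALSE)
  if (nrow(pb) == 0L) stop("chain ", chain_b, " not found", call. = FALSE)
  dm <- .crossDist(.coords(pa), .coords(pb))
  ia <- .residueIndex(pa)
  ib <- .residueIndex(pb)
  mina <- tapply(apply(dm, 1, min), ia$idx, min)
  minb <- tapply(apply(dm, 2, min), ib$idx, min)
  ra <- ia$table; ra$min_dist <- as.numeric(mina)
  rb <- ib$table; rb$min_dist <- as.numeric(minb)
  new("InterfaceReport", chain_a = chain_a, chain_b = chain_b,
      cutoff = cutoff,
      residues_a = ra[ra$min_dist <= cutoff, , drop = FALSE],
      residues_b = rb[rb$min_dist <= cutoff, , drop = FALSE])
}

#' Intra-chain contact partners of a residue
#'
#' Residues of the same chain within `cutoff` (minimum heavy-atom
#' distance, default 4.5 A) and at least `min_seq_sep` residues away in
#' sequence (default 3, suppressing trivial backbone neighbours), sorted
#' by distance.
#'
#' @param model a [StructureModel-class].
#' @param chain,res the query residue.
#' @param cutoff contact cutoff in Angstrom.
#' @param min_seq_sep minimum |resno difference|.
#' @param insert insertion code of the query residue.
#' @return data.frame: `chain`, `resno`, `insert`, `resid`, `min_dist`.
#' @export
contactPartners <- function(model, chain, res, cutoff = 4.5,
                            min_seq_sep = 3L, insert = "") {
  q <- .coords(.resAtoms(model, chain, res, insert))
  a <- atomTable(model)
  others <- a[a$chain == chain & !a$het &
              abs(a$resno - res) >= min_seq_sep, , drop = FALSE]
  if (nrow(others) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE))
  dm <- .crossDist(q, .coords(others))
  io <- .residueIndex(others)
  md <- as.numeric(tapply(apply(dm, 2, min), io$idx, min))
  out <- io$table
  out$min_dist <- md
  out <- out[out$min_dist <= cutoff, , drop = FALSE]
  out <- out[order(out$min_dist), , drop = FALSE]
  out <- cbind(chain = rep(chain, nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Map protein changes onto a structure model
#'
#' Annotates each mutated position with whether it is resolved in the
#' model, whether it lies at an inter-chain interface (minimum
#' heavy-atom distance to any other chain <= `interface_cutoff`), and its
#' intra-chain contact partners.  Positions absent from the model
#' (disordered, or outside the crystallized construct) are flagged
#' `resolved = FALSE`, never dropped.
#'
#' @param changes change data.frame (see [parseProteinChange()]).
#' @param model a [StructureModel-class].
#' @param chain_of_gene named character vector mapping gene -> chain id.
#' @param numbering_offset named integer vector per gene added to mutation
#'   positions to reach the model's residue numbering (default 0); reuse
#'   an [IsoformMap-class] offset when the frames differ.
#' @param interface_cutoff,contact_cutoff,min_seq_sep distance parameters
#'   (defaults 5.0 A, 4.5 A, 3).
#' @return data.frame: `gene`, `label`, `chain`, `model_resno`,
#'   `resolved`, `in_interface`, `interface_partner_chain`, `n_contacts`,
#'   `contacts` (comma-separated partner residue numbers).
#' @export
mapMutationsToStructure <- function(changes, model, chain_of_gene,
                                    numbering_offset = integer(),
                                    interface_cutoff = 5.0,
                                    contact_cutoff = 4.5,
                                    min_seq_sep = 3L) {
  if (nrow(changes) == 0L)
    return(data.frame(gene = character(), label = character(),
                      chain = character(), model_resno = integer(),
                      resolved = logical(), in_interface = logical(),
                      interface_partner_chain = character(),
                      n_contacts = integer(), contacts = character(),
                      stringsAsFactors = FALSE))
  gene_col <- if ("gene" %in% names(changes)) changes$gene
              else rep(names(chain_of_gene)[1], nrow(changes))
  chains <- chainIds(model)
  out <- lapply(seq_len(nrow(changes)), function(i) {
    g <- gene_col[i]
    if (!g %in% names(chain_of_gene))
      stop("no chain mapping for gene ", g, call. = FALSE)
    ch <- chain_of_gene[[g]]
    off <- if (g %in% names(numbering_offset)) numbering_offset[[g]] else 0L
    pos <- changes$position[i] + off
    a <- atomTable(model)
    resolved <- any(a$chain == ch & a$resno == pos & !a$het)
    in_if <- NA
    partner <- NA_character_
    ncont <- NA_integer_
    contacts <- NA_character_
    if (resolved) {
      others <- setdiff(chains, ch)
      in_if <- FALSE
      for (oc in others) {
        rep_if <- interfaceResidues(model, ch, oc, cutoff = interface_cutoff)
        if (pos %in% interfaceSet(rep_if, "a")) {
          in_if <- TRUE
          partner <- oc
          break
        }
      }
      cp <- contactPartners(model, ch, pos, cutoff = contact_cutoff,
                            min_seq_sep = min_seq_sep)
      ncont <- nrow(cp)
      contacts <- paste(cp$resno, collapse = ",")
    }
    data.frame(gene = g, label = changes$label[i], chain = ch,
               model_resno = pos, resolved = resolved, in_interface = in_if,
               interface_partner_chain = partner, n_contacts = ncont,
               contacts = contacts, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
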