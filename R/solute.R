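# Parameterized rigid solutes: PQR/PDB I/O and force-field assignment.
#
# PQR records carry charge + radius; Lennard-Jones sigma is derived from
# the radius (sigma = 2 r / 2^(1/6)) unless explicit LJ parameters are
# supplied.  Epsilon is not part of the PQR format, so the writer emits
# "REMARK LJEPS <serial> <epsilon>" lines that the reader recovers,
# making toy solutes round-trip losslessly.

#' Construct a parameterized rigid solute
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (residue name), `resno` (residue number), `chain`, `x`,
#'   `y`, `z` (Angstrom), `charge` (e), `sigma` (A), `epsilon`
#'   (kcal/mol), `radius` (vdW radius, A).
#' @param disulfides Optional data.frame of cysteine pairs with columns
#'   `resno1`, `resno2` (and optionally `chain1`, `chain2`).
#' @param provenance Named list recording source file / parameter set.
#' @return Object of class `solute_system`; `net_charge` is the sum of
#'   atomic charges.
#' @export
solute_system <- function(atoms, disulfides = NULL, provenance = list()) {
  need <- c("serial", "name", "element", "resid", "resno", "chain",
            "x", "y", "z", "charge", "sigma", "epsilon", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("empty solute: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$sigma < 0) || any(atoms$epsilon < 0) || any(atoms$radius < 0))
    stop("sigma, epsilon and vdw radius must be >= 0")
  if (!is.null(disulfides) && nrow(disulfides)) {
    if (any(disulfides$resno1 == disulfides$resno2))
      stop("a disulfide must pair two distinct residues")
  }
  structure(
    list(atoms = atoms, disulfides = disulfides,
         net_charge = sum(atoms$charge), provenance = provenance),
    class = "solute_system")
}

#' @export
print.solute_system <- function(x, ...) {
  cat(sprintf("<solute_system>  %d atoms, %d residues, net charge %+.4f e\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              x$net_charge))
  if (!is.null(x$disulfides) && nrow(x$disulfides))
    cat(sprintf("  %d disulfide pair(s)\n", nrow(x$disulfides)))
  invisible(x)
}

#' @keywords internal
element_from_name <- function(name) {
  # strip leading digits (PDB hydrogen conventions), take leading letters
  s <- sub("^[0-9]+", "", trimws(name))
  two <- toupper(substr(s, 1, 2))
  one <- toupper(substr(s, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "CA", "SE"),
         two, one)
}

#' Read a PQR file into a solute system
#'
#' @param path PQR file (PDB ATOM/HETATM records with charge and radius
#'   in the occupancy/B-factor columns).
#' @param default_epsilon LJ well depth (kcal/mol) used for atoms
#'   without a `REMARK LJEPS` entry.
#' @return A [solute_system()].
#' @export
read_pqr <- function(path, default_epsilon = 0.1521) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("empty solute: no ATOM/HETATM records in ", path)
  pdb <- tryCatch(bio3d::read.pqr(path),
                  error = function(e) {
                    bad <- grep("^(ATOM|HETATM)", lines)[1]
                    stop(sprintf("malformed PQR record near line %d of %s: %s",
                                 bad, path, conditionMessage(e)))
                  })
  a <- pdb$atom
  eps <- rep(default_epsilon, nrow(a))
  sig <- 2 * a$b / 2^(1 / 6)
  # recover shipped LJ parameters, if present
  rem <- lines[startsWith(lines, "REMARK LJEPS")]
  if (length(rem)) {
    for (ln in rem) {
      f <- strsplit(trimws(ln), " +")[[1]]
      i <- match(as.integer(f[3]), a$eleno)
      if (!is.na(i)) eps[i] <- as.numeric(f[4])
    }
  }
  rem <- lines[startsWith(lines, "REMARK LJSIG")]
  if (length(rem)) {
    for (ln in rem) {
      f <- strsplit(trimws(ln), " +")[[1]]
      i <- match(as.integer(f[3]), a$eleno)
      if (!is.na(i)) sig[i] <- as.numeric(f[4])
    }
  }
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  elem[is.na(elem) | elem == ""] <- element_from_name(a$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = elem,
    resid = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    charge = a$o, sigma = sig, epsilon = eps, radius = a$b,
    stringsAsFactors = FALSE)
  solute_system(atoms, provenance = list(source = path, format = "pqr"))
}

#' Write a solute system as PQR
#'
#' Standard PQR records plus `REMARK LJEPS` / `REMARK LJSIG` lines
#' carrying the Lennard-Jones parameters, so [read_pqr()] round-trips
#' the full parameterization.
#'
#' @param solute A [solute_system()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pqr <- function(solute, path) {
  a <- solute$atoms
  rem <- c(sprintf("REMARK LJEPS %d %.6f", a$serial, a$epsilon),
           sprintf("REMARK LJSIG %d %.6f", a$serial, a$sigma))
  recs <- sprintf(
    "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f %7.4f %7.4f",
    a$serial, substr(a$name, 1, 4), substr(a$resid, 1, 4), a$resno,
    a$x, a$y, a$z, a$charge, a$radius)
  writeLines(c(rem, recs, "END"), path)
  invisible(path)
}

#' Read a flat-text parameter table
#'
#' Whitespace-separated columns: `residue atom charge sigma epsilon
#' radius` (units e, A, kcal/mol, A).  Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_parameter_table <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("residue", "atom", "charge",
                                        "sigma", "epsilon", "radius"))
  tb
}

#' Read a PDB structure with disulfide records
#'
#' Thin wrapper around [bio3d::read.pdb()] that also parses `SSBOND`
#' records (bio3d does not expose them).
#'
#' @param path PDB file.
#' @param chain Optional chain selector (e.g. `"A"`).
#' @return List: `pdb` (bio3d object, possibly trimmed to `chain`),
#'   `ssbond` (data.frame `chain1`, `resno1`, `chain2`, `resno2`).
#' @export
read_pdb_structure <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  lines <- readLines(path)
  ss <- lines[startsWith(lines, "SSBOND")]
  ssbond <- if (length(ss)) {
    data.frame(
      chain1 = trimws(substr(ss, 16, 16)),
      resno1 = as.integer(substr(ss, 18, 21)),
      chain2 = trimws(substr(ss, 30, 30)),
      resno2 = as.integer(substr(ss, 32, 35)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(chain1 = character(), resno1 = integer(),
               chain2 = character(), resno2 = integer(),
               stringsAsFactors = FALSE)
  }
  if (!is.null(chain)) {
    sel <- bio3d::atom.select(pdb, chain = chain)
    pdb <- bio3d::trim.pdb(pdb, sel)
    ssbond <- ssbond[ssbond$chain1 == chain & ssbond$chain2 == chain, ,
                     drop = FALSE]
  }
  list(pdb = pdb, ssbond = ssbond)
}

#' Assign force-field parameters to a parsed structure
#'
#' Attaches charges, LJ parameters and vdW radii to every atom of a
#' (complete, hydrogenated) structure by `(residue name, atom name)`
#' lookup in a flat parameter table.  Protonation-variant residue names
#' are applied first (e.g. HIS -> HID per residue number), then
#' disulfide-bonded cysteines are retyped to the bridged form (`CYX`),
#' so the lookups hit the right entries.  Any unmatched atom raises an
#' error naming it — there are no silent defaults.
#'
#' @param structure A [read_pdb_structure()] result, a bio3d `pdb`
#'   object, or a PDB file path.
#' @param parameter_table data.frame from [read_parameter_table()].
#' @param protonation_spec Optional data.frame `resno`, `residue` giving
#'   per-residue protonation-variant names.
#' @param disulfides Optional data.frame `resno1`, `resno2`; defaults to
#'   the structure's SSBOND records when present.
#' @param cyx_name Residue name used for bridged cysteines in the table.
#' @return A [solute_system()].
#' @export
assign_parameters <- function(structure, parameter_table,
                              protonation_spec = NULL, disulfides = NULL,
                              cyx_name = "CYX") {
  if (is.character(structure)) structure <- read_pdb_structure(structure)
  if (inherits(structure, "pdb")) structure <- list(pdb = structure, ssbond = NULL)
  a <- structure$pdb$atom
  resid <- a$resid
  if (!is.null(protonation_spec) && nrow(protonation_spec)) {
    i <- match(a$resno, protonation_spec$resno)
    hit <- !is.na(i)
    resid[hit] <- protonation_spec$residue[i[hit]]
  }
  if (is.null(disulfides)) disulfides <- structure$ssbond
  if (!is.null(disulfides) && nrow(disulfides)) {
    bridged <- unique(c(disulfides$resno1, disulfides$resno2))
    sel <- a$resno %in% bridged & resid %in% c("CYS", "CYM", "CYX")
    resid[sel] <- cyx_name
  }
  key <- paste(resid, a$elety)
  tkey <- paste(parameter_table$residue, parameter_table$atom)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("missing parameters for: ", paste(bad, collapse = ", "))
  }
  p <- parameter_table[idx, ]
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  sel <- is.na(elem) | elem == ""
  elem[sel] <- element_from_name(a$elety[sel])
  atoms <- data.frame(
    serial = seq_len(nrow(a)), name = a$elety, element = elem,
    resid = resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    charge = p$charge, sigma = p$sigma, epsilon = p$epsilon,
    radius = p$radius, stringsAsFactors = FALSE)
  dis <- if (!is.null(disulfides) && nrow(disulfides)) {
    data.frame(resno1 = disulfides$resno1, resno2 = disulfides$resno2)
  } else NULL
  solute_system(atoms, disulfides = dis,
                provenance = list(parameter_set = "user-table",
                                  protonation = !is.null(protonation_spec)))
}
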