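# Charged-group heavy atoms considered for salt bridges
# (Barlow-Thornton-style criterion).
CATION_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                     HIS = c("ND1", "NE2"))
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA_CHARGE <- c(K = 1, R = 1, H = 1, D = -1, E = -1)

#' Parse ATOM records from PDB-format text
#'
#' Fixed-column PDB dialect: atom name in columns 13-16, residue name
#' 18-20, chain id 22, residue number 23-26, coordinates 31-54. HETATM and
#' ANISOU records are ignored; alternate locations other than blank or 'A'
#' are skipped.
#'
#' @param path Path to a PDB-format file, or a character vector of lines.
#' @return Data frame with `chain_id`, `residue_name`, `residue_number`,
#'   `atom_name`, `x`, `y`, `z`.
#' @export
parse_pdb_atoms <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  is_atom <- startsWith(lines, "ATOM  ")
  idx <- which(is_atom)
  if (!length(idx))
    return(data.frame(chain_id = character(0), residue_name = character(0),
                      residue_number = integer(0), atom_name = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  ll <- lines[idx]
  altloc <- substr(ll, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  ll <- ll[keep]; idx <- idx[keep]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(trimws(substr(ll, from, to))))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", what, " field in ATOM record at line ", idx[bad[1]])
    v
  }
  data.frame(
    chain_id = substr(ll, 22, 22),
    residue_name = trimws(substr(ll, 18, 20)),
    residue_number = as.integer(num(23, 26, "residue number")),
    atom_name = trimws(substr(ll, 13, 16)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"))
}

#' Write atoms as valid PDB ATOM records (fixture writer)
#'
#' @param atoms Data frame as returned by [parse_pdb_atoms()].
#' @param path Output path (or `NULL` to return the lines).
#' @return The lines invisibly (and writes `path` when given).
#' @export
write_pdb_atoms <- function(atoms, path = NULL) {
  name4 <- ifelse(nchar(atoms$atom_name) < 4L,
                  sprintf(" %-3s", atoms$atom_name),
                  atoms$atom_name)
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(nrow(atoms)), name4, atoms$residue_name, atoms$chain_id,
    atoms$residue_number, atoms$x, atoms$y, atoms$z)
  if (!is.null(path)) writeLines(c(lines, "END"), path)
  invisible(lines)
}

#' Enumerate inter-chain salt bridges between two chains
#'
#' All pairs of cation side-chain nitrogens (LYS NZ; ARG NH1/NH2/NE; HIS
#' ND1/NE2 — histidine's protonation being unknown, its contacts are
#' flagged) and anion carboxylate oxygens (ASP OD1/OD2; GLU OE1/OE2), one
#' atom on each chain, with Euclidean distance <= `max_dist`. Symmetric in
#' chain order; sorted by distance ascending.
#'
#' @param atoms Atom data frame (see [parse_pdb_atoms()]).
#' @param chain_a,chain_b Chain identifiers (both must be present).
#' @param max_dist Distance cutoff in Angstrom (default 4.0, the
#'   conventional charged-heavy-atom criterion).
#' @return Data frame with cation and anion atom descriptors
#'   (`cation_chain`, `cation_residue`, `cation_resnum`, `cation_atom`,
#'   `anion_chain`, `anion_residue`, `anion_resnum`, `anion_atom`),
#'   `distance`, and `histidine_cation` flag.
#' @export
find_salt_bridges <- function(atoms, chain_a, chain_b, max_dist = 4.0) {
  have <- unique(atoms$chain_id)
  missing <- setdiff(c(chain_a, chain_b), have)
  if (length(missing))
    stop("chain(s) ", paste(missing, collapse = ", "),
         " not present; available: ", paste(sort(have), collapse = ", "))
  is_cat <- mapply(function(res, at)
    res %in% names(CATION_ATOMS) && at %in% CATION_ATOMS[[res]],
    atoms$residue_name, atoms$atom_name)
  is_an <- mapply(function(res, at)
    res %in% names(ANION_ATOMS) && at %in% ANION_ATOMS[[res]],
    atoms$residue_name, atoms$atom_name)
  empty <- data.frame(cation_chain = character(0),
                      cation_residue = character(0),
                      cation_resnum = integer(0), cation_atom = character(0),
                      anion_chain = character(0),
                      anion_residue = character(0),
                      anion_resnum = integer(0), anion_atom = character(0),
                      distance = numeric(0), histidine_cation = logical(0))
  out <- empty
  for (ch in list(c(chain_a, chain_b), c(chain_b, chain_a))) {
    cats <- atoms[is_cat & atoms$chain_id == ch[1], , drop = FALSE]
    ans <- atoms[is_an & atoms$chain_id == ch[2], , drop = FALSE]
    if (!nrow(cats) || !nrow(ans)) next
    grid <- expand.grid(i = seq_len(nrow(cats)), j = seq_len(nrow(ans)))
    d <- sqrt((cats$x[grid$i] - ans$x[grid$j])^2 +
              (cats$y[grid$i] - ans$y[grid$j])^2 +
              (cats$z[grid$i] - ans$z[grid$j])^2)
    hit <- d <= max_dist
    if (!any(hit)) next
    out <- rbind(out, data.frame(
      cation_chain = cats$chain_id[grid$i[hit]],
      cation_residue = cats$residue_name[grid$i[hit]],
      cation_resnum = cats$residue_number[grid$i[hit]],
      cation_atom = cats$atom_name[grid$i[hit]],
      anion_chain = ans$chain_id[grid$j[hit]],
      anion_residue = ans$residue_name[grid$j[hit]],
      anion_resnum = ans$residue_number[grid$j[hit]],
      anion_atom = ans$atom_name[grid$j[hit]],
      distance = d[hit],
      histidine_cation = cats$residue_name[grid$i[hit]] == "HIS"))
  }
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report how a residue substitution changes each contact's charge pairing
#'
#' For each salt-bridge contact involving the mutated residue (matched by
#' residue number and original one-letter identity on either side), reports
#' whether the substitution turns the attractive cation-carboxylate pair
#' into a like-charge (repulsive) or neutral pair, using the fixed charge
#' table K/R/H = +1, D/E = -1, else 0.
#'
#' @param contacts Output of [find_salt_bridges()].
#' @param mutation Substitution string like `"K78E"` (one-letter original,
#'   residue number, one-letter replacement).
#' @return Data frame with one row per affected contact: the partner
#'   residue, the distance, and `verdict` (`"attractive -> repulsive"`,
#'   `"attractive -> neutral"` or `"attractive -> attractive"`); zero rows
#'   when the mutated residue takes part in no contact.
#' @export
charge_reversal_report <- function(contacts, mutation) {
  m <- regmatches(mutation,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", mutation))[[1]]
  if (length(m) != 4L || !(m[2] %in% AA3_TO_1) || !(m[4] %in% AA3_TO_1))
    stop("cannot parse mutation string '", mutation,
         "' (expected e.g. \"K78E\")")
  orig <- m[2]; resnum <- as.integer(m[3]); new <- m[4]
  new_charge <- if (new %in% names(AA_CHARGE)) AA_CHARGE[[new]] else 0

  rows <- lapply(seq_len(nrow(contacts)), function(i) {
    ct <- contacts[i, ]
    sides <- list(
      list(res = ct$cation_residue, num = ct$cation_resnum,
           partner = sprintf("%s%d (chain %s)", ct$anion_residue,
                             ct$anion_resnum, ct$anion_chain),
           partner_charge = -1),
      list(res = ct$anion_residue, num = ct$anion_resnum,
           partner = sprintf("%s%d (chain %s)", ct$cation_residue,
                             ct$cation_resnum, ct$cation_chain),
           partner_charge = +1))
    for (s in sides) {
      if (s$num == resnum && AA3_TO_1[[s$res]] == orig) {
        after <- new_charge * s$partner_charge
        verdict <- if (after < 0) "attractive -> attractive"
                   else if (after > 0) "attractive -> repulsive"
                   else "attractive -> neutral"
        return(data.frame(mutation = mutation, partner = s$partner,
                          distance = ct$distance, verdict = verdict))
      }
    }
    NULL
  })
  out <- do.call(rbind, c(list(data.frame(mutation = character(0),
                                          partner = character(0),
                                          distance = numeric(0),
                                          verdict = character(0))), rows))
  rownames(out) <- NULL
  out
}
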