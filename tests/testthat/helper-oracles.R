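# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation: plain loops and string ops only.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Exhaustive sliding-window placement: every start for the read and its
# reverse complement, minimum mismatches, tie-break (start, then '+').
oracle_align <- function(seq, ref) {
  L <- nchar(ref); rl <- nchar(seq)
  if (rl < 1 || rl > L) return(NULL)
  best <- list(mm = rl + 1L, start = NA, strand = NA)
  n_best <- 0L
  for (s in 1:(L - rl + 1)) {
    win <- substr(ref, s, s + rl - 1)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seq else revcomp_chr(seq)
      mm <- sum(strsplit(q, "")[[1]] != strsplit(win, "")[[1]])
      if (mm < best$mm) {
        best <- list(mm = mm, start = s, strand = strand)
        n_best <- 1L
      } else if (mm == best$mm) {
        n_best <- n_best + 1L
      }
    }
  }
  c(best, list(n_best = n_best))
}

# Per-column recount of a pileup from (start, oriented sequence) records.
oracle_pileup_column <- function(records, position) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
  for (i in seq_len(nrow(records))) {
    st <- records$start[i]
    sq <- records$seq_ref[i]
    if (st <= position && st + nchar(sq) - 1 >= position) {
      b <- substr(sq, position - st + 1, position - st + 1)
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}

# Long-division decimal expansion of 100 * count / depth, rounded half-up
# to `digits` decimals, computed digit by digit (independent of
# round_percent's integer arithmetic shortcut).
oracle_percent <- function(count, depth, digits = 2) {
  num <- count * 100
  int_part <- num %/% depth
  rem <- num %% depth
  dec <- integer(digits)
  for (i in seq_len(digits)) {
    rem <- rem * 10
    dec[i] <- rem %/% depth
    rem <- rem %% depth
  }
  # half-up: look at the next digit position
  nxt <- (rem * 10) %/% depth
  val <- int_part + sum(dec / 10^seq_len(digits))
  if (nxt >= 5) val <- val + 10^(-digits)
  round(val, digits + 2)  # clean float representation only
}

# Row-wise predicate recheck of the filtration cascade.
oracle_cascade_survivor <- function(alt_aff, pop_af, cons, alt_unaff,
                                    cfg = filter_config()) {
  called <- alt_aff >= cfg$call_min_alt
  af <- if (is.na(pop_af)) 0 else pop_af
  keep <- alt_aff >= cfg$affected_min_alt &&
    af < cfg$max_pop_af &&
    (!is.na(cons) && cons > cfg$min_conservation)
  removed <- alt_unaff > cfg$unaffected_subtract_min_alt
  called && keep && !removed
}

# All-pairs salt-bridge search with the same atom whitelist.
oracle_salt_bridges <- function(atoms, chain_a, chain_b, max_dist = 4.0) {
  cat_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("ND1", "NE2"))
  an_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  hits <- list()
  for (i in seq_len(nrow(atoms))) for (j in seq_len(nrow(atoms))) {
    a <- atoms[i, ]; b <- atoms[j, ]
    pair_ok <- (a$chain_id == chain_a && b$chain_id == chain_b) ||
      (a$chain_id == chain_b && b$chain_id == chain_a)
    if (!pair_ok) next
    if (!(a$residue_name %in% names(cat_atoms)) ||
        !(a$atom_name %in% cat_atoms[[a$residue_name]])) next
    if (!(b$residue_name %in% names(an_atoms)) ||
        !(b$atom_name %in% an_atoms[[b$residue_name]])) next
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    if (d <= max_dist)
      hits[[length(hits) + 1L]] <- data.frame(
        cation_resnum = a$residue_number, cation_atom = a$atom_name,
        anion_resnum = b$residue_number, anion_atom = b$atom_name,
        distance = d)
  }
  if (!length(hits)) return(data.frame(cation_resnum = integer(0),
                                       cation_atom = character(0),
                                       anion_resnum = integer(0),
                                       anion_atom = character(0),
                                       distance = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$distance), , drop = FALSE]
}

# Build an atom row for PDB fixtures.
atom_row <- function(chain, res, num, atom, x, y, z) {
  data.frame(chain_id = chain, residue_name = res, residue_number = num,
             atom_name = atom, x = x, y = y, z = z)
}

# The 18 printed rows of the two mutation-frequency tables
# (frequency %, depth, ref count, mut count, and the two off-base counts).
table_rows <- function() {
  rbind(
    data.frame(table = 2, sample = "P1 endothelial", pct = 14.36,
               depth = 130299, ref = 111585, mut = 18709, o1 = 4, o2 = 1),
    data.frame(table = 2, sample = "P2 dermis", pct = 7.08,
               depth = 128341, ref = 119233, mut = 9091, o1 = 16, o2 = 1),
    data.frame(table = 2, sample = "P2 endothelial", pct = 9.28,
               depth = 100355, ref = 91036, mut = 9314, o1 = 5, o2 = 0),
    data.frame(table = 2, sample = "P2 LCM endothelium", pct = 29.88,
               depth = 60684, ref = 42552, mut = 18131, o1 = 1, o2 = 0),
    data.frame(table = 2, sample = "P3 endothelial", pct = 0.01,
               depth = 99182, ref = 99159, mut = 14, o1 = 6, o2 = 3),
    data.frame(table = 2, sample = "P3 dermis", pct = 0.01,
               depth = 131325, ref = 131300, mut = 16, o1 = 8, o2 = 1),
    data.frame(table = 2, sample = "P4 dermis", pct = 7.39,
               depth = 135365, ref = 125357, mut = 9998, o1 = 8, o2 = 2),
    data.frame(table = 2, sample = "P4 endothelial 1", pct = 0.24,
               depth = 113991, ref = 113714, mut = 269, o1 = 5, o2 = 3),
    data.frame(table = 2, sample = "P4 endothelial 2", pct = 0.13,
               depth = 143019, ref = 142825, mut = 189, o1 = 4, o2 = 1),
    data.frame(table = 2, sample = "P5 dermis", pct = 8.98,
               depth = 147823, ref = 134533, mut = 13276, o1 = 12, o2 = 2),
    data.frame(table = 2, sample = "P6 dermis", pct = 5.72,
               depth = 99490, ref = 93794, mut = 5694, o1 = 0, o2 = 2),
    data.frame(table = 2, sample = "P6 LCM endothelium", pct = 19.93,
               depth = 192942, ref = 154496, mut = 38444, o1 = 0, o2 = 2),
    data.frame(table = 3, sample = "affected dermis", pct = 3.59,
               depth = 91041, ref = 87769, mut = 3265, o1 = 7, o2 = 0),
    data.frame(table = 3, sample = "affected endothelial", pct = 20.74,
               depth = 71630, ref = 56771, mut = 14858, o1 = 1, o2 = 0),
    data.frame(table = 3, sample = "affected fibroblast", pct = 0.02,
               depth = 112155, ref = 112128, mut = 19, o1 = 8, o2 = 0),
    data.frame(table = 3, sample = "affected keratinocyte", pct = 0.01,
               depth = 129481, ref = 129464, mut = 13, o1 = 4, o2 = 0),
    data.frame(table = 3, sample = "unaffected dermis", pct = 0.15,
               depth = 133486, ref = 133264, mut = 206, o1 = 15, o2 = 1),
    data.frame(table = 3, sample = "unaffected fibroblast", pct = 0.01,
               depth = 53404, ref = 53400, mut = 3, o1 = 1, o2 = 0))
}

# Counts for a mosaic call from a table row: table 2 loci are G>A, table 3
# A>G; the two off-target bases carry the o1/o2 counts (T then C).
row_counts <- function(r) {
  if (r$table == 2)
    list(counts = c(A = r$mut, C = r$o2, G = r$ref, T = r$o1),
         ref = "G", alt = "A")
  else
    list(counts = c(A = r$ref, C = r$o2, G = r$mut, T = r$o1),
         ref = "A", alt = "G")
}
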