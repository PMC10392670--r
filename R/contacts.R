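## Protein-DNA contact classification: hydrogen-bond (heavy-atom
## donor/acceptor distance, plus donor angle when hydrogens are present)
## and hydrophobic (carbon-carbon) criteria. A contact to a base atom is a
## "specific" (readout) contact; sugar or phosphate contacts are
## "nonspecific". Cutoffs are package conventions, overridable per call.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
DNA_RESNAMES <- c("DA", "DC", "DG", "DT", "A", "C", "G", "T")

PROTEIN_DONORS <- list(
  "*" = "N", ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2",
  GLN = "NE2", HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  TRP = "NE1", CYS = "SG")
PROTEIN_ACCEPTORS <- list(
  "*" = c("O", "OXT"), ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG",
  THR = "OG1", TYR = "OH", MET = "SD")
DNA_DONORS <- list(DA = "N6", DG = c("N1", "N2"), DC = "N4", DT = "N3")
DNA_ACCEPTORS <- list(
  DA = c("N1", "N3", "N7"), DG = c("O6", "N3", "N7"),
  DC = c("O2", "N3"), DT = c("O2", "O4"))
DNA_BACKBONE_ACCEPTORS <- c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'")

#' Contact classification criteria
#'
#' @param hbond_dist Heavy-atom donor-acceptor cutoff, Angstrom
#'   (default 3.5).
#' @param hbond_angle Minimal donor-H-acceptor angle in degrees when
#'   hydrogens are present (default 120); falls back to distance-only when
#'   the donor carries no hydrogen in the structure.
#' @param hydrophobic_dist Carbon-carbon cutoff, Angstrom (default 4.5).
#' @return List of criteria.
#' @export
contact_criteria <- function(hbond_dist = 3.5, hbond_angle = 120,
                             hydrophobic_dist = 4.5) {
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       hydrophobic_dist = hydrophobic_dist)
}

is_hydrogen <- function(elety) grepl("^[0-9]?H", elety)

#' Classify protein-DNA contacts in one snapshot
#'
#' Hydrogen bonds: donor-acceptor heavy-atom distance <= `hbond_dist`, and,
#' when the donor carries hydrogens in the structure, a donor-H-acceptor
#' angle >= `hbond_angle` for at least one hydrogen. Hydrophobic contacts:
#' any protein-carbon to DNA-carbon distance <= `hydrophobic_dist`. Each
#' record is tagged with the DNA moiety (base / sugar / phosphate) and the
#' derived classification (specific = base, nonspecific otherwise).
#'
#' @param df Atom data.frame of one model (columns chain, resno, resname,
#'   elety, x, y, z; as produced by [read_dna_pdb()]).
#' @param criteria See [contact_criteria()].
#' @return data.frame of contact records (possibly 0 rows): protein_chain,
#'   protein_resno, protein_resname, protein_atom, dna_chain, dna_resno,
#'   dna_resname, dna_atom, moiety, type, distance, angle, classification.
#' @export
classify_contacts <- function(df, criteria = contact_criteria()) {
  prot <- df[df$resname %in% AA3, , drop = FALSE]
  dna <- df[df$resname %in% DNA_RESNAMES, , drop = FALSE]
  if (nrow(dna) == 0) stop("no DNA chain detected")
  dna$resname <- ifelse(nchar(dna$resname) == 1,
                        paste0("D", dna$resname), dna$resname)
  if (is.null(dna$moiety)) dna$moiety <- dna_moiety(dna$elety)
  empty <- data.frame(protein_chain = character(0), protein_resno = integer(0),
                      protein_resname = character(0), protein_atom = character(0),
                      dna_chain = character(0), dna_resno = integer(0),
                      dna_resname = character(0), dna_atom = character(0),
                      moiety = character(0), type = character(0),
                      distance = numeric(0), angle = numeric(0),
                      classification = character(0))
  if (nrow(prot) == 0) return(empty)
  ph <- prot[is_hydrogen(prot$elety), , drop = FALSE]
  prot_heavy <- prot[!is_hydrogen(prot$elety), , drop = FALSE]
  dna_heavy <- dna[!is_hydrogen(dna$elety), , drop = FALSE]
  P <- as.matrix(prot_heavy[, c("x", "y", "z")])
  Dm <- as.matrix(dna_heavy[, c("x", "y", "z")])
  D2 <- outer(rowSums(P^2), rowSums(Dm^2), `+`) - 2 * P %*% t(Dm)
  D2[D2 < 0] <- 0
  dist <- sqrt(D2)

  p_donor <- prot_heavy$elety %in% PROTEIN_DONORS[["*"]] |
    vapply(seq_len(nrow(prot_heavy)), function(i)
      prot_heavy$elety[i] %in% PROTEIN_DONORS[[prot_heavy$resname[i]]],
      logical(1))
  p_acc <- prot_heavy$elety %in% PROTEIN_ACCEPTORS[["*"]] |
    vapply(seq_len(nrow(prot_heavy)), function(i)
      prot_heavy$elety[i] %in% PROTEIN_ACCEPTORS[[prot_heavy$resname[i]]],
      logical(1))
  d_donor <- vapply(seq_len(nrow(dna_heavy)), function(i)
    dna_heavy$elety[i] %in% DNA_DONORS[[dna_heavy$resname[i]]], logical(1))
  d_acc <- vapply(seq_len(nrow(dna_heavy)), function(i)
    dna_heavy$elety[i] %in% DNA_ACCEPTORS[[dna_heavy$resname[i]]] ||
      dna_heavy$elety[i] %in% DNA_BACKBONE_ACCEPTORS, logical(1))
  p_carbon <- grepl("^C", prot_heavy$elety)
  d_carbon <- grepl("^C", dna_heavy$elety)

  donor_angle_ok <- function(donor_row, acc_xyz) {
    hs <- ph[ph$chain == prot_heavy$chain[donor_row] &
               ph$resno == prot_heavy$resno[donor_row], , drop = FALSE]
    if (nrow(hs) == 0) return(TRUE)  # no hydrogens: distance-only fallback
    dxyz <- as.numeric(prot_heavy[donor_row, c("x", "y", "z")])
    hd <- sqrt(rowSums(sweep(as.matrix(hs[, c("x", "y", "z")]), 2, dxyz)^2))
    hs <- hs[hd <= 1.25, , drop = FALSE]
    if (nrow(hs) == 0) return(TRUE)
    ang <- vapply(seq_len(nrow(hs)), function(k) {
      h <- as.numeric(hs[k, c("x", "y", "z")])
      v1 <- dxyz - h; v2 <- acc_xyz - h
      rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))))
    }, numeric(1))
    any(ang >= criteria$hbond_angle)
  }

  recs <- list()
  add <- function(i, j, type, ang = NA_real_) {
    recs[[length(recs) + 1]] <<- data.frame(
      protein_chain = prot_heavy$chain[i], protein_resno = prot_heavy$resno[i],
      protein_resname = prot_heavy$resname[i], protein_atom = prot_heavy$elety[i],
      dna_chain = dna_heavy$chain[j], dna_resno = dna_heavy$resno[j],
      dna_resname = dna_heavy$resname[j], dna_atom = dna_heavy$elety[j],
      moiety = dna_heavy$moiety[j], type = type, distance = dist[i, j],
      angle = ang,
      classification = if (dna_heavy$moiety[j] == "base") "specific"
                       else "nonspecific")
  }
  hb <- which(dist <= criteria$hbond_dist, arr.ind = TRUE)
  for (r in seq_len(nrow(hb))) {
    i <- hb[r, 1]; j <- hb[r, 2]
    acc_xyz <- as.numeric(dna_heavy[j, c("x", "y", "z")])
    if (p_donor[i] && d_acc[j]) {
      if (donor_angle_ok(i, acc_xyz)) add(i, j, "hbond")
    } else if (p_acc[i] && d_donor[j]) {
      add(i, j, "hbond")  # DNA donor: heavy-atom criterion only
    }
  }
  hp <- which(dist <= criteria$hydrophobic_dist, arr.ind = TRUE)
  for (r in seq_len(nrow(hp))) {
    i <- hp[r, 1]; j <- hp[r, 2]
    if (p_carbon[i] && d_carbon[j]) add(i, j, "hydrophobic")
  }
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Per-frame contact occupancy table
#'
#' Classifies every frame and aggregates contacts at the protein-residue /
#' DNA-residue / moiety level; occupancy is the fraction of frames in which
#' the aggregated contact is present.
#'
#' @param frames A `dna_structure` (multi-model) or list of atom
#'   data.frames.
#' @param criteria See [contact_criteria()].
#' @return data.frame with columns key, protein_res, dna_res, moiety,
#'   classification, n_frames, occupancy.
#' @export
occupancy <- function(frames, criteria = contact_criteria()) {
  models <- if (inherits(frames, "dna_structure")) frames$models else frames
  stopifnot(length(models) >= 1)
  nf <- length(models)
  seen <- list()
  for (m in seq_len(nf)) {
    cc <- classify_contacts(models[[m]], criteria)
    if (nrow(cc) == 0) next
    key <- unique(data.frame(
      protein_res = paste(cc$protein_chain, cc$protein_resno,
                          cc$protein_resname, sep = ":"),
      dna_res = paste(cc$dna_chain, cc$dna_resno, cc$dna_resname, sep = ":"),
      moiety = cc$moiety, classification = cc$classification))
    for (r in seq_len(nrow(key))) {
      k <- paste(key$protein_res[r], key$dna_res[r], key$moiety[r], sep = "|")
      if (is.null(seen[[k]]))
        seen[[k]] <- c(list(count = 0), as.list(key[r, ]))
      seen[[k]]$count <- seen[[k]]$count + 1
    }
  }
  if (!length(seen))
    return(data.frame(key = character(0), protein_res = character(0),
                      dna_res = character(0), moiety = character(0),
                      classification = character(0), n_frames = integer(0),
                      occupancy = numeric(0)))
  out <- data.frame(
    key = names(seen),
    protein_res = vapply(seen, `[[`, character(1), "protein_res"),
    dna_res = vapply(seen, `[[`, character(1), "dna_res"),
    moiety = vapply(seen, `[[`, character(1), "moiety"),
    classification = vapply(seen, `[[`, character(1), "classification"),
    n_frames = nf,
    occupancy = vapply(seen, function(s) s$count / nf, numeric(1)))
  rownames(out) <- NULL
  out[order(-out$occupancy, out$key), ]
}
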