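## Idealized duplex construction from helical parameters, multi-model PDB
## I/O, and coordinate-level readouts: per-bp frames refit from atoms,
## Watson-Crick hydrogen-bond integrity, and groove geometry.

## Backbone atom positions in the owning base's reference frame (Angstrom).
## Chosen to emulate fibre B-DNA: phosphorus at ~8.9 A helical radius so
## that raw cross-strand P-P separations reproduce B-like groove widths.
BACKBONE_LOCAL <- list(
  "P"   = c(1.24, 8.82, 0.90),
  "OP1" = c(0.35, 9.55, 1.75),
  "OP2" = c(2.45, 9.25, 1.45),
  "O5'" = c(1.30, 8.85, -0.55),
  "O4'" = c(-3.40, 6.00, 0.60)
)

## Backbone radius correction subtracted from raw P-P distances (El
## Hassan-Calladine convention).
GROOVE_P_CORRECTION <- 5.8

## Atom-name partition used by the contact classifier and groove code.
MOIETY_TABLE <- list(
  phosphate = c("P", "OP1", "OP2", "O1P", "O2P", "O3'", "O5'"),
  sugar = c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'")
)

dna_moiety <- function(atom_names) {
  out <- rep("base", length(atom_names))
  out[atom_names %in% MOIETY_TABLE$phosphate] <- "phosphate"
  out[atom_names %in% MOIETY_TABLE$sugar] <- "sugar"
  out
}

## Inverse of bp_frame_and_params(): place the flipped-Crick and Watson
## base frames around a bp mid-frame given the six intra-bp parameters.
split_bp_frames <- function(mid, intra) {
  intra <- as_param6(intra, INTRA_PAR_NAMES)
  buckle <- deg2rad(intra[4]); prop <- deg2rad(intra[5]); open <- deg2rad(intra[6])
  gamma <- sqrt(buckle^2 + prop^2)
  phi <- atan2(-buckle, prop)
  hb <- c(-sin(phi), cos(phi), 0)
  Rm <- mid$axes
  R2 <- Rm %*% rot_axis(hb, gamma / 2) %*% rot_z(open / 2)
  R1 <- Rm %*% rot_axis(hb, -gamma / 2) %*% rot_z(-open / 2)
  half <- as.numeric(Rm %*% intra[1:3]) / 2
  list(crick_flipped = base_frame(mid$origin - half, R1),
       watson = base_frame(mid$origin + half, R2))
}

#' Build idealized duplex coordinates from helical parameters
#'
#' Places standard-geometry base atoms (plus C1', O4' and phosphate atoms)
#' by composing bp frames with [compose_step()]. Applying the package's
#' frame-fitting analysis to the result recovers the input parameters to
#' numerical precision, which makes the builder the fixture generator for
#' the geometry and contact modules.
#'
#' @param sequence Watson-strand sequence (ACGT), length n.
#' @param step_parameters Per-model step parameters: an `n-1 x 6` matrix for
#'   a single model, or a list of such matrices (one per model), columns in
#'   `shift, slide, rise, tilt, roll, twist` order.
#' @param intra_parameters Optional intra-bp parameters, `n x 6`
#'   (`shear, stretch, stagger, buckle, propeller, opening`), same list
#'   convention; default all zero.
#' @return A `dna_structure`: list with `sequence`, `n_bp` and `models` (a
#'   list of atom data.frames with columns chain, resno, resname, elety,
#'   moiety, x, y, z).
#' @export
build_coordinates <- function(sequence, step_parameters = NULL,
                              intra_parameters = NULL) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% names(COMPLEMENT)))
    stop("sequence contains non-ACGT characters")
  n <- length(bases)
  if (is.null(step_parameters)) {
    step_parameters <- ideal_bdna_params(n)
  }
  if (!is.list(step_parameters)) step_parameters <- list(step_parameters)
  if (!is.null(intra_parameters) && !is.list(intra_parameters))
    intra_parameters <- list(intra_parameters)
  models <- lapply(seq_along(step_parameters), function(m) {
    sp <- step_parameters[[m]]
    if (n > 1 && (!is.matrix(sp) || nrow(sp) != n - 1 || ncol(sp) != 6))
      stop("step parameter matrix must be (n_bp - 1) x 6")
    ip <- if (is.null(intra_parameters)) NULL else intra_parameters[[m]]
    build_model(bases, sp, ip)
  })
  structure(list(sequence = sequence, n_bp = n, models = models),
            class = "dna_structure")
}

ideal_bdna_params <- function(n_bp, twist = 36, rise = 3.38) {
  if (n_bp < 2) return(matrix(numeric(0), 0, 6,
                              dimnames = list(NULL, STEP_PAR_NAMES)))
  matrix(rep(c(0, 0, rise, 0, 0, twist), each = n_bp - 1), n_bp - 1, 6,
         dimnames = list(NULL, STEP_PAR_NAMES))
}

place_atoms <- function(frame, local) {
  sweep(local %*% t(frame$axes), 2, frame$origin, `+`)
}

build_model <- function(bases, sp, ip) {
  n <- length(bases)
  mids <- vector("list", n)
  mids[[1]] <- base_frame()
  if (n > 1)
    for (i in seq_len(n - 1)) mids[[i + 1]] <- compose_step(mids[[i]], sp[i, ])
  rows <- list()
  for (i in seq_len(n)) {
    if (is.null(ip)) {
      fw <- mids[[i]]; fcf <- mids[[i]]
    } else {
      s <- split_bp_frames(mids[[i]], ip[i, ])
      fw <- s$watson; fcf <- s$crick_flipped
    }
    fc <- flip_frame(fcf)
    bw <- bases[i]; bc <- COMPLEMENT[[bw]]
    ## Watson residue i (chain A)
    loc_w <- STANDARD_BASES[[bw]]
    extra_w <- if (i > 1) BACKBONE_LOCAL else BACKBONE_LOCAL["O4'"]
    loc_w <- rbind(loc_w, do.call(rbind, extra_w))
    rownames(loc_w)[(nrow(loc_w) - length(extra_w) + 1):nrow(loc_w)] <-
      names(extra_w)
    xyz_w <- place_atoms(fw, loc_w)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "A", resno = i, resname = paste0("D", bw),
      elety = rownames(loc_w), xyz_w, row.names = NULL)
    ## Crick residue pairing with bp i sits at chain-B resno n - i + 1;
    ## its P exists when that resno >= 2, i.e. i <= n - 1.
    jc <- n - i + 1
    loc_c <- STANDARD_BASES[[bc]]
    extra_c <- if (jc > 1) BACKBONE_LOCAL else BACKBONE_LOCAL["O4'"]
    loc_c <- rbind(loc_c, do.call(rbind, extra_c))
    rownames(loc_c)[(nrow(loc_c) - length(extra_c) + 1):nrow(loc_c)] <-
      names(extra_c)
    xyz_c <- place_atoms(fc, loc_c)
    rows[[length(rows) + 1]] <- data.frame(
      chain = "B", resno = jc, resname = paste0("D", bc),
      elety = rownames(loc_c), xyz_c, row.names = NULL)
  }
  df <- do.call(rbind, rows)
  names(df)[5:7] <- c("x", "y", "z")
  df$moiety <- dna_moiety(df$elety)
  df <- df[order(df$chain, df$resno), ]
  rownames(df) <- NULL
  df
}

#' Write a `dna_structure` (or list of atom tables) as multi-model PDB
#'
#' One MODEL/ENDMDL block per snapshot.
#'
#' @param x A `dna_structure` or a single atom data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  models <- if (inherits(x, "dna_structure")) x$models
            else if (is.data.frame(x)) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    df <- models[[m]]
    if (length(models) > 1) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- seq_len(nrow(df))
    name4 <- ifelse(nchar(df$elety) >= 4, substr(df$elety, 1, 4),
                    paste0(" ", formatC(df$elety, width = -3)))
    lines <- sprintf(
      "ATOM  %5d %4s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name4, df$resname, df$chain, df$resno,
      df$x, df$y, df$z, 1.0, 0.0, substr(df$elety, 1, 1))
    writeLines(lines, con)
    writeLines("TER", con)
    if (length(models) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file into a `dna_structure`-style object
#'
#' Thin wrapper over `bio3d::read.pdb(multi = TRUE)`; each MODEL becomes one
#' atom data.frame. Non-DNA chains (protein) are retained so the result can
#' feed the contact classifier as well as the geometry readouts.
#'
#' @param path PDB file path.
#' @return A `dna_structure` with `models`, `sequence` (Watson strand, from
#'   the first DNA chain) and `n_bp`.
#' @export
read_dna_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  models <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    df <- data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
                     elety = at$elety, x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3])
    df$moiety <- dna_moiety(df$elety)
    df
  })
  dna <- models[[1]]$resname %in% c("DA", "DC", "DG", "DT", "A", "C", "G", "T")
  seq_chain <- if (any(dna)) {
    first <- models[[1]][dna, ]
    ch <- sort(unique(first$chain))[1]
    resd <- first[first$chain == ch, ]
    paste(sub("^D", "", resd$resname[!duplicated(resd$resno)][order(
      sort(unique(resd$resno)))]), collapse = "")
  } else ""
  structure(list(sequence = seq_chain, n_bp = nchar(seq_chain),
                 models = models), class = "dna_structure")
}

model_base_atoms <- function(df, chain, resno) {
  sel <- df$chain == chain & df$resno == resno
  m <- as.matrix(df[sel, c("x", "y", "z")])
  rownames(m) <- df$elety[sel]
  m
}

#' Fit base, base-pair frames and intra-bp parameters for one snapshot
#'
#' Bases are paired positionally: Watson chain residue i with Crick chain
#' residue n - i + 1. Returns the refit bp frames plus intra-bp parameters.
#'
#' @param df Atom data.frame of one model (as in `dna_structure$models`).
#' @param chains Character length-2: Watson and Crick chain identifiers.
#' @return List with `bp_frames` (list of `base_frame`), `intra` (n x 6
#'   matrix), `watson_frames`, `crick_frames`.
#' @export
structure_frames <- function(df, chains = c("A", "B")) {
  dfw <- df[df$chain == chains[1], ]
  dfc <- df[df$chain == chains[2], ]
  res_w <- sort(unique(dfw$resno))
  res_c <- sort(unique(dfc$resno))
  n <- length(res_w)
  if (length(res_c) != n) stop("strands have different lengths")
  bp_frames <- vector("list", n)
  wf <- vector("list", n); cf <- vector("list", n)
  intra <- matrix(NA_real_, n, 6, dimnames = list(NULL, INTRA_PAR_NAMES))
  for (i in seq_len(n)) {
    rw <- res_w[i]
    bw <- sub("^D", "", dfw$resname[dfw$resno == rw][1])
    rc <- res_c[n - i + 1]
    bc <- sub("^D", "", dfc$resname[dfc$resno == rc][1])
    fw <- fit_base_frame(model_base_atoms(df, chains[1], rw), bw)
    fc <- fit_base_frame(model_base_atoms(df, chains[2], rc), bc)
    bp <- bp_frame_and_params(fw, flip_frame(fc))
    bp_frames[[i]] <- bp$frame
    intra[i, ] <- bp$params
    wf[[i]] <- fw; cf[[i]] <- fc
  }
  list(bp_frames = bp_frames, intra = intra,
       watson_frames = wf, crick_frames = cf)
}

#' Per-model helical parameter table
#'
#' Runs the frame fit on every model of a structure and returns the six
#' inter-bp step parameters (and intra-bp parameters) in long format,
#' suitable for CSV export.
#'
#' @param x A `dna_structure`.
#' @param chains Watson/Crick chain identifiers.
#' @return data.frame with columns model, index, parameter, value and a
#'   `kind` column (`step` or `intra`).
#' @export
helical_parameter_table <- function(x, chains = c("A", "B")) {
  out <- list()
  for (m in seq_along(x$models)) {
    fr <- structure_frames(x$models[[m]], chains)
    n <- length(fr$bp_frames)
    if (n > 1) {
      sp <- t(vapply(seq_len(n - 1), function(i)
        step_params(fr$bp_frames[[i]], fr$bp_frames[[i + 1]]), numeric(6)))
      out[[length(out) + 1]] <- data.frame(
        model = m, kind = "step", index = rep(seq_len(n - 1), 6),
        parameter = rep(STEP_PAR_NAMES, each = n - 1),
        value = as.numeric(sp))
    }
    out[[length(out) + 1]] <- data.frame(
      model = m, kind = "intra", index = rep(seq_len(n), 6),
      parameter = rep(INTRA_PAR_NAMES, each = n),
      value = as.numeric(fr$intra))
  }
  do.call(rbind, out)
}

#' Watson-Crick hydrogen-bond integrity check
#'
#' Measures the canonical WC heavy-atom donor-acceptor distances for every
#' bp and flags a pair as melted when any distance is >= 4.0 Angstrom (the
#' boundary value itself counts as melted).
#'
#' @param df Atom data.frame of one model.
#' @param chains Watson/Crick chain identifiers.
#' @param threshold Melting threshold in Angstrom (default 4.0).
#' @return data.frame with columns bp, base_pair, max_distance, melted.
#' @export
wc_hbond_check <- function(df, chains = c("A", "B"), threshold = 4.0) {
  dfw <- df[df$chain == chains[1], ]
  dfc <- df[df$chain == chains[2], ]
  res_w <- sort(unique(dfw$resno)); res_c <- sort(unique(dfc$resno))
  n <- length(res_w)
  out <- data.frame(bp = seq_len(n), base_pair = NA_character_,
                    max_distance = NA_real_, melted = NA)
  for (i in seq_len(n)) {
    bw <- sub("^D", "", dfw$resname[dfw$resno == res_w[i]][1])
    bc <- sub("^D", "", dfc$resname[dfc$resno == res_c[n - i + 1]][1])
    key <- paste(bw, bc, sep = ":")
    pairs <- WC_HBOND_PAIRS[[key]]
    if (is.null(pairs)) stop("not a Watson-Crick base pair: ", key)
    aw <- model_base_atoms(df, chains[1], res_w[i])
    ac <- model_base_atoms(df, chains[2], res_c[n - i + 1])
    d <- vapply(pairs, function(p) {
      if (!p[1] %in% rownames(aw) || !p[2] %in% rownames(ac))
        return(NA_real_)
      sqrt(sum((aw[p[1], ] - ac[p[2], ])^2))
    }, numeric(1))
    out$base_pair[i] <- key
    out$max_distance[i] <- max(d, na.rm = TRUE)
    out$melted[i] <- out$max_distance[i] >= threshold
  }
  out
}

#' Major and minor groove geometry from cross-strand phosphate distances
#'
#' Widths are minimal cross-strand P-P distances minus a 5.8 Angstrom
#' backbone radius correction, in the spirit of the El Hassan-Calladine
#' refined method but without a curvilinear axis: each phosphate carries a
#' fractional bp "level" (P of Watson residue i sits at level i - 0.5; P of
#' the Crick residue paired with bp j at level j + 0.5) and a cross-strand
#' pair reports at the level of its midpoint. Pairs whose strand-level
#' offset falls on the minor-groove side (Watson level below Crick level)
#' yield the minor width, the near-aligned offsets the major width. Depth is
#' the distance from the bp mid-frame origin at that level to the line
#' through the selected P-P pair. Levels without flanking phosphates are
#' reported as NA (flagged, never silently zeroed).
#'
#' @param x Either an atom data.frame of one model (chains as in
#'   [structure_frames()]) or a list
#'   `list(p_watson, p_crick, frames)` with phosphate coordinate matrices
#'   (rownames = residue numbers) and the bp frames.
#' @param chains Watson/Crick chain identifiers when `x` is an atom table.
#' @param correction Backbone radius correction in Angstrom (default 5.8).
#' @return data.frame (class `groove_profile`) with columns level,
#'   minor_width, minor_depth, major_width, major_depth; one row per
#'   interior bp level.
#' @export
groove_geometry <- function(x, chains = c("A", "B"),
                            correction = GROOVE_P_CORRECTION) {
  if (is.data.frame(x)) {
    fr <- structure_frames(x, chains)$bp_frames
    n <- length(fr)
    pw_df <- x[x$chain == chains[1] & x$elety == "P", ]
    pc_df <- x[x$chain == chains[2] & x$elety == "P", ]
    pw <- as.matrix(pw_df[, c("x", "y", "z")])
    rownames(pw) <- pw_df$resno
    pc <- as.matrix(pc_df[, c("x", "y", "z")])
    rownames(pc) <- pc_df$resno
  } else {
    pw <- x$p_watson; pc <- x$p_crick; fr <- x$frames
    n <- length(fr)
  }
  lw <- as.numeric(rownames(pw)) - 0.5
  lc <- n - as.numeric(rownames(pc)) + 1.5
  levels <- if (n >= 3) 2:(n - 1) else integer(0)
  out <- data.frame(level = levels, minor_width = NA_real_,
                    minor_depth = NA_real_, major_width = NA_real_,
                    major_depth = NA_real_)
  if (nrow(pw) == 0 || nrow(pc) == 0) {
    class(out) <- c("groove_profile", class(out))
    return(out)
  }
  D <- sqrt(outer(rowSums(pw^2), rowSums(pc^2), `+`) - 2 * pw %*% t(pc))
  diff <- outer(lw, lc, `-`)
  mid <- outer(lw, lc, `+`) / 2
  pick <- function(L, lo, hi) {
    sel <- which(diff >= lo & diff <= hi & round(mid) == L, arr.ind = TRUE)
    if (nrow(sel) == 0) return(NULL)
    k <- which.min(D[sel])
    list(d = D[sel][k], i = sel[k, 1], j = sel[k, 2])
  }
  point_line_dist <- function(p, a, b) {
    u <- b - a
    sqrt(max(0, sum((p - a)^2) - sum((p - a) * u)^2 / sum(u^2)))
  }
  for (r in seq_along(levels)) {
    L <- levels[r]
    mn <- pick(L, -7.5, -1.5)
    mj <- pick(L, -1.5, 3.5)
    if (!is.null(mn)) {
      out$minor_width[r] <- mn$d - correction
      out$minor_depth[r] <- point_line_dist(fr[[L]]$origin, pw[mn$i, ],
                                            pc[mn$j, ])
    }
    if (!is.null(mj)) {
      out$major_width[r] <- mj$d - correction
      out$major_depth[r] <- point_line_dist(fr[[L]]$origin, pw[mj$i, ],
                                            pc[mj$j, ])
    }
  }
  class(out) <- c("groove_profile", class(out))
  out
}
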