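## Fixture: an idealized duplex with a few strategically placed protein
## atoms (built in code, no stored files).
protein_atom <- function(resno, resname, elety, xyz, chain = "P") {
  data.frame(chain = chain, resno = resno, resname = resname, elety = elety,
             x = xyz[1], y = xyz[2], z = xyz[3], moiety = "base")
}

dna_atom_xyz <- function(df, chain, resno, elety) {
  as.numeric(df[df$chain == chain & df$resno == resno &
                  df$elety == elety, c("x", "y", "z")])
}

test_that("hydrogen-bond contacts are classified by moiety", {
  s <- build_coordinates("GCACGTGC")
  df <- s$models[[1]]
  o6 <- dna_atom_xyz(df, "A", 5, "O6")     # guanine O6, base moiety
  op1 <- dna_atom_xyz(df, "A", 5, "OP1")   # backbone oxygen
  arg_base <- protein_atom(1, "ARG", "NH1", o6 + c(0, 0, 2.9))
  cc <- classify_contacts(rbind(df, arg_base))
  hb <- cc[cc$type == "hbond", ]
  expect_true(nrow(hb) >= 1)
  expect_true(all(hb$moiety == "base"))
  expect_true(all(hb$classification == "specific"))
  expect_equal(hb$dna_atom[1], "O6")
  expect_equal(hb$distance[1], 2.9, tolerance = 1e-6)
  ## the same side chain at a phosphate oxygen is nonspecific
  arg_bb <- protein_atom(1, "ARG", "NH1", op1 + c(0, 0, 2.9))
  cc2 <- classify_contacts(rbind(df, arg_bb))
  hb2 <- cc2[cc2$type == "hbond", ]
  expect_true(nrow(hb2) >= 1)
  expect_true(all(hb2$classification == "nonspecific"))
  expect_true(all(hb2$moiety %in% c("phosphate", "sugar")))
  ## specific + nonspecific counts add up to the total
  both <- classify_contacts(rbind(df, arg_base, arg_bb))
  expect_equal(sum(both$classification == "specific") +
                 sum(both$classification == "nonspecific"), nrow(both))
  expect_error(classify_contacts(rbind(arg_base)), "no DNA")
})

test_that("hydrophobic contacts respect the carbon-carbon cutoff boundary", {
  s <- build_coordinates("GCATAT")
  df <- s$models[[1]]
  c7 <- dna_atom_xyz(df, "A", 4, "C7")     # thymine methyl carbon
  leu44 <- protein_atom(2, "LEU", "CD1", c7 + c(0, 0, 4.4))
  cc <- classify_contacts(rbind(df, leu44))
  hp <- cc[cc$type == "hydrophobic", ]
  expect_true(any(hp$dna_atom == "C7" & hp$classification == "specific"))
  leu46 <- protein_atom(2, "LEU", "CD1", c7 + c(0, 0, 4.6))
  cc2 <- classify_contacts(rbind(df, leu46))
  expect_false(any(cc2$dna_atom == "C7" & cc2$type == "hydrophobic"))
})

test_that("donor hydrogens gate hydrogen bonds by geometry when present", {
  s <- build_coordinates("GCGC")
  df <- s$models[[1]]
  o6 <- dna_atom_xyz(df, "A", 3, "O6")
  don <- o6 + c(0, 0, 2.9)
  ser <- protein_atom(3, "SER", "OG", don)
  ## hydrogen pointing at the acceptor: angle ~180, accepted
  h_to <- protein_atom(3, "SER", "HG", don - c(0, 0, 1.0))
  cc_to <- classify_contacts(rbind(df, ser, h_to))
  expect_true(any(cc_to$type == "hbond" & cc_to$dna_atom == "O6"))
  ## hydrogen pointing away: angle ~0, rejected
  h_away <- protein_atom(3, "SER", "HG", don + c(0, 0, 1.0))
  cc_away <- classify_contacts(rbind(df, ser, h_away))
  expect_false(any(cc_away$type == "hbond" & cc_away$dna_atom == "O6"))
})

test_that("classification is deterministic and rigid-motion invariant", {
  set.seed(81)
  s <- build_coordinates("GCACGT")
  df <- s$models[[1]]
  o6 <- dna_atom_xyz(df, "A", 4, "O6")
  prot <- rbind(protein_atom(1, "ARG", "NH2", o6 + c(1.5, 1.5, 1.5)),
                protein_atom(2, "LEU", "CD1", o6 + c(2, 2, 2)))
  all_atoms <- rbind(df, prot)
  cc1 <- classify_contacts(all_atoms)
  expect_identical(cc1, classify_contacts(all_atoms))
  R <- random_rotation(); t0 <- stats::rnorm(3, 0, 20)
  moved <- all_atoms
  xyz <- as.matrix(all_atoms[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1] + t0[1]; moved$y <- xyz[, 2] + t0[2]
  moved$z <- xyz[, 3] + t0[3]
  cc2 <- classify_contacts(moved)
  expect_equal(nrow(cc2), nrow(cc1))
  expect_equal(cc2$distance, cc1$distance, tolerance = 1e-9)
  expect_identical(cc2$classification, cc1$classification)
})

test_that("occupancies count frame fractions, matching a Bernoulli toggle", {
  s <- build_coordinates("GCGC")
  df <- s$models[[1]]
  o6 <- dna_atom_xyz(df, "A", 3, "O6")
  near <- protein_atom(1, "ARG", "NH1", o6 + c(0, 0, 2.9))
  far <- protein_atom(1, "ARG", "NH1", o6 + c(0, 0, 9))
  ## always present
  occ1 <- occupancy(list(rbind(df, near), rbind(df, near)))
  expect_equal(occ1$occupancy[occ1$moiety == "base"][1], 1.0)
  ## 1 of 4 frames
  frames <- list(rbind(df, near), rbind(df, far), rbind(df, far),
                 rbind(df, far))
  occ2 <- occupancy(frames)
  base_row <- occ2[occ2$dna_res == "A:3:DG" & occ2$moiety == "base", ]
  expect_equal(nrow(base_row), 1L)
  expect_equal(base_row$occupancy, 0.25)
  expect_equal(base_row$classification, "specific")
  ## seeded Bernoulli toggle at p = 0.3 stays inside the binomial CI
  set.seed(82)
  n <- 400
  p <- 0.3
  frames3 <- lapply(seq_len(n), function(i)
    if (stats::runif(1) < p) rbind(df, near) else rbind(df, far))
  occ3 <- occupancy(frames3)
  row3 <- occ3[occ3$dna_res == "A:3:DG" & occ3$moiety == "base", ]
  expect_equal(nrow(row3), 1L)
  expect_lt(abs(row3$occupancy - p), 3 * sqrt(p * (1 - p) / n))
})
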