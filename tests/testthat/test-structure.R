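test_that("base-frame fit recovers identity, known transforms and noisy placements", {
  for (b in c("A", "C", "G", "T")) {
    std <- dnatwist:::STANDARD_BASES[[b]]
    f <- fit_base_frame(std, b)
    expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-8)
    expect_equal(f$axes, diag(3), tolerance = 1e-8)
  }
  ## equivariance: rotated + translated base recovers exactly R and t
  set.seed(21)
  std <- dnatwist:::STANDARD_BASES[["G"]]
  R <- random_rotation(); t0 <- stats::rnorm(3, 0, 8)
  moved <- sweep(std %*% t(R), 2, t0, `+`)
  rownames(moved) <- rownames(std)
  f <- fit_base_frame(moved, "G")
  expect_equal(f$origin, t0, tolerance = 1e-8)
  expect_equal(f$axes, R, tolerance = 1e-8)
  ## 0.1 A isotropic noise: frame stays within a tolerance computed from an
  ## independent Kabsch superposition (bio3d least-squares rotation)
  noisy <- moved + matrix(stats::rnorm(length(moved), 0, 0.1), nrow(moved))
  rownames(noisy) <- rownames(std)
  fn <- fit_base_frame(noisy, "G")
  ring <- dnatwist:::BASE_RING_ATOMS[["G"]]
  obs <- noisy[ring, ]; ref <- std[ring, ]
  ## independent superposition oracle (bio3d least-squares rotation): the
  ## fitted ring coordinates determine the frame uniquely, so both routes
  ## must land on the same superposed coordinates
  oc <- sweep(obs, 2, colMeans(obs))
  rc <- sweep(ref, 2, colMeans(ref))
  oracle <- matrix(bio3d::rot.lsq(xx = as.vector(t(rc)),
                                  yy = as.vector(t(oc))),
                   ncol = 3, byrow = TRUE)
  oracle <- sweep(oracle, 2, colMeans(obs), `+`)
  mine <- dnatwist:::place_atoms(fn, ref)
  expect_equal(unname(mine), unname(oracle), tolerance = 1e-6)
  ## the noisy frame stays within the noise scale of the clean one
  rms_oracle <- sqrt(mean((oracle - obs)^2))
  expect_lt(max(abs(fn$origin - t0)), 3 * rms_oracle)
  ang <- acos(pmin(1, (sum(diag(t(fn$axes) %*% R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 5)
  ## missing ring atom is named in the error
  expect_error(fit_base_frame(std[rownames(std) != "N7", ], "G"), "N7")
  expect_error(fit_base_frame(std, "X"), "unknown base")
})

test_that("built coordinates round-trip through the frame fit", {
  ## ideal B-DNA parameters are recovered from rebuilt coordinates
  s <- build_coordinates("GATC")
  fr <- structure_frames(s$models[[1]])
  for (i in 1:3)
    expect_equal(unname(step_params(fr$bp_frames[[i]], fr$bp_frames[[i + 1]])),
                 c(0, 0, 3.38, 0, 0, 36), tolerance = 1e-6)
  expect_equal(unname(fr$intra), matrix(0, 4, 6), tolerance = 1e-6,
               ignore_attr = TRUE)
  ## arbitrary seeded parameters (inter + intra) are fully recovered
  set.seed(22)
  n <- 6
  sp <- cbind(stats::rnorm(n - 1, 0, 0.5), stats::rnorm(n - 1, 0, 0.5),
              stats::rnorm(n - 1, 3.38, 0.2), stats::rnorm(n - 1, 0, 4),
              stats::rnorm(n - 1, 2, 4), stats::rnorm(n - 1, 34, 4))
  ip <- cbind(stats::rnorm(n, 0, 0.2), stats::rnorm(n, 0, 0.2),
              stats::rnorm(n, 0, 0.2), stats::rnorm(n, 0, 5),
              stats::rnorm(n, -8, 5), stats::rnorm(n, 0, 3))
  s2 <- build_coordinates("GATCGA", sp, ip)
  fr2 <- structure_frames(s2$models[[1]])
  got_sp <- t(vapply(1:(n - 1), function(i)
    step_params(fr2$bp_frames[[i]], fr2$bp_frames[[i + 1]]), numeric(6)))
  expect_equal(unname(got_sp), unname(sp), tolerance = 1e-6)
  expect_equal(unname(fr2$intra), unname(ip), tolerance = 1e-6)
  ## degenerate single bp: one model, no steps
  s1 <- build_coordinates("G")
  expect_equal(length(s1$models), 1L)
  expect_equal(s1$n_bp, 1L)
  expect_error(build_coordinates("GAXT"), "non-ACGT")
})

test_that("multi-model PDB writing round-trips through bio3d", {
  set.seed(23)
  sp1 <- dnatwist:::ideal_bdna_params(5)
  sp2 <- sp1; sp2[, "twist"] <- sp2[, "twist"] + stats::rnorm(4, 0, 2)
  s <- build_coordinates("GATCG", list(sp1, sp2))
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  back <- read_dna_pdb(path)
  expect_equal(length(back$models), 2L)
  expect_equal(back$sequence, "GATCG")
  m0 <- s$models[[2]]; m1 <- back$models[[2]]
  m1 <- m1[order(m1$chain, m1$resno, m1$elety), ]
  m0 <- m0[order(m0$chain, m0$resno, m0$elety), ]
  expect_equal(m1$elety, m0$elety)
  expect_equal(m1$x, m0$x, tolerance = 1e-3)
  expect_equal(m1$z, m0$z, tolerance = 1e-3)
  ## analysis works identically on the re-read structure
  tab <- helical_parameter_table(back)
  tw <- tab$value[tab$kind == "step" & tab$parameter == "twist" &
                    tab$model == 2]
  expect_equal(tw, unname(sp2[, "twist"]), tolerance = 1e-3)
})

test_that("Watson-Crick hydrogen bond check flags melting at >= 4 A", {
  s <- build_coordinates("GCAT")
  hb <- wc_hbond_check(s$models[[1]])
  expect_true(all(hb$max_distance < 4))
  expect_false(any(hb$melted))
  expect_equal(nrow(hb), 4L)
  ## artificially opened pair: translate the Crick strand of bp 2 away
  df <- s$models[[1]]
  sel <- df$chain == "B" & df$resno == 3  # pairs with Watson bp 2
  df$x[sel] <- df$x[sel] + 5
  hb2 <- wc_hbond_check(df)
  expect_true(hb2$melted[2])
  ## boundary: a pair sitting exactly at 4.0 A counts as melted (the ">="
  ## convention); only the O6-N4 pair is measurable here
  df3 <- rbind(
    data.frame(chain = "A", resno = 1, resname = "DG", elety = "O6",
               x = 0, y = 0, z = 0),
    data.frame(chain = "B", resno = 1, resname = "DC", elety = "N4",
               x = 4, y = 0, z = 0))
  hb3 <- wc_hbond_check(df3)
  expect_identical(hb3$max_distance, 4.0)
  expect_true(hb3$melted)
  ## unknown base pairing errors out
  df4 <- df3; df4$resname[df4$chain == "B"] <- "DT"
  expect_error(wc_hbond_check(df4), "Watson-Crick")
})

test_that("groove widths match a brute-force cross-strand P-P scan", {
  s <- build_coordinates(SEQ23)
  df <- s$models[[1]]
  g <- groove_geometry(df)
  ## independent oracle: exhaustive scan over all cross-strand P-P
  ## distances, classified by the sign of the fractional level offset
  n <- 23
  pw <- df[df$chain == "A" & df$elety == "P", ]
  pc <- df[df$chain == "B" & df$elety == "P", ]
  lw <- pw$resno - 0.5
  lc <- n - pc$resno + 1.5
  for (L in c(5, 9, 12, 16, 19)) {
    best_minor <- Inf; best_major <- Inf
    for (i in seq_len(nrow(pw))) for (j in seq_len(nrow(pc))) {
      d <- sqrt(sum((pw[i, c("x", "y", "z")] - pc[j, c("x", "y", "z")])^2))
      lev <- (lw[i] + lc[j]) / 2
      if (round(lev) != L) next
      if (lw[i] < lc[j]) best_minor <- min(best_minor, d)
      else best_major <- min(best_major, d)
    }
    row <- g[g$level == L, ]
    expect_equal(row$minor_width, best_minor - 5.8, tolerance = 0.01)
    expect_equal(row$major_width, best_major - 5.8, tolerance = 0.01)
  }
  expect_true(all(g$minor_width >= 0, na.rm = TRUE))
})

test_that("groove widths respond to radial expansion and undertwisting", {
  s <- build_coordinates(SEQ23)
  df <- s$models[[1]]
  g <- groove_geometry(df)
  ## +1 A radial expansion of every P widens both grooves at every level
  df2 <- df
  isP <- df2$elety == "P"
  r <- sqrt(df2$x[isP]^2 + df2$y[isP]^2)
  df2$x[isP] <- df2$x[isP] * (r + 1) / r
  df2$y[isP] <- df2$y[isP] * (r + 1) / r
  g2 <- groove_geometry(df2)
  expect_true(all(g2$minor_width > g$minor_width, na.rm = TRUE))
  expect_true(all(g2$major_width > g$major_width, na.rm = TRUE))
  ## undertwisted fibre: wider major groove at interior levels
  s31 <- build_coordinates(SEQ23, dnatwist:::ideal_bdna_params(23, twist = 31))
  g31 <- groove_geometry(s31$models[[1]])
  interior <- g$level %in% 6:18
  expect_true(all(g31$major_width[interior] > g$major_width[interior]))
  ## a structure missing interior phosphates flags NA instead of failing
  df3 <- df[!(df$elety == "P" & df$chain == "A" & df$resno %in% 9:13), ]
  g3 <- groove_geometry(df3)
  expect_true(anyNA(g3$minor_width))
})
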