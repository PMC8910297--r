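# shared fixtures and small independent oracles, all built in code

# the nine residues with the largest planted bound-state shifts of the
# demonstration fixture: the panel a global fit would use
demo_panel9 <- function() {
  res <- galectin_demo_residues()
  off <- sqrt(res$dH_offset^2 + (0.14 * res$dN_offset)^2)
  res[order(-off, res$residue_id), ][1:9, ]
}

# a randomized but valid titration dataset for round-trip properties
random_titration <- function(seed, n_res = 6, n_pts = 4,
                             qualities = c("ok", "overlapped", "missing")) {
  withr::with_seed(seed, {
    ids <- sort(sample(108:250, n_res))
    names_ <- sample(c("ALA", "HIS", "ASN"), n_res, replace = TRUE)
    lig <- c(0, sort(runif(n_pts - 1, 1, 2000)))
    rows <- do.call(rbind, lapply(seq_len(n_pts), function(i) {
      q <- sample(qualities, n_res, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1)[seq_along(qualities)])
      data.frame(
        point_index = i, protein_total_uM = 270, ligand_total_uM = lig[i],
        residue_id = ids,
        residue_name = names_,
        delta_H_ppm = ifelse(q == "missing", NA, round(runif(n_res, 7, 9.5), 4)),
        delta_N_ppm = ifelse(q == "missing", NA, round(runif(n_res, 105, 130), 3)),
        quality = q
      )
    }))
    as_titration_data(rows, metadata = list(ligand = "TestLigand",
                                            temperature_K = "303"))
  })
}

# a toy two-residue PDB built line by line (synthetic coordinates)
toy_pdb_lines <- function() {
  fmt <- function(serial, name, resn, resi, x, y, z, b) {
    sprintf("ATOM  %5d %-4s%3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
            serial, name, resn, resi, x, y, z, 1.00, b,
            substr(trimws(name), 1, 1))
  }
  c("HEADER    TOY STRUCTURE",
    fmt(1, " N  ", "HIS", 158, 1.0, 2.0, 3.0, 10.00),
    fmt(2, " CA ", "HIS", 158, 2.0, 2.5, 3.5, 10.00),
    fmt(3, " N  ", "ASN", 160, 4.0, 4.5, 5.0, 20.00),
    fmt(4, " CA ", "ASN", 160, 5.0, 5.5, 6.0, 20.00),
    "TER",
    "END")
}

# von Mises sampler (Best & Fisher 1979), used only as a test oracle
rvonmises_deg <- function(n, mu_deg, kappa) {
  mu <- mu_deg * pi / 180
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1
    }
  }
  deg <- out * 180 / pi
  ((deg + 180) %% 360) - 180
}

# uniformly random proper rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

make_moving_dataset <- function(disp_H, disp_N = rep(0, length(disp_H)),
                                quality = rep("ok", length(disp_H))) {
  n <- length(disp_H)
  as_titration_data(data.frame(
    point_index = seq_len(n), protein_total_uM = 270,
    ligand_total_uM = c(0, seq_len(n - 1)) * 10,
    residue_id = 158L, residue_name = "HIS",
    delta_H_ppm = 8 + disp_H, delta_N_ppm = 118 + disp_N, quality = quality
  ))
}

make_profiles <- function(d_final, ids = seq_along(d_final) + 107L) {
  # two-point profiles with prescribed final distances (delta_H = d*sqrt(2))
  as_titration_data(data.frame(
    point_index = rep(1:2, each = length(ids)), protein_total_uM = 270,
    ligand_total_uM = rep(c(0, 1000), each = length(ids)),
    residue_id = rep(ids, 2), residue_name = "ALA",
    delta_H_ppm = 8 + c(rep(0, length(ids)), d_final * sqrt(2)),
    delta_N_ppm = 118, quality = "ok"
  )) |> csp_profiles()
}

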