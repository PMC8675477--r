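# Independent oracles and small fixture builders used across the suite.

# Horn's quaternion-eigenvalue method for the optimal-superposition RMSD:
# independent of the SVD route used by kabsch().
quaternion_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  m <- crossprod(ac, bc)
  s <- matrix(0, 4, 4)
  s[1, 1] <- m[1, 1] + m[2, 2] + m[3, 3]
  s[1, 2] <- s[2, 1] <- m[2, 3] - m[3, 2]
  s[1, 3] <- s[3, 1] <- m[3, 1] - m[1, 3]
  s[1, 4] <- s[4, 1] <- m[1, 2] - m[2, 1]
  s[2, 2] <- m[1, 1] - m[2, 2] - m[3, 3]
  s[2, 3] <- s[3, 2] <- m[1, 2] + m[2, 1]
  s[2, 4] <- s[4, 2] <- m[1, 3] + m[3, 1]
  s[3, 3] <- -m[1, 1] + m[2, 2] - m[3, 3]
  s[3, 4] <- s[4, 3] <- m[2, 3] + m[3, 2]
  s[4, 4] <- -m[1, 1] - m[2, 2] + m[3, 3]
  lam <- max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a))
}

# Closed-form chi-square upper tail at even degrees of freedom 2k:
# P(X >= x) = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!
chisq_even_df_tail <- function(x, k) {
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

# Angle between an estimated and a planted axis, sign-invariant (a C2 axis
# has no preferred direction).
axis_angle_deg <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

random_rotation <- function() {
  ax <- rnorm(3)
  pseudosym:::rotation_about_axis(ax / sqrt(sum(ax^2)), runif(1, 0.1, pi))
}

# Hand-format a CA-only PDB ATOM line.
pdb_ca_line <- function(serial, resname, chain, resno, x, y, z, occ = 1,
                        atom = "CA") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, paste0(" ", atom), resname, chain, resno, x, y, z, occ, 0)
}

# Minimal mmCIF with the given CA records (list of lists with resname, chain,
# resno, x, y, z).
write_minimal_cif <- function(records, path) {
  hdr <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    sprintf("ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
            i, r$resname, r$chain, r$resno, r$x, r$y, r$z, r$resno, r$resname,
            r$chain)
  }, character(1))
  writeLines(c(hdr, body, "#"), path)
  path
}

# Location of optional real reference data (downloadable where a network
# exists; see scripts/fetch_reference_data.R).
reference_path <- function(file) {
  local <- file.path("..", "..", "inst", "extdata", "reference", file)
  inst <- system.file("extdata", "reference", file, package = "pseudosym")
  if (nzchar(inst) && file.exists(inst)) return(inst)
  local
}
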