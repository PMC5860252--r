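# fixtures are built in code at test time; oracles here are deliberately
# naive re-derivations, independent of the package's vectorized paths

pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, alt = " ", icode = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f  0.00           %s",
          serial, name, alt, resid, chain, resno, icode,
          xyz[1], xyz[2], xyz[3], occ, substr(name, 1, 1))
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# place two residues (with CB) at an exact representative-atom distance
two_residue_structure <- function(distance, sep = 10L) {
  L <- sep + 1L
  ca <- matrix(0, L, 3)
  ca[, 1] <- seq(0, by = 300, length.out = L)  # park the others far away
  cb <- ca + 1.53 * matrix(c(0, 1, 0), L, 3, byrow = TRUE)
  ca[L, ] <- c(0, 0, 400)
  cb[L, ] <- cb[1, ] + c(distance, 0, 0)
  structure_model("pair", paste(rep("A", L), collapse = ""), ca, cb)
}

random_structure <- function(L, seed) {
  make_native(generator_config(seed = seed, L = L, topology = "random_coil"))
}

# O(L^2) all-pairs contact scan
oracle_contacts <- function(structure, criteria = contact_criteria()) {
  rep <- representative_coords(structure, warn = FALSE)
  L <- model_length(structure)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < criteria$min_separation) next
      d <- sqrt(sum((rep[i, ] - rep[j, ])^2))
      if (d < criteria$distance_cutoff) {
        ii <- c(ii, i); jj <- c(jj, j)
      }
    }
  }
  if (!length(ii)) return(NULL)
  data.frame(i = ii, j = jj, sep = jj - ii,
             range = ifelse(jj - ii > criteria$short_long_boundary,
                            "long", "short"))
}

# run enumeration for the spread metric
oracle_spread <- function(predictions, truth, L) {
  correct <- in_contact_set(predictions$i, predictions$j, truth)
  covered <- sort(unique(c(predictions$i[correct], predictions$j[correct])))
  covered <- covered[covered <= L]
  if (!length(covered)) return(1)
  longest <- 0
  run <- 0
  for (r in seq_len(L)) {
    if (r %in% covered) run <- 0 else run <- run + 1
    longest <- max(longest, run)
  }
  longest / L
}

# O(n^2) pairwise-identity Neff
oracle_neff <- function(m, threshold = 0.8) {
  rows <- strsplit(m$rows, "")
  n <- length(rows)
  total <- 0
  for (s in seq_len(n)) {
    cluster <- 0
    for (t in seq_len(n)) {
      if (s == t) { cluster <- cluster + 1; next }
      a <- rows[[s]]; b <- rows[[t]]
      both <- a != "-" & a != "." & b != "-" & b != "."
      id <- if (!any(both)) 0 else sum(a[both] == b[both]) / sum(both)
      if (id >= threshold) cluster <- cluster + 1
    }
    total <- total + 1 / cluster
  }
  total
}

# exhaustive threshold scan with naive per-candidate confusion counts
oracle_threshold <- function(sat, lab) {
  obs <- sat[!is.na(sat)]
  cand <- sort(unique(c(0, obs, max(c(obs, 0)) + 1e-9)))
  err <- vapply(cand, function(t) {
    kept <- !is.na(sat) & sat >= t
    sum(kept & !lab) + sum(!kept & lab)
  }, numeric(1))
  cand[which.min(err)]
}

oracle_roc_point <- function(sat, lab, t) {
  kept <- !is.na(sat) & sat >= t
  c(sensitivity = sum(kept & lab) / sum(lab),
    specificity = sum(!kept & !lab) / sum(!lab))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_copy <- function(model, seed) {
  rot <- random_rotation(seed)
  set.seed(seed + 1)
  shift <- rnorm(3, sd = 10)
  ca <- model$ca %*% rot + matrix(shift, nrow(model$ca), 3, byrow = TRUE)
  structure_model(paste0(model$id, "_rigid"), model$sequence, ca, NULL)
}
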