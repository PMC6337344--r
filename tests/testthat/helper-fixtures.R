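# Fixtures are generated in code at test time; nothing binary on disk.

write_fasta_text <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}

# synthetic AAindex1 flat file with three entries:
#   SYNT000101: values 1..20 (canonical order probe)
#   SYNT000102: a hydropathy-like synthetic scale
#   SYNT000103: contains NA values (must be flagged unusable)
write_aaindex_fixture <- function(path = tempfile(fileext = ".txt")) {
  fmt_row <- function(v) paste(sprintf("%8s", v), collapse = "")
  scale2 <- c("1.8", "-4.5", "-3.5", "-3.5", "2.5", "-3.5", "-3.5",
              "-0.4", "-3.2", "4.5", "3.8", "-3.9", "1.9", "2.8",
              "-1.6", "-0.8", "-0.7", "-0.9", "-1.3", "4.2")
  lines <- c(
    "H SYNT000101",
    "D Integer ramp 1..20 (synthetic test fixture)",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    fmt_row(1:10), fmt_row(11:20),
    "//",
    "H SYNT000102",
    "D Hydropathy-like synthetic scale",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    fmt_row(scale2[1:10]), fmt_row(scale2[11:20]),
    "//",
    "H SYNT000103",
    "D Scale with missing values",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    fmt_row(c("0.1", "NA", as.character(3:10))), fmt_row(11:20),
    "//")
  writeLines(lines, path)
  path
}

# synthetic symmetric substitution matrix in square text format
write_submat_fixture <- function(path = tempfile(fileext = ".txt")) {
  aa <- aa_alphabet()
  m <- outer(1:20, 1:20, function(i, j) round(8 * exp(-abs(i - j) / 4)))
  lines <- c("# synthetic substitution matrix (test fixture)",
             paste(" ", paste(aa, collapse = "  ")),
             vapply(1:20, function(i)
               paste(aa[i], paste(m[i, ], collapse = " ")), ""))
  writeLines(lines, path)
  path
}

# minimal single-chain PDB text from an atom table
# (resno, name, element, x, y, z, altloc optional)
write_pdb_fixture <- function(atoms, path = tempfile(fileext = ".pdb")) {
  lines <- vapply(seq_len(nrow(atoms)), function(r) {
    a <- atoms[r, ]
    alt <- if (!is.null(a$altloc)) a$altloc else ""
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r, a$name, alt, "ALA", "A", a$resno, "",
            a$x, a$y, a$z, 1.00, 0.00, a$element)
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# brute-force contact oracle: all-against-all atom double loop
brute_force_contacts <- function(atoms, threshold = 8) {
  res <- match(atoms$resno, unique(atoms$resno))
  n <- max(res)
  pairs <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    ia <- which(res == a); ib <- which(res == b)
    mind <- Inf
    for (p in ia) for (q in ib) {
      d <- sqrt(sum((unlist(atoms[p, c("x", "y", "z")]) -
                     unlist(atoms[q, c("x", "y", "z")])) ^ 2))
      mind <- min(mind, d)
    }
    if (mind < threshold) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs)) do.call(rbind, pairs) else matrix(integer(), 0L, 2L)
}

random_toy_atoms <- function(n_res = 6, max_atoms = 3, spread = 12) {
  rows <- lapply(seq_len(n_res), function(r) {
    k <- sample.int(max_atoms, 1L)
    center <- runif(3, 0, spread)
    data.frame(resno = r,
               x = center[1] + rnorm(k), y = center[2] + rnorm(k),
               z = center[3] + rnorm(k))
  })
  do.call(rbind, rows)
}

pair_keys <- function(m) {
  if (nrow(m) == 0L) return(character())
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
}
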