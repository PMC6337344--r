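test_that("contacts use the strict minimum-heavy-atom distance rule", {
  atoms <- data.frame(resno = c(1, 2), x = c(0, 7.9), y = 0, z = 0)
  expect_equal(nrow(contact_map_from_coords(atoms)$pairs), 1L)
  atoms$x[2] <- 8.0                       # exactly 8 A is NOT a contact
  expect_equal(nrow(contact_map_from_coords(atoms)$pairs), 0L)
  # a residue is never in contact with itself
  solo <- data.frame(resno = 1, x = c(0, 1), y = 0, z = 0)
  cm <- contact_map_from_coords(solo)
  expect_equal(nrow(cm$pairs), 0L)
  expect_error(contact_map(cbind(3, 3), 5), "self-pairs")
  expect_error(contact_map_from_coords(atoms[0, ]), "empty structure")
})

test_that("coordinate contact maps match the brute-force oracle", {
  set.seed(41)
  for (rep in 1:8) {
    atoms <- random_toy_atoms(n_res = 6)
    fast <- contact_map_from_coords(atoms)
    slow <- brute_force_contacts(atoms)
    expect_setequal(pair_keys(fast$pairs), pair_keys(slow))
  }
})

test_that("PDB reading drops hydrogens and keeps heavy-atom geometry", {
  # residue 2's hydrogen sits close to residue 1; heavy atoms are far
  atoms <- data.frame(resno = c(1, 2, 2),
                      name = c("CA", "CA", "H"),
                      element = c("C", "C", "H"),
                      x = c(0, 20, 5), y = 0, z = 0)
  p <- write_pdb_fixture(atoms)
  cm <- contact_map_from_structure(p)
  expect_equal(nrow(cm$pairs), 0L)
  # move the heavy atom inside the threshold
  atoms$x[2] <- 6
  cm2 <- contact_map_from_structure(write_pdb_fixture(atoms))
  expect_equal(pair_keys(cm2$pairs), "1 2")
})

test_that("contact maps round-trip through TSV", {
  cm <- contact_map(rbind(c(2, 9), c(1, 7)), n_residues = 10)
  p <- tempfile(fileext = ".tsv")
  write_contact_tsv(cm, p)
  back <- read_contact_tsv(p, n_residues = 10)
  expect_setequal(pair_keys(back$pairs), pair_keys(cm$pairs))
})

test_that("PPV counts true positives among the top k", {
  truth <- contact_map(cbind(1:200, 301:500), n_residues = 600)
  perfect <- data.frame(i = 1:200, j = 301:500)
  pv <- ppv_curve(perfect, truth)
  expect_equal(pv$ppv, rep(1, 200))
  expect_equal(pv$auc200, 200)

  none <- data.frame(i = 1:100, j = 201:300)
  pv0 <- ppv_curve(none, truth)
  expect_equal(pv0$auc200, 0)
  expect_true(pv0$short)

  # outcomes (T, F, T, F) -> PPV (1, 1/2, 2/3, 1/2)
  mixed <- data.frame(i = c(1, 250, 2, 251), j = c(301, 590, 302, 591))
  pvm <- ppv_curve(mixed, truth)
  expect_equal(pvm$ppv, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(pvm$auc200, 8 / 3)
  expect_error(ppv_curve(perfect[0, ], truth), "empty prediction")
})

test_that("PPV depends only on prediction order and truth membership", {
  truth <- contact_map(rbind(c(1, 9), c(2, 8)), n_residues = 10)
  base <- data.frame(i = c(1, 3, 2), j = c(9, 9, 8), score = c(9, 5, 1))
  rescored <- transform(base, score = score * 100 - 7)
  expect_equal(ppv_curve(base, truth)$ppv, ppv_curve(rescored, truth)$ppv)
})

test_that("swapping a false positive for a true one increases AUC200", {
  truth <- contact_map(cbind(1:50, 101:150), n_residues = 200)
  pred <- data.frame(i = c(1:30, 61:80), j = c(101:130, 161:180))
  worse <- pred
  worse$i[10] <- 60; worse$j[10] <- 160   # make rank-10 a false positive
  expect_gt(ppv_curve(pred, truth)$auc200, ppv_curve(worse, truth)$auc200)
})

test_that("per-k t-tests follow the textbook pooled formula", {
  set.seed(42)
  n <- 150
  A <- matrix(rnorm(n * 5, mean = 0.9, sd = 0.05), n, 5)
  B <- matrix(rnorm(n * 5, mean = 0.5, sd = 0.05), n, 5)
  res <- compare_ppv_sets(A, B)
  expect_true(all(res$p_value < 1e-10))
  expect_equal(res$verdict, "different")

  # oracle: pooled two-sample t statistic at k = 1
  a <- A[, 1]; b <- B[, 1]
  sp2 <- ((n - 1) * var(a) + (n - 1) * var(b)) / (2 * n - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / n))
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 2 * n - 2)
  expect_equal(res$statistic[1], t_manual, tolerance = 1e-10)
  expect_equal(res$p_value[1], p_manual, tolerance = 1e-10)
})

test_that("the all-k rule governs the verdict", {
  set.seed(43)
  n <- 40
  A <- matrix(rnorm(n * 4, 0.9, 0.05), n, 4)
  B <- matrix(rnorm(n * 4, 0.5, 0.05), n, 4)
  B[, 3] <- A[, 3]                        # one indistinguishable level
  res <- compare_ppv_sets(A, B)
  expect_true(any(res$p_value >= 0.05))
  expect_equal(res$verdict, "indistinguishable")

  ident <- compare_ppv_sets(A, A)
  expect_equal(ident$p_value, rep(1, 4))
  expect_equal(ident$statistic, rep(0, 4))
  expect_equal(ident$verdict, "indistinguishable")

  expect_error(compare_ppv_sets(A, B[1:10, ]), "family counts differ")
})

test_that("reference mapping skips gap columns of the first sequence", {
  x <- msa(c("A-CD-E", "AACDDE"))
  mp <- reference_mapping(x)
  expect_equal(mp, c(1L, NA, 2L, 3L, NA, 4L))

  pred <- structure(
    data.frame(rank = 1:3, i = c(1L, 2L, 3L), j = c(6L, 6L, 6L),
               score = c(3, 2, 1)),
    class = c("contact_prediction", "data.frame"),
    min_separation = 0L, L = 6L)
  mapped <- map_prediction(pred, mp)
  expect_equal(nrow(mapped), 2L)          # pair touching column 2 dropped
  expect_equal(mapped$i, c(1L, 2L))
  expect_equal(mapped$j, c(4L, 4L))
})
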