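test_that("feature perception matches the group definitions", {
  # benzene: exactly one feature, Aro, at the ring centroid
  benz <- read_sdf(paste(benzene_sdf_text(), collapse = "\n"))[[1]]
  fe <- perceive_features(benz)
  expect_equal(nrow(fe), 1L)
  expect_equal(fe$ftype, "Aro")
  expect_equal(c(fe$x, fe$y, fe$z), colMeans(benz$conformers[[1]]),
               tolerance = 1e-9)

  # glycine zwitterion: one Cat (N), one Ani (carboxylate midpoint),
  # Don/Acc present, no Aro, no Hyd
  gly <- glycine_zwitterion()
  fg <- perceive_features(gly)
  expect_equal(sum(fg$ftype == "Cat"), 1L)
  expect_equal(sum(fg$ftype == "Ani"), 1L)
  expect_false(any(fg$ftype %in% c("Aro", "Hyd")))
  expect_true(any(fg$ftype == "Don"))
  expect_true(any(fg$ftype == "Acc"))
  ani <- fg[fg$ftype == "Ani", ]
  expect_equal(c(ani$x, ani$y, ani$z),
               colMeans(gly$conformers[[1]][4:5, ]), tolerance = 1e-9)

  # diprotonated piperazine: two cation features on the opposite nitrogens
  pip <- piperazine_2h()
  fp <- perceive_features(pip)
  expect_equal(sum(fp$ftype == "Cat"), 2L)
  expect_false(any(fp$ftype == "Aro"))

  expect_error(perceive_features(gly, conformer = 2L), "out of range")
})

test_that("matching: identity placement, type mismatch, sorted output", {
  ph1 <- toy_ph1()
  centers <- ph1$features[, c("x", "y", "z")]
  ident <- data.frame(
    ftype = c("Ani", "Aro", "Hyd"),
    x = centers$x[c(1, 3, 5)], y = centers$y[c(1, 3, 5)],
    z = centers$z[c(1, 3, 5)],
    member_atoms = I(list(1L, 2L, 3L)))
  m <- match_model(ph1, ident)
  expect_equal(nrow(m), 1L)
  expect_lt(m$fit_rmsd[1], 1e-9)
  expect_equal(m$matched_labels[1], "F1,F3,F5")

  # retyping the F5-site feature breaks the essential point
  bad <- ident
  bad$ftype[3] <- "Aro"
  expect_equal(nrow(match_model(ph1, bad)), 0L)

  # two placements: exact and 0.5-A-perturbed; exact sorts first
  pert <- ident
  pert$x <- pert$x + c(0.3, -0.3, 0.3)
  both <- rbind(ident, pert)
  both$member_atoms <- I(as.list(1:6))
  mm <- match_model(ph1, both)
  expect_gt(nrow(mm), 1L)
  expect_equal(mm$fit_rmsd, sort(mm$fit_rmsd))
  expect_lt(mm$fit_rmsd[1], 1e-9)
})

test_that("matcher equals the exhaustive enumeration oracle on random cases", {
  set.seed(7)
  types <- c("Aro", "Hyd", "Ani", "Cat", "Don", "Acc")
  for (case in 1:12) {
    nf <- sample(3:6, 1)
    feats_m <- data.frame(label = paste0("F", seq_len(nf)),
                          ftype = sample(types, nf, replace = TRUE),
                          x = runif(nf, -6, 6), y = runif(nf, -6, 6),
                          z = runif(nf, -6, 6),
                          radius = runif(nf, 0.8, 2.0))
    ess <- sample(feats_m$label, 1)
    model <- pharmacophore_model("rand", feats_m,
                                 constraint_spec(essential = ess))
    nl <- sample(4:8, 1)
    # half the ligand features sit near model centers, half are random
    near <- sample(nf, min(nl, nf))
    lx <- rbind(
      as.matrix(feats_m[near, c("x", "y", "z")]) +
        matrix(runif(3 * length(near), -1, 1), ncol = 3),
      matrix(runif(3 * max(0, nl - length(near)), -8, 8), ncol = 3))
    lf <- data.frame(ftype = c(feats_m$ftype[near],
                               sample(types, nl - length(near), replace = TRUE)),
                     x = lx[, 1], y = lx[, 2], z = lx[, 3],
                     member_atoms = I(as.list(seq_len(nl))))
    got <- match_model(model, lf)
    want <- exhaustive_match(model, lf)
    expect_equal(nrow(got), length(want))
    if (nrow(got)) {
      got_keys <- sort(vapply(seq_len(nrow(got)), function(r)
        paste(names(got$assignment[[r]]), got$assignment[[r]],
              sep = ":", collapse = ","), ""))
      want_keys <- sort(vapply(want, `[[`, "", "key"))
      expect_equal(got_keys, want_keys)
      expect_equal(sort(got$fit_rmsd),
                   sort(vapply(want, `[[`, 0, "rmsd")), tolerance = 1e-9)
    }
  }
})

test_that("matching is invariant under rigid motion of the conformer", {
  ph1 <- toy_ph1()
  lig <- make_matching_ligand(ph1, c("F1", "F3", "F5"), seed = 11)
  fe <- perceive_features(lig)
  base <- match_model(ph1, fe)
  set.seed(99)
  for (rep in 1:5) {
    mo <- random_rigid_motion()
    fe2 <- fe
    fe2[, c("x", "y", "z")] <- apply_rigid(as.matrix(fe[, c("x", "y", "z")]), mo)
    m2 <- match_model(ph1, fe2)
    expect_equal(nrow(m2), nrow(base))
    expect_equal(m2$matched_labels, base$matched_labels)
    expect_equal(m2$fit_rmsd, base$fit_rmsd, tolerance = 1e-6)
  }
})

test_that("planted ligands match their generating model; decoys do not", {
  for (seed in c(1, 2, 3)) {
    ph1 <- toy_ph1()
    ph2 <- toy_ph2()
    for (model in list(ph1, ph2)) {
      lig <- make_matching_ligand(model, c("F2", "F4", "F5"), seed = seed)
      m <- match_model(model, perceive_features(lig))
      expect_gt(nrow(m), 0L)
      expect_true(any(grepl("F5", m$matched_labels)))
      decoy <- make_matching_ligand(model, c("F2", "F4", "F5"), seed = seed,
                                    drop_label = "F5")
      expect_equal(nrow(match_model(model, perceive_features(decoy))), 0L)
    }
  }
})

test_that("Lipinski filter: thresholds, boundaries, and worked molecules", {
  mk <- function(el, bonds, fc = NULL, logp = NULL) {
    m <- small_molecule(el, bonds, matrix(rnorm(3 * length(el)), ncol = 3),
                        formal_charge = fc)
    if (!is.null(logp)) m$properties$logp <- logp
    m
  }
  # ethanol: HBA 1, HBD 1, MW ~ 46.07
  eth <- mk(c("C", "C", "O"), data.frame(i = 1:2, j = 2:3, order = 1))
  rep_eth <- lipinski_filter(eth)
  expect_equal(rep_eth$hba, 1L)
  expect_equal(rep_eth$hbd, 1)
  expect_equal(rep_eth$mw, 46.069, tolerance = 1e-3)
  expect_true(rep_eth$passes)

  # oversized molecule fails on MW only
  big <- mk(rep("C", 42), data.frame(i = 1:41, j = 2:42, order = 1), logp = 2)
  rep_big <- lipinski_filter(big)
  expect_false(rep_big$passes)
  expect_equal(rep_big$violated_rules, "MW")

  # boundary semantics: HBA = 10 and HBD = 5 pass (rules are <=)
  el <- c(rep("N", 5), rep("O", 5), rep("C", 3))
  bonds <- data.frame(i = c(11:12, 1:5, 6:10), j = c(12:13, rep(11, 5), rep(12, 5)),
                      order = 1)
  m10 <- mk(el, bonds, logp = 1)
  r10 <- lipinski_filter(m10)
  expect_equal(r10$hba, 10L)
  expect_true(!("HBA" %in% r10$violated_rules))
  hbd <- sum(ppiscreen:::.implicit_h(m10)[1:10])
  expect_gte(hbd, 5)   # construction check: enough N-H/O-H to probe HBD

  # logp property preferred over the estimator; missing estimator errors
  withp <- mk(c("C", "O"), data.frame(i = 1, j = 2, order = 1), logp = 7)
  expect_equal(lipinski_filter(withp)$violated_rules, "LOGP")
  nop <- mk(c("C", "O"), data.frame(i = 1, j = 2, order = 1))
  expect_error(lipinski_filter(nop, logp_estimator = NULL), "estimator")
  expect_error(lipinski_filter(mk("XX", data.frame(i = integer(),
                                                   j = integer(),
                                                   order = integer()))),
               "unknown element")
})

test_that("HBA counting is monotone under adding heteroatoms", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    el <- sample(c("C", "N", "O"), n, replace = TRUE)
    bonds <- data.frame(i = seq_len(n - 1), j = 2:n, order = 1)
    m <- small_molecule(el, bonds, matrix(rnorm(3 * n), ncol = 3))
    m$properties$logp <- 1
    base <- lipinski_filter(m)$hba
    m2 <- small_molecule(c(el, "O"), rbind(bonds, data.frame(i = n, j = n + 1,
                                                             order = 1)),
                         matrix(rnorm(3 * (n + 1)), ncol = 3))
    m2$properties$logp <- 1
    expect_gte(lipinski_filter(m2)$hba, base + 1L)
  }
})
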