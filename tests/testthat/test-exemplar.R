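test_that("ROI extraction counts valid window centers", {
  # grid exactly 20x20 in-plane: valid 9x9 centers form a 12x12 lattice
  v <- ct_volume(array(-500, c(20, 20, 1)))
  m <- voxel_mask(array(TRUE, c(20, 20, 1)))
  expect_length(extract_rois(v, m, stride = 1), 144)
  expect_length(extract_rois(v, m, stride = 2), 36)

  m1 <- voxel_mask(array(FALSE, c(20, 20, 1)))
  m1$data[10, 10, 1] <- TRUE
  expect_length(extract_rois(v, m1), 1)
  expect_error(extract_rois(v, voxel_mask(array(FALSE, c(20, 20, 1)))),
               "empty")
})

test_that("ROI similarity is a symmetric negative squared distance", {
  a <- make_patch(-800); b <- make_patch(-400)
  expect_identical(roi_similarity(a, a), 0)
  set.seed(2)
  r1 <- make_patch(-600, 50); r2 <- make_patch(-300, 80)
  expect_equal(roi_similarity(r1, r2), roi_similarity(r2, r1))
  # hand evaluation: 81 elements each differing by 400/1224 in feature space
  expect_equal(roi_similarity(a, b), -81 * (400 / 1224)^2)
  # clipping: -1100 and -1024 are feature-identical
  expect_identical(roi_similarity(make_patch(-1100), make_patch(-1024)), 0)
})

test_that("affinity propagation finds the obvious exemplar structure", {
  expect_identical(affinity_propagation(matrix(0, 1, 1))$exemplars, 1L)

  # three tight, mutually distant clusters of 5 points
  set.seed(4)
  pts <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 10, 0.05), 5),
               matrix(rnorm(10, 20, 0.05), 5))
  D2 <- as.matrix(dist(pts))^2
  ap <- affinity_propagation(-D2)
  expect_length(ap$exemplars, 3)
  expect_true(ap$converged)
  # labels match nearest-exemplar assignment (brute force)
  nearest <- ap$exemplars[apply(D2[, ap$exemplars], 1, which.min)]
  expect_identical(ap$labels, as.integer(nearest))

  # duplicates receive identical labels
  pts2 <- rbind(pts, pts[1, , drop = FALSE])
  D2b <- as.matrix(dist(pts2))^2
  apb <- affinity_propagation(-D2b)
  expect_identical(apb$labels[16], apb$labels[1])

  expect_error(affinity_propagation(matrix(0, 2, 3)), "square")
  expect_error(affinity_propagation(-D2, damping = 1), "damping")
})

test_that("the exemplar fit recovers well-separated texture levels", {
  lvls <- seq(-950, -100, length.out = 9)
  rois <- make_level_rois(lvls, per_level = 6, noise_sd = 8, seed = 1)
  mod <- fit_exemplar_model(rois)
  expect_s3_class(mod, "exemplar_model")
  expect_identical(nrow(mod$features), 9L)
  # one exemplar per level: exemplar mean HU close to a distinct level
  mhu <- sort(vapply(mod$patches, function(p) mean(p$values), numeric(1)))
  expect_true(all(abs(mhu - lvls) < 40))
  # color partition: ground-glass-like codes at the lowest densities
  expect_identical(sort(names(mod$groups[mod$groups == "BCG"])),
                   c("B", "C", "G"))
  expect_identical(sort(names(mod$groups[mod$groups == "VIRO"])),
                   c("I", "O", "R", "V"))
  # each exemplar is its own nearest exemplar
  selfsim <- apply(mod$features, 1, function(f)
    which.max(-colSums((t(mod$features) - f)^2)))
  expect_identical(unname(selfsim), 1:9)
})

test_that("the single-exemplar limit equals the exhaustive medoid", {
  rois <- make_level_rois(c(-800, -750, -700), per_level = 4, noise_sd = 30,
                          seed = 3)
  mod1 <- fit_exemplar_model(rois, k_target = 1)
  Fm <- t(vapply(rois, nodulect:::roi_features, numeric(81)))
  S <- -as.matrix(dist(Fm))^2
  best <- oracle_1medoid(S)
  expect_equal(mod1$patches[[1]]$values, rois[[best]]$values)
})

test_that("too few ROIs is an error", {
  expect_error(fit_exemplar_model(make_level_rois(c(-500), 3), k_target = 9),
               "at least 9")
})

test_that("voxel classification equals the brute-force argmax", {
  lvls <- seq(-950, -100, length.out = 9)
  mod <- fit_exemplar_model(make_level_rois(lvls, 6, 8, seed = 1))

  # random textured nodule in a small volume
  set.seed(9)
  v <- ct_volume(array(rnorm(24^3, -500, 250), c(24, 24, 24)))
  m <- voxel_mask(array(FALSE, c(24, 24, 24)))
  m$data[8:17, 9:15, 11:13] <- TRUE
  lab <- classify_voxels(v, m, mod)
  expect_identical(lab[m$data], oracle_classify(v, m, mod))

  # voxels whose window is an exact copy of exemplar Y's patch all map to Y
  vy <- v
  patchY <- mod$patches[["Y"]]$values
  my <- voxel_mask(array(FALSE, c(24, 24, 24)))
  for (z in c(5, 12)) for (bx in c(1, 10)) for (by in c(1, 10)) {
    vy$data[bx:(bx + 8), by:(by + 8), z] <- patchY
    my$data[bx + 4, by + 4, z] <- TRUE
  }
  laby <- classify_voxels(vy, my, mod)
  expect_true(all(attr(laby, "colors")[laby[my$data]] == "Y"))

  m1 <- voxel_mask(array(FALSE, c(24, 24, 24)))
  m1$data[12, 12, 12] <- TRUE
  expect_equal(sum(classify_voxels(v, m1, mod) > 0), 1)
})

test_that("glyphs are normalized percentages of labeled voxels", {
  m <- voxel_mask(array(TRUE, c(5, 5, 4)))
  lab <- array(1L, c(5, 5, 4))  # all V
  attr(lab, "colors") <- nodulect:::EXEMPLAR_COLORS
  g <- compute_glyph(lab, m)
  expect_equal(unname(unclass(g)["V"]), 100)
  expect_equal(sum(unclass(g)), 100)

  lab2 <- array(0L, c(5, 5, 4))
  lab2[1:100] <- rep(c(1L, 2L, 5L, 9L), each = 25)  # V, I, Y, P
  attr(lab2, "colors") <- nodulect:::EXEMPLAR_COLORS
  g2 <- compute_glyph(lab2, m)
  expect_equal(unname(unclass(g2)[c("V", "I", "Y", "P")]), rep(25, 4))

  set.seed(5)
  lab3 <- array(sample(1:9, 100, TRUE), c(5, 5, 4))
  attr(lab3, "colors") <- nodulect:::EXEMPLAR_COLORS
  g3 <- compute_glyph(lab3, m)
  counts <- table(factor(nodulect:::EXEMPLAR_COLORS[lab3],
                         levels = nodulect:::EXEMPLAR_COLORS))
  expect_equal(unclass(g3), 100 * c(counts) / 100, ignore_attr = TRUE)
})

test_that("composite features partition the glyph", {
  g <- structure(c(V = 100, I = 0, B = 0, G = 0, Y = 0, O = 0, R = 0,
                   C = 0, P = 0), class = "glyph")
  cf <- composite_features(g)
  expect_equal(unname(cf["VIRO"]), 100)
  expect_equal(unname(cf["YP"] + cf["BCG"]), 0)

  set.seed(6)
  for (i in 1:200) {
    x <- runif(9); x <- 100 * x / sum(x)
    gi <- structure(setNames(x, nodulect:::EXEMPLAR_COLORS), class = "glyph")
    ci <- composite_features(gi)
    expect_lt(abs(ci["VIRO"] + ci["YP"] + ci["BCG"] - 100), 1e-9)
    expect_equal(unname(ci["YplusG"]), unname(ci["Y"] + ci["G"]))
  }
})

test_that("screening cutoffs are boundary-inclusive", {
  f <- function(viro, yp) structure(
    c(VIRO = viro, YP = yp, BCG = 100 - viro - yp, Y = yp / 2, G = 5,
      YplusG = yp / 2 + 5), class = "composite_features")
  expect_true(apply_cutoff(f(70, 20), "VIRO"))
  expect_true(apply_cutoff(f(71, 20), "VIRO"))
  expect_false(apply_cutoff(f(71.0001, 20), "VIRO"))
  expect_true(apply_cutoff(f(50, 23.5), "YP"))
  expect_false(apply_cutoff(f(50, 23.4), "YP"))
  expect_error(apply_cutoff(f(50, 20), "nope"), "unknown")
})

test_that("risk groups order by the invasive component", {
  mk <- function(viro) {
    rest <- (100 - viro) / 5
    structure(setNames(c(viro, 0, rest, rest, rest, 0, 0, rest, rest),
                       nodulect:::EXEMPLAR_COLORS), class = "glyph")
  }
  labs <- assign_risk_groups(list(mk(5), mk(50), mk(95)))
  expect_identical(labs, c("G", "I", "P"))

  expect_warning(labs2 <- assign_risk_groups(list(mk(50), mk(50), mk(50))),
                 "degenerate")
  expect_identical(labs2, rep("I", 3))

  # 12 nodules from 3 archetypes: agreement with the generative archetype
  set.seed(7)
  glyphs <- list(); truth <- integer(0)
  for (arc in 1:3) for (r in 1:4) {
    base <- c(5, 50, 95)[arc]
    x <- pmax(unclass(mk(base)) + rnorm(9, 0, 1), 0)
    x <- 100 * x / sum(x)
    glyphs <- c(glyphs, list(structure(
      setNames(x, nodulect:::EXEMPLAR_COLORS), class = "glyph")))
    truth <- c(truth, arc)
  }
  labs3 <- assign_risk_groups(glyphs)
  expect_gte(mean(labs3 == c("G", "I", "P")[truth]), 0.95)
  # clustering matches the exhaustive 3-medoid optimum
  Gm <- t(vapply(glyphs, unclass, numeric(9)))
  br <- oracle_best_3medoids(as.matrix(dist(Gm)))
  expect_identical(as.integer(factor(labs3, levels = c("G", "I", "P"))),
                   as.integer(factor(br$assignment,
                                     levels = unique(br$assignment))))
})
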