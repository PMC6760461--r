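atlas1 <- roi_atlas("J1")
atlas2 <- roi_atlas(c("J1", "J2"))
right_idx <- which(atlas1$hemisphere == "right")
left_idx <- which(atlas1$hemisphere == "left")
fl_idx <- which(atlas1$region_class == "fronto-limbic")
op_idx <- which(atlas1$region_class == "occipito-parietal")

test_that("intra-brain lateralization matches hand counts", {
  # all edges in the right hemisphere -> +1
  m <- adj_from_edges(26, list(right_idx[1:2], right_idx[2:3]))
  expect_equal(as.numeric(lateralization_intra(m, atlas1)), 1)
  # R = 3, L = 1 -> (3 - 1) / (3 + 1) = 0.5
  m <- adj_from_edges(26, list(right_idx[1:2], right_idx[2:3],
                               right_idx[c(1, 4)], left_idx[1:2]))
  expect_equal(as.numeric(lateralization_intra(m, atlas1)), 0.5)
  # equal counts -> 0; inter-hemispheric edges are excluded
  m <- adj_from_edges(26, list(right_idx[1:2], left_idx[1:2],
                               c(right_idx[3], left_idx[3])))
  expect_equal(as.numeric(lateralization_intra(m, atlas1)), 0)
  # no classified edges -> 0 with flag
  m <- adj_from_edges(26, list(c(right_idx[1], left_idx[1])))
  r <- lateralization_intra(m, atlas1)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "no_classified_edges"))
})

test_that("intra-brain regional asymmetry matches hand counts", {
  m <- adj_from_edges(26, list(fl_idx[1:2], fl_idx[2:3]))
  expect_equal(as.numeric(regional_asymmetry_intra(m, atlas1)), 1)
  # F = 1, P = 3 -> -0.5
  m <- adj_from_edges(26, list(fl_idx[1:2], op_idx[1:2], op_idx[2:3],
                               op_idx[c(1, 4)]))
  expect_equal(as.numeric(regional_asymmetry_intra(m, atlas1)), -0.5)
  # F = 2, P = 2 -> 0
  m <- adj_from_edges(26, list(fl_idx[1:2], fl_idx[3:4], op_idx[1:2],
                               op_idx[3:4]))
  expect_equal(as.numeric(regional_asymmetry_intra(m, atlas1)), 0)
})

test_that("inter-brain indices count attachments of the chosen member", {
  empty <- matrix(0, 26, 26)
  # all inter edges attach to J1's right hemisphere -> +1
  inter <- matrix(0, 26, 26)
  inter[right_idx[1], 1:3] <- 1
  h <- assemble_hyperbrain(empty, empty, inter)
  expect_equal(as.numeric(lateralization_inter(h, atlas2, "J1")), 1)
  # 6 right-attached, 2 left-attached -> 0.5
  inter <- matrix(0, 26, 26)
  inter[right_idx[1], 1:4] <- 1
  inter[right_idx[2], 5:6] <- 1
  inter[left_idx[1], 7:8] <- 1
  h <- assemble_hyperbrain(empty, empty, inter)
  expect_equal(as.numeric(lateralization_inter(h, atlas2, "J1")), 0.5)
  # symmetric attachment -> 0
  inter <- matrix(0, 26, 26)
  inter[right_idx[1], 1] <- 1
  inter[left_idx[1], 2] <- 1
  h <- assemble_hyperbrain(empty, empty, inter)
  expect_equal(as.numeric(lateralization_inter(h, atlas2, "J1")), 0)
  # J2 attachments counted over columns: 1 FL vs 3 OP -> -0.5
  fl2 <- which(atlas1$region_class == "fronto-limbic")
  op2 <- which(atlas1$region_class == "occipito-parietal")
  inter <- matrix(0, 26, 26)
  inter[1, fl2[1]] <- 1
  inter[2, op2[1]] <- 1; inter[3, op2[2]] <- 1; inter[4, op2[3]] <- 1
  h <- assemble_hyperbrain(empty, empty, inter)
  expect_equal(as.numeric(regional_asymmetry_inter(h, atlas2, "J2")), -0.5)
  expect_error(lateralization_inter(h, atlas2, "J9"), "not present")
})

test_that("swapping class labels negates every index", {
  set.seed(5)
  flipped <- atlas1
  flipped$hemisphere <- ifelse(atlas1$hemisphere == "left", "right", "left")
  flipped_rc <- atlas1
  flipped_rc$region_class <- ifelse(atlas1$region_class == "fronto-limbic",
                                    "occipito-parietal", "fronto-limbic")
  for (k in 1:10) {
    m <- rand_adj(26, 0.15)
    expect_equal(as.numeric(lateralization_intra(m, flipped)),
                 -as.numeric(lateralization_intra(m, atlas1)))
    expect_equal(as.numeric(regional_asymmetry_intra(m, flipped_rc)),
                 -as.numeric(regional_asymmetry_intra(m, atlas1)))
  }
})

test_that("adding a favored-class edge never decreases the index", {
  set.seed(6)
  for (k in 1:20) {
    m <- rand_adj(26, 0.1)
    base <- as.numeric(lateralization_intra(m, atlas1))
    free <- which(m[right_idx, right_idx] == 0 &
                    upper.tri(m[right_idx, right_idx]), arr.ind = TRUE)
    if (!nrow(free)) next
    pick <- free[sample(nrow(free), 1), ]
    m2 <- m
    m2[right_idx[pick[1]], right_idx[pick[2]]] <- 1
    m2[right_idx[pick[2]], right_idx[pick[1]]] <- 1
    expect_gte(as.numeric(lateralization_intra(m2, atlas1)), base)
  }
})

test_that("all indices stay within [-1, 1] on random networks", {
  set.seed(7)
  for (k in 1:10) {
    m <- rand_adj(26, runif(1, 0.05, 0.6))
    vals <- c(as.numeric(lateralization_intra(m, atlas1)),
              as.numeric(regional_asymmetry_intra(m, atlas1)))
    inter <- matrix(rbinom(676, 1, 0.2), 26, 26)
    h <- assemble_hyperbrain(m, m, inter)
    vals <- c(vals,
              as.numeric(lateralization_inter(h, atlas2, "J1")),
              as.numeric(lateralization_inter(h, atlas2, "J2")),
              as.numeric(regional_asymmetry_inter(h, atlas2, "J1")),
              as.numeric(regional_asymmetry_inter(h, atlas2, "J2")))
    expect_true(all(vals >= -1 & vals <= 1))
  }
})
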