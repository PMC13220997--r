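# The pairwise complexity game and the Bradley-Terry fit.

test_that("duels compare each feature independently and antisymmetrically", {
  a <- list(info_density = 2.0, heterogeneity = 0.7, variability = 5.0)
  b <- list(info_density = 1.0, heterogeneity = 0.5, variability = 3.0)
  expect_equal(duel(a, b), list(wins_a = 3L, wins_b = 0L, ties = 0L))
  expect_equal(duel(a, a), list(wins_a = 0L, wins_b = 0L, ties = 3L))
  mixed <- list(info_density = 3.0, heterogeneity = 0.5, variability = 1.0)
  ab <- duel(a, mixed); ba <- duel(mixed, a)
  expect_equal(ab$wins_a, ba$wins_b)
  expect_equal(ab$wins_b, ba$wins_a)
  expect_equal(ab$ties, ba$ties)
  expect_equal(ab$wins_a + ab$wins_b + ab$ties, 3)
  bad <- list(info_density = NaN, heterogeneity = 0.5, variability = 1)
  expect_error(duel(a, bad), class = "leaftex_validation_error")
})

test_that("a dominating species wins every contested point", {
  tr <- fake_triplets(c(1, 2), n_per_species = 5, noise = 0)
  W <- run_tournament(tr, pairs_per_species_pair = 50, seed = 1)
  expect_equal(unname(W$w["sp02", "sp01"]), 150)
  expect_equal(unname(W$w["sp01", "sp02"]), 0)
  expect_equal(unname(W$n_matches["sp01", "sp02"]), 150)
  # per-patch win fractions: dominated species never wins a point
  pp <- W$patch_points
  expect_true(all(pp$win_fraction[pp$species == "sp01"] == 0))
  expect_true(all(pp$win_fraction[pp$species == "sp02"] == 1))
})

test_that("win credits are conserved for every species pair", {
  tr <- fake_triplets(c(1, 1.02, 1.04, 1.06), n_per_species = 8, noise = 0.05)
  W <- run_tournament(tr, pairs_per_species_pair = 40, seed = 3)
  expect_equal(W$w + t(W$w), W$n_matches + 0)
  expect_true(all(diag(W$w) == 0))
  expect_true(all(W$w >= 0))
  # total patch points match the matrix totals
  expect_equal(sum(W$patch_points$points_won), sum(W$w))
  expect_equal(sum(W$patch_points$points_contested), sum(W$n_matches))
})

test_that("identical patch populations draw at one half", {
  base <- fake_triplets(c(1), n_per_species = 30, noise = 1, seed = 7)
  two <- rbind(base, transform(base, species = "sp99",
                               patch_id = paste0(patch_id, "x")))
  fr <- vapply(1:10, function(s) {
    W <- run_tournament(two, pairs_per_species_pair = 1000, seed = s)
    W$w["sp01", "sp99"] / W$n_matches["sp01", "sp99"]
  }, 0)
  expect_lt(abs(mean(fr) - 0.5), 0.02)
})

test_that("tournament reruns are seed-deterministic and validate input", {
  tr <- fake_triplets(c(1, 2, 3), n_per_species = 6, noise = 0.1)
  W1 <- run_tournament(tr, pairs_per_species_pair = 100, seed = 5)
  W2 <- run_tournament(tr, pairs_per_species_pair = 100, seed = 5)
  expect_identical(W1$w, W2$w)
  expect_identical(W1$patch_points, W2$patch_points)
  expect_error(run_tournament(tr[tr$species == "sp01", ]),
               class = "leaftex_validation_error")
  one_patch <- rbind(tr, transform(tr[1, ], species = "lonely"))
  expect_error(run_tournament(one_patch, seed = 1),
               class = "leaftex_validation_error")
})

test_that("two-player Bradley-Terry matches the closed form", {
  w <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  fit <- fit_bradley_terry(make_winmatrix(w), pseudocount = 0)
  expect_equal(fit$bt_ability[fit$species == "A"] /
                 fit$bt_ability[fit$species == "B"], 3, tolerance = 1e-6)
  expect_equal(sum(fit$log_ability), 0, tolerance = 1e-9)
})

test_that("Bradley-Terry MM agrees with a likelihood grid search", {
  # two players
  w2 <- matrix(c(0, 7, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  fit2 <- fit_bradley_terry(make_winmatrix(w2), pseudocount = 0.5)
  grid2 <- bt_grid_search(w2 + 0.5 - diag(c(0.5, 0.5)))
  expect_lt(max(abs(fit2$log_ability - grid2)), 0.01)
  # three players, asymmetric
  w3 <- matrix(c(0, 8, 3,
                 4, 0, 6,
                 9, 2, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fit3 <- fit_bradley_terry(make_winmatrix(w3), pseudocount = 0.5)
  grid3 <- bt_grid_search(w3 + 0.5 - diag(rep(0.5, 3)))
  expect_lt(max(abs(fit3$log_ability - grid3)), 0.01)
})

test_that("symmetric win matrices give equal abilities and scores of 0.5", {
  w <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(w) <- 0
  fit <- fit_bradley_terry(make_winmatrix(w))
  expect_equal(fit$log_ability, rep(0, 3), tolerance = 1e-8)
  expect_equal(fit$score, rep(0.5, 3))
})

test_that("species relabeling permutes the score table identically", {
  w <- matrix(c(0, 9, 1,
                3, 0, 5,
                7, 6, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- fit_bradley_terry(make_winmatrix(w))
  perm <- c(3, 1, 2)
  w2 <- w[perm, perm]
  dimnames(w2) <- list(c("x", "y", "z"), c("x", "y", "z"))
  fit2 <- fit_bradley_terry(make_winmatrix(w2))
  # c->x, a->y, b->z
  m <- match(c("y", "z", "x"), fit2$species)
  expect_equal(fit2$log_ability[m], fit$log_ability, tolerance = 1e-9)
  expect_equal(fit2$rank[m], fit$rank)
})

test_that("extra wins strictly increase a species' ability", {
  for (s in 1:5) {
    w <- with_test_seed(s, matrix(rpois(25, 20), 5, 5))
    diag(w) <- 0
    dimnames(w) <- list(letters[1:5], letters[1:5])
    fit <- fit_bradley_terry(make_winmatrix(w))
    w2 <- w; w2[1, 2] <- w2[1, 2] + 15
    fit2 <- fit_bradley_terry(make_winmatrix(w2))
    expect_gt(fit2$log_ability[1] - fit$log_ability[1], 0)
  }
})

test_that("rank_species sorts ascending with lexicographic ties", {
  tbl <- data.frame(species = c("B", "A", "C"), score = c(0.9, 0.1, 0.5))
  expect_equal(rank_species(tbl)$species, c("A", "C", "B"))
  tie <- data.frame(species = c("B", "A"), score = c(0.5, 0.5))
  expect_equal(rank_species(tie)$species, c("A", "B"))
})
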