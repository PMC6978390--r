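# The planted-truth generators.

test_that("rho = 1 members correlate perfectly with the anchor", {
  panel <- simulate_accessibility_panel(n_background = 20, n_members = 5,
                                        n_celltypes = 10, rho = 1, seed = 2)
  rv <- correlate_with_anchor(panel$matrix, panel$truth$anchor_id)
  member_r <- rv$r[rv$region_id %in% panel$truth$member_ids]
  expect_equal(member_r, rep(1, 5), tolerance = 1e-12)
})

test_that("sample correlations concentrate around the generation rho", {
  panel <- simulate_accessibility_panel(n_background = 30, n_members = 10,
                                        n_celltypes = 100, rho = 0.9,
                                        seed = 1)
  rv <- correlate_with_anchor(panel$matrix, panel$truth$anchor_id)
  member_r <- rv$r[rv$region_id %in% panel$truth$member_ids]
  expect_true(all(abs(member_r - 0.9) < 0.06))
})

test_that("zero members yields an independent panel with an empty member list", {
  panel <- simulate_accessibility_panel(n_background = 15, n_members = 0,
                                        n_celltypes = 8, rho = 0.95, seed = 4)
  expect_equal(length(panel$truth$member_ids), 0)
  expect_equal(nrow(panel$matrix), nrow(panel$regions))
})

test_that("generator rejects invalid rho and too few cell types", {
  expect_error(simulate_accessibility_panel(rho = 0, seed = 1), "rho")
  expect_error(simulate_accessibility_panel(rho = 1.2, seed = 1), "rho")
  expect_error(simulate_accessibility_panel(n_celltypes = 3, seed = 1),
               "n_celltypes")
})

test_that("signal values are non-negative and the truth chain is nested", {
  st <- simulate_plexus_study(seed = 9)
  vals <- as.matrix(st$matrix[, -1])
  expect_true(all(vals >= 0))
  expect_true(all(st$truth$mutated_ids %in% st$truth$marked_ids))
  expect_true(all(st$truth$marked_ids %in% st$truth$member_ids))
  # every variant position falls inside its mutated region
  mut <- st$regions[match(st$truth$mutated_ids, st$regions$region_id), ]
  for (i in seq_len(nrow(st$variants))) {
    pos0 <- st$variants$pos[i] - 1
    expect_true(any(pos0 >= mut$start & pos0 < mut$end))
  }
})

test_that("activity peaks cover exactly the marked members", {
  st <- simulate_plexus_study(seed = 12)
  members <- st$regions[match(st$truth$member_ids, st$regions$region_id), ]
  active <- call_active(members, st$activity_track)
  expect_setequal(active$region_id, st$truth$marked_ids)
})

test_that("variants-per-region of 1 gives one SNV per mutated member", {
  panel <- simulate_accessibility_panel(n_background = 20, n_members = 6,
                                        n_celltypes = 10, seed = 5)
  layer <- simulate_tracks_and_variants(panel, marked_fraction = 1,
                                        mutated_count = 6,
                                        variants_per_region = 1,
                                        n_tumors = 3, seed = 6)
  expect_equal(layer$truth$n_variants, 6)
  expect_equal(layer$truth$n_mutated, 6)
  expect_equal(layer$truth$n_tumors, 3)
})

test_that("mutated_count above the marked count is refused", {
  panel <- simulate_accessibility_panel(n_background = 10, n_members = 4,
                                        n_celltypes = 10, seed = 7)
  expect_error(
    simulate_tracks_and_variants(panel, marked_fraction = 0.5,
                                 mutated_count = 4, seed = 7),
    "exceeds"
  )
})

test_that("same seed produces byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(simulate_plexus_study(seed = 42), d1,
                scores = simulate_essentiality(n_lines = 50, seed = 42))
  write_fixture(simulate_plexus_study(seed = 42), d2,
                scores = simulate_essentiality(n_lines = 50, seed = 42))
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("cascade reproduces the truth manifest across 20 random seeds", {
  for (seed in 1:20) {
    st <- simulate_plexus_study(seed = seed, n_background = 60,
                                n_members = 8, n_celltypes = 50,
                                marked_fraction = 0.75, mutated_count = 2,
                                variants_per_region = c(2, 1), n_tumors = 2)
    rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                       st$activity_track, st$variants)
    expect_equal(rep$n_dhs_in_window, st$truth$n_dhs_in_window,
                 label = sprintf("seed %d window", seed))
    expect_equal(rep$n_plexus_members, st$truth$n_members,
                 label = sprintf("seed %d members", seed))
    expect_equal(rep$n_active, st$truth$n_active,
                 label = sprintf("seed %d active", seed))
    expect_equal(rep$n_mutated, st$truth$n_mutated,
                 label = sprintf("seed %d mutated", seed))
    expect_equal(rep$n_variants, st$truth$n_variants,
                 label = sprintf("seed %d variants", seed))
    expect_equal(rep$n_tumors, st$truth$n_tumors,
                 label = sprintf("seed %d tumors", seed))
  }
})

test_that("force_extreme places the group strictly below all background", {
  sim <- simulate_essentiality(n_lines = 40, group_size = 4,
                               force_extreme = TRUE, seed = 8)
  grp <- sim$scores$score[sim$scores$id %in% sim$group]
  bg <- sim$scores$score[!sim$scores$id %in% sim$group]
  expect_true(max(grp) < min(bg))
})

test_that("a group equal to the whole panel gives p = 1", {
  sim <- simulate_essentiality(n_lines = 12, group_size = 12, seed = 9)
  res <- permutation_median_test(sim$scores, sim$group, n_perm = 200,
                                 seed = 10)
  expect_equal(res$p_value, 1)
})
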